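# Persistence and configuration-driven runs.

# write a numeric data.frame/matrix as CSV with full double precision so a
# round trip reproduces every value bit-for-bit (internal)
write_csv_exact <- function(x, path) {
  x <- as.data.frame(x)
  chr <- vapply(x, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  }, character(nrow(x)))
  chr <- matrix(chr, nrow = nrow(x))
  con <- file(path, "wb")  # binary mode: identical bytes across platforms
  on.exit(close(con))
  writeLines(paste(colnames(x), collapse = ","), con)
  writeLines(apply(chr, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Persist a kmreg fit to a directory
#'
#' Writes the stored samples (`samples.csv`, one row per stored state with
#' columns `beta.*`, `sigma2`, `lam`, `r.*`, `delta.*`, `tau_b2`; probit
#' latent draws in `ystar.csv`), the run metadata (`metadata.json`: seed,
#' control and prior settings, acceptance rates, column names,
#' standardization constants, package version, input checksum), the knots
#' (`knots.csv`, GPP fits) and the training data (`data.csv`) — everything
#' needed to reproduce any posterior summary exactly.
#'
#' @param fit a [kmreg] fit.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_kmreg <- function(fit, dir) {
  stopifnot(inherits(fit, "kmreg"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_csv_exact(flatten_samples(fit), file.path(dir, "samples.csv"))
  if (!is.null(fit$samples$ystar)) {
    ys <- fit$samples$ystar
    colnames(ys) <- paste0("ystar.", seq_len(ncol(ys)))
    write_csv_exact(ys, file.path(dir, "ystar.csv"))
  }
  dat <- data.frame(y = fit$data$y, fit$data$Z, check.names = FALSE)
  if (ncol(fit$data$X)) dat <- cbind(dat, fit$data$X)
  if (!is.null(fit$data$id)) dat$.cluster <- fit$data$id
  write_csv_exact(dat, file.path(dir, "data.csv"))
  if (!is.null(fit$knots)) {
    # persisted on the standardized exposure scale used by the kernel, so
    # a reload reproduces the fit's algebra exactly
    kn <- as.data.frame(fit$knots)
    names(kn) <- colnames(fit$data$Z)
    write_csv_exact(kn, file.path(dir, "knots.csv"))
  }
  meta <- list(
    package = "kmrmix",
    version = as.character(utils::packageVersion("kmrmix")),
    family = fit$family, varsel = fit$varsel,
    groups = if (is.null(fit$groups)) NULL else as.character(fit$groups),
    exposures = colnames(fit$data$Z), covariates = colnames(fit$data$X),
    n = length(fit$data$y), n_stored = fit$n_stored,
    control = unclass(fit$control), priors = unclass(fit$priors),
    acceptance = fit$acceptance,
    std_center = unname(fit$std$center), std_scale = unname(fit$std$scale),
    standardize = fit$std$standardize, nugget = fit$nugget,
    data_checksum = unname(tools::md5sum(file.path(dir, "data.csv"))))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' Reload a persisted kmreg fit
#'
#' Reconstructs a [kmreg] object from a directory written by
#' [write_kmreg()]; all posterior summaries recomputed from the reloaded
#' object reproduce the in-memory results bit-for-bit.
#'
#' @param dir directory written by [write_kmreg()].
#' @return object of class `kmreg`.
#' @export
read_kmreg <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  flat <- as.matrix(utils::read.csv(file.path(dir, "samples.csv")))
  dat <- utils::read.csv(file.path(dir, "data.csv"), check.names = FALSE)
  M <- length(meta$exposures); P <- length(meta$covariates)
  S <- nrow(flat)
  grab <- function(prefix, k, names_out) {
    if (k == 0) return(matrix(numeric(0), S, 0))
    m <- flat[, paste0(prefix, seq_len(k)), drop = FALSE]
    colnames(m) <- names_out
    m
  }
  samples <- list(
    beta = grab("beta.", P, meta$covariates),
    sigma2 = flat[, "sigma2"], lam = flat[, "lam"],
    r = grab("r.", M, meta$exposures),
    delta = grab("delta.", M, meta$exposures),
    tau_b2 = if ("tau_b2" %in% colnames(flat)) flat[, "tau_b2"] else NULL,
    ystar = NULL, loglik = NULL)
  ys_path <- file.path(dir, "ystar.csv")
  if (file.exists(ys_path))
    samples$ystar <- unname(as.matrix(utils::read.csv(ys_path)))
  id <- if (".cluster" %in% names(dat)) dat$.cluster else NULL
  kd <- kmr_data(outcome = dat$y,
                 exposures = as.matrix(dat[, meta$exposures, drop = FALSE]),
                 covariates = if (P) as.matrix(dat[, meta$covariates, drop = FALSE]) else NULL,
                 id = id, family = meta$family)
  # recompute the standardization from the (exactly round-tripped) data so
  # downstream summaries reproduce the in-memory results bit-for-bit
  std <- if (meta$standardize) {
    s <- standardize_exposures(kd$Z)
    list(center = s$center, scale = s$scale, standardize = TRUE)
  } else {
    M0 <- ncol(kd$Z)
    list(center = stats::setNames(rep(0, M0), meta$exposures),
         scale = stats::setNames(rep(1, M0), meta$exposures),
         standardize = FALSE)
  }
  knots <- NULL
  kn_path <- file.path(dir, "knots.csv")
  if (file.exists(kn_path)) {
    knots <- as.matrix(utils::read.csv(kn_path))
    dimnames(knots) <- NULL
  }
  control <- do.call(kmr_control,
                     meta$control[names(meta$control) %in% names(formals(kmr_control))])
  priors <- do.call(kmr_priors,
                    meta$priors[names(meta$priors) %in% names(formals(kmr_priors))])
  structure(list(samples = samples, acceptance = meta$acceptance,
                 data = kd,
                 Zstd = apply_standardize(kd$Z, std$center, std$scale),
                 std = std, knots = knots, nugget = meta$nugget,
                 family = meta$family, varsel = meta$varsel,
                 groups = meta$groups, priors = priors, control = control,
                 n_stored = S, call = NULL, time = NA_real_),
            class = "kmreg")
}

# normalize a config given as a list or a YAML file path (internal).
# Custom bool handlers keep bare y/n/yes/no column names as strings
# (YAML 1.1 would otherwise read a column called "y" as TRUE).
read_config <- function(config) {
  if (is.character(config)) {
    keep_word <- function(x)
      if (toupper(x) %in% c("TRUE", "FALSE")) as.logical(toupper(x)) else x
    config <- yaml::read_yaml(config,
                              handlers = list("bool#yes" = keep_word,
                                              "bool#no" = keep_word))
  }
  stopifnot(is.list(config))
  config
}

#' Fit a model from a configuration
#'
#' Config-driven end-to-end run: reads a CSV dataset, fits [kmreg()] and
#' persists the result with [write_kmreg()] plus a PIP table
#' (`pips.csv`), posterior estimates (`estimates.csv`) and a text summary.
#' The configuration is a list or YAML file with fields `data` (CSV path),
#' `outcome`, `exposures`, optional `covariates`/`id`, `family`, `varsel`,
#' `groups`, `knots`, `output` (directory), `seed`, `n_iter`, `burn`,
#' `thin`, and optional `priors`/`control` override lists mirroring
#' [kmr_priors()] and [kmr_control()].
#'
#' @param config list or YAML path.
#' @return the [kmreg] fit, invisibly.
#' @export
kmr_run <- function(config) {
  cfg <- read_config(config)
  for (field in c("data", "outcome", "exposures", "output"))
    if (is.null(cfg[[field]])) stop("config field missing: ", field)
  df <- utils::read.csv(cfg$data, check.names = FALSE)
  dat <- kmr_data(df, outcome = cfg$outcome, exposures = cfg$exposures,
                  covariates = cfg$covariates, id = cfg$id,
                  family = if (is.null(cfg$family)) "gaussian" else cfg$family)
  ctrl_args <- if (is.null(cfg$control)) list() else cfg$control
  for (field in c("n_iter", "burn", "thin", "seed"))
    if (!is.null(cfg[[field]])) ctrl_args[[field]] <- cfg[[field]]
  control <- do.call(kmr_control, ctrl_args)
  priors <- do.call(kmr_priors,
                    if (is.null(cfg$priors)) list() else cfg$priors)
  varsel <- if (is.null(cfg$varsel)) TRUE else cfg$varsel
  fit <- kmreg(dat, varsel = varsel, groups = cfg$groups, knots = cfg$knots,
               priors = priors, control = control)
  out <- cfg$output
  ok <- FALSE
  tryCatch({
    write_kmreg(fit, out)
    if (varsel) write_csv_exact(extract_pips(fit), file.path(out, "pips.csv"))
    write_csv_exact(posterior_estimates(fit), file.path(out, "estimates.csv"))
    con <- file(file.path(out, "summary.txt"), "w")
    sink(con); print(summary(fit)); sink(); close(con)
    ok <- TRUE
  }, finally = if (!ok) unlink(out, recursive = TRUE))
  invisible(fit)
}

#' Summarize a persisted fit
#'
#' Recomputes requested posterior summaries from a directory written by
#' [write_kmreg()]/[kmr_run()] and writes them as CSV files alongside it.
#'
#' @param dir fit directory.
#' @param requests any of `"pips"`, `"overall"`, `"single"`, `"interact"`,
#'   `"rd"` (probit fits only), `"cross-section"`.
#' @param rd_m exposure index for `"rd"`.
#' @param cs_m exposure index for `"cross-section"`.
#' @param ... further arguments passed to the individual summary functions.
#' @return named list of the computed data.frames, invisibly.
#' @export
kmr_summarize <- function(dir, requests = c("pips", "overall", "single",
                                            "interact"),
                          rd_m = 2, cs_m = 1, ...) {
  fit <- read_kmreg(dir)
  out <- list()
  for (req in requests) {
    res <- switch(req,
      pips = extract_pips(fit),
      overall = overall_effect(fit, ...),
      single = single_exposure_effects(fit, ...),
      interact = interactive_effects(fit, ...),
      rd = risk_difference(fit, m = rd_m, ...),
      `cross-section` = univariate_cross_section(fit, m = cs_m, ...),
      stop("unknown request: ", req))
    fname <- paste0("summary_", gsub("-", "_", req), ".csv")
    write_csv_exact(res, file.path(dir, fname))
    out[[req]] <- res
  }
  invisible(out)
}

#' Predict from a persisted fit
#'
#' Reads new exposure points from CSV, predicts with [predict.kmreg()] and
#' writes the posterior summary table.
#'
#' @param dir fit directory.
#' @param newdata CSV path with the training exposure columns (plus
#'   covariate columns for `type = "prob"`).
#' @param out output CSV path.
#' @param type `"h"` or `"prob"`.
#' @param ... passed to [predict.kmreg()].
#' @return the prediction data.frame, invisibly.
#' @export
kmr_predict_csv <- function(dir, newdata, out, type = "h", ...) {
  fit <- read_kmreg(dir)
  nd <- utils::read.csv(newdata, check.names = FALSE)
  if (!nrow(nd)) stop("new-points file is empty: ", newdata)
  expo <- colnames(fit$data$Z)
  missing_cols <- setdiff(expo, names(nd))
  if (length(missing_cols))
    stop("new-points file lacks exposure columns: ",
         paste(missing_cols, collapse = ", "))
  Xnew <- NULL
  if (type == "prob") {
    cov <- colnames(fit$data$X)
    missing_x <- setdiff(cov, names(nd))
    if (length(missing_x))
      stop("new-points file lacks covariate columns: ",
           paste(missing_x, collapse = ", "))
    Xnew <- as.matrix(nd[, cov, drop = FALSE])
  }
  pred <- predict(fit, Znew = as.matrix(nd[, expo, drop = FALSE]),
                  Xnew = Xnew, type = type, ...)
  write_csv_exact(pred, out)
  invisible(pred)
}
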