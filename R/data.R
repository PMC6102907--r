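#' Assemble and validate a mixture dataset
#'
#' Bundles an outcome vector, an exposure matrix, an optional covariate
#' matrix and optional cluster labels into the validated container used by
#' [kmreg()]. Inputs can be given either as a `data.frame` plus column
#' roles, or directly as vectors/matrices.
#'
#' @param data optional `data.frame` holding all columns. When supplied,
#'   `outcome`, `exposures`, `covariates` and `id` are interpreted as column
#'   names of `data`; otherwise they are taken as the data themselves.
#' @param outcome outcome column name, or a numeric vector of length n.
#'   For `family = "binomial"` every value must be 0 or 1.
#' @param exposures exposure column names, or an n-by-M numeric matrix.
#' @param covariates covariate column names, or an n-by-P numeric matrix
#'   (may be `NULL` for P = 0).
#' @param id optional cluster-id column name or length-n vector of labels
#'   identifying repeated/clustered observations.
#' @param family `"gaussian"` for a continuous outcome or `"binomial"` for
#'   a binary outcome fit by probit regression.
#' @return An object of class `kmr_data`: a list with elements `y`, `Z`,
#'   `X`, `id` (integer codes or `NULL`), and `family`.
#' @examples
#' d <- data.frame(y = rnorm(50), z1 = rnorm(50), z2 = rnorm(50), x = rnorm(50))
#' kmr_data(d, outcome = "y", exposures = c("z1", "z2"), covariates = "x")
#' @export
kmr_data <- function(data = NULL, outcome, exposures, covariates = NULL,
                     id = NULL, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  if (!is.null(data)) {
    stopifnot(is.data.frame(data))
    roles <- c(outcome, exposures, covariates, id)
    if (anyDuplicated(roles))
      stop("duplicated column roles: ", paste(roles[duplicated(roles)], collapse = ", "))
    missing_cols <- setdiff(roles, names(data))
    if (length(missing_cols))
      stop("columns not found in data: ", paste(missing_cols, collapse = ", "))
    y <- data[[outcome]]
    Z <- as.matrix(data[, exposures, drop = FALSE])
    X <- if (length(covariates)) as.matrix(data[, covariates, drop = FALSE]) else NULL
    idv <- if (!is.null(id)) data[[id]] else NULL
  } else {
    y <- as.numeric(outcome)
    Z <- as.matrix(exposures)
    X <- if (!is.null(covariates)) as.matrix(covariates) else NULL
    idv <- id
  }
  n <- length(y)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  if (is.null(X)) X <- matrix(numeric(0), nrow = n, ncol = 0)
  if (!is.null(X) && ncol(X) > 0 && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  storage.mode(Z) <- "double"
  if (ncol(X)) storage.mode(X) <- "double"

  if (nrow(Z) != n || nrow(X) != n)
    stop("y, Z and X must have the same number of rows")
  na_report <- function(M, what) {
    if (anyNA(M)) {
      idx <- which(is.na(M), arr.ind = is.matrix(M))
      if (is.matrix(M)) {
        stop(sprintf("missing values in %s: row %d, column %s", what,
                     idx[1, 1], colnames(M)[idx[1, 2]]))
      }
      stop(sprintf("missing values in %s: row %d", what, idx[1]))
    }
  }
  na_report(y, "outcome")
  na_report(Z, "exposures")
  if (ncol(X)) na_report(X, "covariates")
  if (family == "binomial") {
    bad <- setdiff(unique(y), c(0, 1))
    if (length(bad))
      stop("binomial (probit) outcome must be 0/1; found value ", bad[1])
  }
  if (!is.null(idv)) {
    if (length(idv) != n) stop("cluster id must have length n")
    if (anyNA(idv)) stop("missing values in cluster id")
    idv <- as.integer(factor(idv))
    if (max(idv) < 2L) stop("cluster id defines a single cluster; tau_b^2 is unidentifiable")
  }
  if (n < ncol(Z) + ncol(X) + 2)
    warning(sprintf("small sample: n = %d < M + P + 2 = %d", n, ncol(Z) + ncol(X) + 2))
  structure(list(y = as.numeric(y), Z = Z, X = X, id = idv, family = family),
            class = "kmr_data")
}

#' Standardize exposure columns
#'
#' Centers and scales each exposure column to mean 0 and sample standard
#' deviation 1, recording the transform so predictions and effect summaries
#' can be reported on the original exposure scale. Standardization makes the
#' kernel weights r_m comparable across exposures measured in different units.
#'
#' @param Z numeric matrix of exposures (no constant columns).
#' @return list with elements `Z` (standardized matrix), `center` and
#'   `scale` (per-column constants).
#' @examples
#' standardize_exposures(cbind(z1 = c(1, 2, 3)))
#' @export
standardize_exposures <- function(Z) {
  Z <- as.matrix(Z)
  center <- colMeans(Z)
  scale <- apply(Z, 2, stats::sd)
  if (any(scale == 0)) {
    bad <- colnames(Z)[scale == 0]
    if (is.null(bad)) bad <- which(scale == 0)
    stop("constant exposure column: ", paste(bad, collapse = ", "))
  }
  Zs <- sweep(sweep(Z, 2, center), 2, scale, "/")
  list(Z = Zs, center = center, scale = scale)
}

# inverse of standardize_exposures (internal)
unstandardize <- function(Zs, center, scale) {
  sweep(sweep(as.matrix(Zs), 2, scale, "*"), 2, center, "+")
}

# apply stored standardization to new points (internal)
apply_standardize <- function(Z, center, scale) {
  sweep(sweep(as.matrix(Z), 2, center), 2, scale, "/")
}

#' Prior specification for kernel machine regression
#'
#' Hyperparameters for every prior used by [kmreg()]. The regression
#' coefficients get a flat (improper) prior. The residual variance gets an
#' inverse-gamma prior, the kernel variance ratio lambda = tau^2/sigma^2 a
#' gamma prior, and each selected kernel weight r_m a "slab" prior (uniform
#' by default). The random-intercept variance is parameterized as the ratio
#' lambda_b = tau_b^2/sigma^2 with a gamma prior, which keeps the residual
#' variance update conjugate. Posterior inclusion probabilities can be
#' sensitive to the slab choice, so a sensitivity analysis over these
#' settings is recommended practice.
#'
#' @param sigma2_shape,sigma2_rate inverse-gamma prior on sigma^2.
#' @param lambda_shape,lambda_rate gamma prior on lambda = tau^2/sigma^2.
#' @param slab slab family for active r_m: `"uniform"` on (0, `slab_rmax`)
#'   or `"gamma"` with `slab_shape`/`slab_rate`.
#' @param slab_rmax upper bound of the uniform slab.
#' @param slab_shape,slab_rate gamma slab parameters.
#' @param pi prior inclusion probability of each exposure (or each group in
#'   hierarchical selection), in (0, 1).
#' @param lambda_b_shape,lambda_b_rate gamma prior on the random-intercept
#'   variance ratio lambda_b = tau_b^2/sigma^2.
#' @param birth_rate rate of the truncated-exponential proposal used when a
#'   spike-and-slab birth move draws a fresh r_m.
#' @return object of class `kmr_priors`.
#' @export
kmr_priors <- function(sigma2_shape = 0.001, sigma2_rate = 0.001,
                       lambda_shape = 1, lambda_rate = 0.1,
                       slab = c("uniform", "gamma"), slab_rmax = 100,
                       slab_shape = 1, slab_rate = 1, pi = 0.5,
                       lambda_b_shape = 1, lambda_b_rate = 0.1,
                       birth_rate = 2) {
  slab <- match.arg(slab)
  stopifnot(sigma2_shape > 0, sigma2_rate > 0, lambda_shape > 0,
            lambda_rate > 0, slab_rmax > 0, slab_shape > 0, slab_rate > 0,
            pi > 0, pi < 1, lambda_b_shape > 0, lambda_b_rate > 0,
            birth_rate > 0)
  structure(list(sigma2_shape = sigma2_shape, sigma2_rate = sigma2_rate,
                 lambda_shape = lambda_shape, lambda_rate = lambda_rate,
                 slab = slab, slab_rmax = slab_rmax, slab_shape = slab_shape,
                 slab_rate = slab_rate, pi = pi,
                 lambda_b_shape = lambda_b_shape,
                 lambda_b_rate = lambda_b_rate, birth_rate = birth_rate),
            class = "kmr_priors")
}

#' MCMC control settings
#'
#' Tuning parameters of the hybrid Gibbs/Metropolis-Hastings sampler.
#' Proposal standard deviations apply to random walks on the log scale.
#' The `update_*` switches freeze individual blocks at their starting
#' values, which is useful for validation runs against closed-form
#' conditional distributions.
#'
#' @param n_iter total MCMC iterations (>= 2).
#' @param burn burn-in fraction in \[0, 1).
#' @param thin thinning interval (>= 1).
#' @param seed integer seed; the whole sample path is reproducible given it.
#' @param sd_log_lambda,sd_log_r,sd_log_lambda_b random-walk proposal sds.
#' @param update_beta,update_sigma2,update_lambda,update_r block switches.
#' @param lambda_start,r_start,sigma2_start,lambda_b_start starting values.
#'   `sigma2_start = NULL` uses the residual variance of an initial
#'   least-squares fit. `r_start = NULL` (default) starts every kernel
#'   weight at `0.25/M`, which keeps the initial kernel's total bandwidth
#'   moderate regardless of the number of exposures; with many exposures a
#'   fixed per-component start would make every off-diagonal kernel entry
#'   vanish and strand the sampler in a likelihood region that is flat in
#'   the weights.
#' @param verbose print progress every `report_every` iterations to stderr.
#' @param report_every reporting interval.
#' @return object of class `kmr_control`.
#' @export
kmr_control <- function(n_iter = 10000, burn = 0.5, thin = 1, seed = 1,
                        sd_log_lambda = 0.25, sd_log_r = 0.2,
                        sd_log_lambda_b = 0.25,
                        update_beta = TRUE, update_sigma2 = TRUE,
                        update_lambda = TRUE, update_r = TRUE,
                        lambda_start = 1, r_start = NULL, sigma2_start = NULL,
                        lambda_b_start = 0.5,
                        verbose = FALSE, report_every = 500) {
  stopifnot(n_iter >= 2, burn >= 0, burn < 1, thin >= 1,
            sd_log_lambda > 0, sd_log_r > 0, sd_log_lambda_b > 0,
            lambda_start >= 0, is.null(r_start) || r_start >= 0,
            lambda_b_start >= 0)
  structure(list(n_iter = as.integer(n_iter), burn = burn,
                 thin = as.integer(thin), seed = as.integer(seed),
                 sd_log_lambda = sd_log_lambda, sd_log_r = sd_log_r,
                 sd_log_lambda_b = sd_log_lambda_b,
                 update_beta = update_beta, update_sigma2 = update_sigma2,
                 update_lambda = update_lambda, update_r = update_r,
                 lambda_start = lambda_start, r_start = r_start,
                 sigma2_start = sigma2_start, lambda_b_start = lambda_b_start,
                 verbose = verbose, report_every = as.integer(report_every)),
            class = "kmr_control")
}

# validate a groups argument: integer/character vector of length M with NA
# for ungrouped exposures; returns a list of index vectors (groups) plus the
# ungrouped singletons, or NULL when no grouping. (internal)
check_groups <- function(groups, M) {
  if (is.null(groups)) return(NULL)
  if (length(groups) != M)
    stop("groups must have one entry per exposure (length M)")
  lab <- as.character(groups)
  grouped <- which(!is.na(groups))
  if (!length(grouped)) return(NULL)
  idx <- split(grouped, lab[grouped])
  if (any(!lengths(idx)))
    stop("every declared group needs at least one exposure")
  list(groups = idx, singletons = which(is.na(groups)))
}

# inverse-gamma log-density (internal)
dinvgamma_log <- function(x, shape, rate) {
  shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x
}

# slab log-density (internal)
dslab_log <- function(r, priors) {
  if (priors$slab == "uniform")
    stats::dunif(r, 0, priors$slab_rmax, log = TRUE)
  else
    stats::dgamma(r, shape = priors$slab_shape, rate = priors$slab_rate, log = TRUE)
}

# Birth proposal for spike-and-slab moves: an equal mixture of the slab
# prior and two truncated exponentials (rates `birth_rate` and
# `birth_rate`/8 on (0, rmax)). The exponential components concentrate
# proposals over the short-to-moderate kernel length scales where
# posterior-relevant weights live on standardized exposures; the slab
# component keeps the reverse (death) move acceptable anywhere in the
# slab's support. (internal)
dbirth_log <- function(r, priors) {
  rmax <- if (priors$slab == "uniform") priors$slab_rmax else Inf
  dexp_trunc <- function(rate)
    ifelse(r > 0 & r < rmax,
           rate * exp(-rate * r) / (1 - exp(-rate * rmax)), 0)
  log(exp(dslab_log(r, priors)) / 3 +
      dexp_trunc(priors$birth_rate) / 3 +
      dexp_trunc(priors$birth_rate / 8) / 3)
}

rbirth <- function(priors) {
  rmax <- if (priors$slab == "uniform") priors$slab_rmax else Inf
  u <- stats::runif(1)
  if (u < 1 / 3) {
    if (priors$slab == "uniform") stats::runif(1, 0, rmax)
    else stats::rgamma(1, shape = priors$slab_shape, rate = priors$slab_rate)
  } else {
    rate <- if (u < 2 / 3) priors$birth_rate else priors$birth_rate / 8
    v <- stats::runif(1, 0, 1 - exp(-rate * rmax))
    -log(1 - v) / rate
  }
}

# joint log prior density of a parameter state, up to the constant from the
# flat beta prior. state: list(beta, sigma2, lam, r, delta, lam_b). (internal)
log_prior <- function(state, priors, groups = NULL) {
  if (any((state$r == 0) != (state$delta == 0)))
    stop("inconsistent state: r_m must be 0 exactly when delta_m = 0")
  lp <- 0
  if (!is.null(state$sigma2) && !isTRUE(attr(state$sigma2, "fixed")))
    lp <- lp + dinvgamma_log(state$sigma2, priors$sigma2_shape, priors$sigma2_rate)
  if (!is.null(state$lam))
    lp <- lp + stats::dgamma(state$lam, shape = priors$lambda_shape,
                             rate = priors$lambda_rate, log = TRUE)
  if (!is.null(state$lam_b))
    lp <- lp + stats::dgamma(state$lam_b, shape = priors$lambda_b_shape,
                             rate = priors$lambda_b_rate, log = TRUE)
  gi <- if (is.list(groups)) groups else check_groups(groups, length(state$r))
  comp <- function(m) {
    if (state$delta[m] == 1)
      log(priors$pi) + dslab_log(state$r[m], priors)
    else
      log(1 - priors$pi)
  }
  if (is.null(gi)) {
    lp <- lp + sum(vapply(seq_along(state$r), comp, 0))
  } else {
    for (g in gi$groups) {
      act <- g[state$delta[g] == 1]
      if (length(act) > 1)
        stop("hierarchical selection allows at most one active member per group")
      if (length(act) == 1)
        lp <- lp + log(priors$pi) - log(length(g)) + dslab_log(state$r[act], priors)
      else
        lp <- lp + log(1 - priors$pi)
    }
    lp <- lp + sum(vapply(gi$singletons, comp, 0))
  }
  lp
}

# evaluate code under a temporary RNG seed, restoring the caller's RNG state
# (internal)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
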