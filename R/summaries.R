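# Posterior summaries of the fitted exposure-response surface.

#' Posterior draws of the exposure-response surface
#'
#' Low-level workhorse behind [predict.kmreg()] and the effect estimands:
#' returns one row of h values per stored MCMC state at the requested
#' prediction points. For each state the marginalized model gives the
#' Gaussian conditional of `h(Znew)` given the working response, with
#' mean `lambda K_{new,n} V^{-1} (resp - X beta)` and covariance
#' `sigma^2 [lambda K_{new,new} - lambda^2 K_{new,n} V^{-1} K_{n,new}]`,
#' where `V = I + lambda K` (plus the cluster block term when a random
#' intercept is present). `mode = "full"` draws from this conditional
#' jointly across points; `mode = "mean"` returns the conditional mean
#' only. In GPP fits every kernel block is replaced by its knot
#' projection. Probit fits predict on the latent scale using each state's
#' stored latent response.
#'
#' @param fit a [kmreg] fit.
#' @param Znew matrix of exposure profiles on the original scale.
#' @param mode `"full"` or `"mean"`.
#' @param seed seed for the conditional draws; defaults to a value derived
#'   from the fit's seed so results are reproducible.
#' @param states optional subset of stored state indices.
#' @return matrix of h draws, states by prediction points.
#' @export
posterior_h_draws <- function(fit, Znew, mode = c("full", "mean"),
                              seed = NULL, states = NULL) {
  mode <- match.arg(mode)
  Znew <- as.matrix(Znew)
  if (ncol(Znew) != ncol(fit$data$Z))
    stop("Znew must have ", ncol(fit$data$Z), " exposure columns")
  Zs_new <- apply_standardize(Znew, fit$std$center, fit$std$scale)
  Zs <- fit$Zstd
  n <- nrow(Zs); p <- nrow(Zs_new); M <- ncol(Zs)
  sm <- fit$samples
  if (is.null(states)) states <- seq_len(fit$n_stored)
  gpp <- !is.null(fit$knots)
  if (gpp) {
    kn <- fit$knots; K <- nrow(kn)
    DU <- lapply(seq_len(M), function(m) outer(Zs[, m], kn[, m], "-")^2)
    DA <- lapply(seq_len(M), function(m) outer(kn[, m], kn[, m], "-")^2)
    DP <- lapply(seq_len(M), function(m) outer(Zs_new[, m], kn[, m], "-")^2)
  } else {
    Dtr <- lapply(seq_len(M), function(m) outer(Zs[, m], Zs[, m], "-")^2)
    Dc <- lapply(seq_len(M), function(m) outer(Zs[, m], Zs_new[, m], "-")^2)
    Dn <- lapply(seq_len(M), function(m) outer(Zs_new[, m], Zs_new[, m], "-")^2)
  }
  B <- NULL
  if (!is.null(fit$data$id)) {
    C <- matrix(0, n, max(fit$data$id))
    C[cbind(seq_len(n), fit$data$id)] <- 1
    B <- tcrossprod(C)
  }
  X <- fit$data$X; P <- ncol(X)
  probit <- fit$family == "binomial"
  wsum <- function(Dl, r) {
    S <- 0
    for (m in which(r > 0)) S <- S + r[m] * Dl[[m]]
    if (is.matrix(S)) S else matrix(0, nrow(Dl[[1]]), ncol(Dl[[1]]))
  }
  draws <- matrix(NA_real_, length(states), p)
  run <- function() {
    for (si in seq_along(states)) {
      s <- states[si]
      r <- sm$r[s, ]; lam <- sm$lam[s]; sigma2 <- sm$sigma2[s]
      resp <- if (probit) sm$ystar[s, ] else fit$data$y
      e <- if (P > 0) resp - drop(X %*% sm$beta[s, ]) else resp
      if (gpp) {
        A <- exp(-wsum(DA, r)) + fit$nugget * diag(K)
        RA <- chol_psd(A)
        Ptr <- t(backsolve(RA, t(exp(-wsum(DU, r))), transpose = TRUE))
        Pnew <- t(backsolve(RA, t(exp(-wsum(DP, r))), transpose = TRUE))
        Ktr <- tcrossprod(Ptr)
        Kc <- tcrossprod(Ptr, Pnew)          # n x p
        Kn <- tcrossprod(Pnew)
      } else {
        Ktr <- exp(-wsum(Dtr, r))
        Kc <- exp(-wsum(Dc, r))
        Kn <- exp(-wsum(Dn, r))
      }
      if (lam == 0) { draws[si, ] <- 0; next }
      V <- diag(n) + lam * Ktr
      if (!is.null(B)) V <- V + (sm$tau_b2[s] / sigma2) * B
      Rv <- chol_psd(V)
      sol <- backsolve(Rv, backsolve(Rv, cbind(e, Kc), transpose = TRUE))
      mu <- lam * drop(crossprod(Kc, sol[, 1]))
      if (mode == "mean") {
        draws[si, ] <- mu
      } else {
        Sigma_h <- sigma2 * (lam * Kn -
                             lam^2 * crossprod(Kc, sol[, -1, drop = FALSE]))
        Rh <- chol_psd((Sigma_h + t(Sigma_h)) / 2 + 1e-12 * diag(p))
        draws[si, ] <- mu + drop(crossprod(Rh, stats::rnorm(p)))
      }
    }
    draws
  }
  if (mode == "full") {
    if (is.null(seed)) seed <- fit$control$seed + 1L
    with_seed(seed, run())
  } else run()
}

# equal-tailed summary of a draws matrix, one row per column (internal)
summarize_draws <- function(draws, level = 0.95) {
  a <- (1 - level) / 2
  data.frame(mean = colMeans(draws),
             sd = apply(draws, 2, stats::sd),
             lower = apply(draws, 2, stats::quantile, a, type = 7),
             upper = apply(draws, 2, stats::quantile, 1 - a, type = 7))
}

# all-exposure quantile point on the original scale (internal; type-7)
quantile_point <- function(Z, q) apply(Z, 2, stats::quantile, q, type = 7)

# assemble a unique point matrix for a list of settings and return draws
# plus an index to look settings up (internal). Joint drawing across all
# points within each state means contrasts reuse common conditional draws.
contrast_draws <- function(fit, points, mode, seed) {
  pts <- unique(points)
  key <- apply(points, 1, paste, collapse = "\r")
  ukey <- apply(pts, 1, paste, collapse = "\r")
  idx <- match(key, ukey)
  draws <- posterior_h_draws(fit, pts, mode = mode, seed = seed)
  list(draws = draws, idx = idx)
}

#' Posterior inclusion probabilities
#'
#' For a component-wise variable-selection fit, the PIP of exposure m is
#' the posterior frequency of `delta_m = 1`. For a hierarchical fit, the
#' group PIP is the posterior probability that any member of the group is
#' active, and within-group conditional PIPs (which sum to 1 inside each
#' group) give the probability that each member is the active one given
#' the group is selected.
#'
#' @param fit a [kmreg] fit with `varsel = TRUE`.
#' @return data.frame with columns `exposure` and `pip`, plus `group` and
#'   `cond_pip` for hierarchical fits (ungrouped exposures have `group` NA
#'   and `cond_pip` equal to `pip`).
#' @export
extract_pips <- function(fit) {
  stopifnot(inherits(fit, "kmreg"))
  if (!fit$varsel)
    stop("PIPs undefined without variable selection (varsel = FALSE)")
  delta <- fit$samples$delta
  expo <- colnames(delta)
  if (is.null(fit$groups)) {
    return(data.frame(exposure = expo, pip = colMeans(delta)))
  }
  gi <- check_groups(fit$groups, ncol(delta))
  out <- data.frame(exposure = expo, group = as.character(fit$groups),
                    pip = NA_real_, cond_pip = NA_real_)
  for (gname in names(gi$groups)) {
    g <- gi$groups[[gname]]
    active <- rowSums(delta[, g, drop = FALSE]) > 0
    gp <- mean(active)
    out$pip[g] <- gp
    out$cond_pip[g] <- if (any(active))
      colMeans(delta[active, g, drop = FALSE]) else NA_real_
  }
  for (m in gi$singletons) {
    out$pip[m] <- mean(delta[, m])
    out$cond_pip[m] <- out$pip[m]
  }
  out
}

#' Predict the exposure-response surface at new points
#'
#' Computes the posterior of `h` at new exposure profiles from the stored
#' MCMC states, either drawing from the full Gaussian conditional per state
#' (`mode = "full"`) or using the per-state conditional mean only
#' (`mode = "mean"`, faster, narrower intervals; the mode is recorded on
#' the result). For probit fits `h` is on the latent scale;
#' `type = "prob"` additionally applies `pnorm(h + x'beta)` and requires
#' `Xnew`.
#'
#' @param object a [kmreg] fit.
#' @param Znew matrix of exposure profiles on the original scale
#'   (default: the training exposures).
#' @param Xnew covariate values (single row or one per prediction point);
#'   needed for `type = "prob"`.
#' @param type `"h"` (latent/outcome scale surface) or `"prob"`
#'   (probability scale, probit fits only).
#' @param mode `"full"` or `"mean"` posterior prediction.
#' @param seed seed for the conditional draws (default derived from the
#'   fit's seed, so repeated calls are reproducible).
#' @param draws return the draw matrix as attribute `"draws"`.
#' @param ... unused.
#' @return data.frame with `est`, `sd`, `lower`, `upper` (95% equal-tailed
#'   credible bounds), one row per prediction point.
#' @export
predict.kmreg <- function(object, Znew = NULL, Xnew = NULL,
                          type = c("h", "prob"), mode = c("full", "mean"),
                          seed = NULL, draws = FALSE, ...) {
  type <- match.arg(type); mode <- match.arg(mode)
  if (is.null(Znew)) Znew <- object$data$Z
  Znew <- as.matrix(Znew)
  if (type == "prob") {
    dm <- predict_probability(object, Znew, Xnew, mode = mode, seed = seed)
  } else {
    dm <- posterior_h_draws(object, Znew, mode = mode, seed = seed)
  }
  out <- summarize_draws(dm)
  names(out)[1] <- "est"
  attr(out, "mode") <- mode
  if (draws) attr(out, "draws") <- dm
  out
}

#' Univariate cross-section of the exposure-response function
#'
#' Varies a single exposure over a grid while fixing every other exposure
#' at its empirical quantile `q_fix` (median by default), and summarizes the
#' posterior of `h` pointwise with 95% credible bands.
#'
#' @param fit a [kmreg] fit.
#' @param m exposure index (or name) to vary.
#' @param grid grid of values on the original exposure scale (default: 50
#'   equally spaced points over the observed range). Values outside the
#'   observed range trigger an extrapolation warning.
#' @param q_fix quantile at which the remaining exposures are fixed.
#' @param ngrid grid size when `grid` is not supplied.
#' @param mode,seed passed to the posterior predictor.
#' @return data.frame with columns `z`, `est`, `sd`, `lower`, `upper`.
#' @export
univariate_cross_section <- function(fit, m, grid = NULL, q_fix = 0.5,
                                     ngrid = 50, mode = c("full", "mean"),
                                     seed = NULL) {
  mode <- match.arg(mode)
  Z <- fit$data$Z
  if (is.character(m)) m <- match(m, colnames(Z))
  rng <- range(Z[, m])
  if (is.null(grid)) grid <- seq(rng[1], rng[2], length.out = ngrid)
  if (any(grid < rng[1] | grid > rng[2]))
    warning("grid extends beyond the observed range of exposure ", m,
            "; extrapolating")
  base <- quantile_point(Z, q_fix)
  pts <- matrix(rep(base, each = length(grid)), nrow = length(grid))
  pts[, m] <- grid
  colnames(pts) <- colnames(Z)
  dm <- posterior_h_draws(fit, pts, mode = mode, seed = seed)
  cbind(data.frame(z = grid), summarize_draws(dm) |>
          stats::setNames(c("est", "sd", "lower", "upper")))
}

#' Bivariate cross-section of the exposure-response function
#'
#' Posterior-mean surface of `h` over a grid of two exposures, optionally
#' repeated with a third exposure fixed at several quantiles (all other
#' exposures at their `q_fix` quantile). Differences in surface shape
#' across the third exposure's panels indicate three-way interaction.
#'
#' @param fit a [kmreg] fit.
#' @param m1,m2 indices (or names) of the two exposures to vary.
#' @param m3 optional index of a third, conditioning exposure.
#' @param q3 quantiles of exposure `m3` defining the panels.
#' @param ngrid grid size per axis.
#' @param q_fix quantile for the remaining exposures.
#' @param seed passed to the posterior predictor.
#' @return long data.frame with columns `z1`, `z2`, `q3`, `est`.
#' @export
bivariate_cross_section <- function(fit, m1, m2, m3 = NULL,
                                    q3 = c(0.1, 0.5, 0.9), ngrid = 15,
                                    q_fix = 0.5, seed = NULL) {
  Z <- fit$data$Z
  if (is.character(m1)) m1 <- match(m1, colnames(Z))
  if (is.character(m2)) m2 <- match(m2, colnames(Z))
  if (is.character(m3)) m3 <- match(m3, colnames(Z))
  ids <- c(m1, m2, m3)
  if (anyDuplicated(ids)) stop("m1, m2 and m3 must be distinct exposures")
  g1 <- seq(min(Z[, m1]), max(Z[, m1]), length.out = ngrid)
  g2 <- seq(min(Z[, m2]), max(Z[, m2]), length.out = ngrid)
  base <- quantile_point(Z, q_fix)
  if (is.null(m3)) q3 <- NA_real_
  out <- NULL
  for (q in q3) {
    pts <- matrix(rep(base, each = ngrid^2), nrow = ngrid^2)
    pts[, m1] <- rep(g1, times = ngrid)
    pts[, m2] <- rep(g2, each = ngrid)
    if (!is.na(q)) pts[, m3] <- stats::quantile(Z[, m3], q, type = 7)
    dm <- posterior_h_draws(fit, pts, mode = "mean")
    out <- rbind(out, data.frame(z1 = pts[, m1], z2 = pts[, m2], q3 = q,
                                 est = colMeans(dm)))
  }
  out
}

#' Overall effect of the mixture
#'
#' Posterior summary of `h` with every exposure fixed at quantile `q`
#' versus every exposure fixed at quantile `q_ref`, covariates held
#' constant: the overall mixture effect `Delta_tot(q_ref, q)`.
#'
#' @param fit a [kmreg] fit.
#' @param q vector of comparison quantiles.
#' @param q_ref reference quantile (scalar).
#' @param mode,seed passed to the posterior predictor.
#' @return data.frame with one row per `q`: `q`, `q_ref`, `mean`, `sd`,
#'   `lower`, `upper` (95% equal-tailed interval).
#' @export
overall_effect <- function(fit, q = seq(0.25, 0.75, by = 0.05), q_ref = 0.5,
                           mode = c("full", "mean"), seed = NULL) {
  mode <- match.arg(mode)
  Z <- fit$data$Z
  pts <- rbind(t(vapply(q, function(qq) quantile_point(Z, qq),
                        numeric(ncol(Z)))),
               quantile_point(Z, q_ref))
  cd <- contrast_draws(fit, pts, mode, seed)
  ref <- cd$draws[, cd$idx[length(q) + 1]]
  contr <- cd$draws[, cd$idx[seq_along(q)], drop = FALSE] - ref
  cbind(data.frame(q = q, q_ref = q_ref), summarize_draws(contr))
}

# draws of single-exposure contrasts for one conditioning quantile set
# (internal): returns S x M matrix of Delta_m(q1, q2 | q_fix) draws
single_effect_draws <- function(fit, q_fix, q1, q2, mode, seed) {
  Z <- fit$data$Z; M <- ncol(Z)
  base <- quantile_point(Z, q_fix)
  pts <- NULL
  for (m in seq_len(M)) {
    lo <- base; lo[m] <- stats::quantile(Z[, m], q1, type = 7)
    hi <- base; hi[m] <- stats::quantile(Z[, m], q2, type = 7)
    pts <- rbind(pts, hi, lo)
  }
  cd <- contrast_draws(fit, pts, mode, seed)
  hi_idx <- cd$idx[seq(1, 2 * M, by = 2)]
  lo_idx <- cd$idx[seq(2, 2 * M, by = 2)]
  cd$draws[, hi_idx, drop = FALSE] - cd$draws[, lo_idx, drop = FALSE]
}

#' Single-exposure effects
#'
#' For each exposure m, the change in `h` when exposure m moves from its
#' `q1` to its `q2` quantile while all other exposures are fixed at their
#' `q_fix` quantile: `Delta_m(q1, q2 | q_fix)`. Comparing the estimates
#' across conditioning quantiles reveals interaction with co-exposures.
#'
#' @param fit a [kmreg] fit.
#' @param q_fix conditioning quantiles for the other exposures.
#' @param q1,q2 quantiles defining the contrast for the moving exposure.
#' @param mode,seed passed to the posterior predictor.
#' @return data.frame with one row per (exposure, q_fix): `exposure`,
#'   `q_fix`, `mean`, `sd`, `lower`, `upper`.
#' @export
single_exposure_effects <- function(fit, q_fix = c(0.25, 0.5, 0.75),
                                    q1 = 0.25, q2 = 0.75,
                                    mode = c("full", "mean"), seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(seed)) seed <- fit$control$seed + 1L
  M <- ncol(fit$data$Z)
  out <- NULL
  for (i in seq_along(q_fix)) {
    dm <- single_effect_draws(fit, q_fix[i], q1, q2, mode, seed + i)
    out <- rbind(out, cbind(data.frame(exposure = colnames(fit$data$Z),
                                       q_fix = q_fix[i]),
                            summarize_draws(dm)))
  }
  rownames(out) <- NULL
  out
}

#' Interactive effects
#'
#' The difference of single-exposure effects at two conditioning levels of
#' all other exposures, `Delta_m(q1, q2 | q_high) - Delta_m(q1, q2 | q_low)`,
#' computed draw-by-draw from a common set of posterior h draws. Values away
#' from 0 indicate that exposure m's effect depends on co-exposure levels.
#'
#' @param fit a [kmreg] fit.
#' @param q1,q2 contrast quantiles for the moving exposure.
#' @param q_low,q_high conditioning quantiles being compared.
#' @param mode,seed passed to the posterior predictor.
#' @return data.frame with one row per exposure.
#' @export
interactive_effects <- function(fit, q1 = 0.25, q2 = 0.75,
                                q_low = 0.25, q_high = 0.75,
                                mode = c("full", "mean"), seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(seed)) seed <- fit$control$seed + 1L
  d_hi <- single_effect_draws(fit, q_high, q1, q2, mode, seed + 1L)
  d_lo <- single_effect_draws(fit, q_low, q1, q2, mode, seed + 2L)
  cbind(data.frame(exposure = colnames(fit$data$Z)),
        summarize_draws(d_hi - d_lo))
}

#' Posterior draws of outcome probabilities (probit fits)
#'
#' For each stored state, `P(Y = 1) = pnorm(h(z) + x'beta)` using
#' latent-scale draws of h.
#'
#' @param fit a probit-family [kmreg] fit.
#' @param Znew exposure profiles (original scale).
#' @param Xnew covariate values: one row, or one row per profile.
#' @param mode,seed passed to the posterior predictor.
#' @return matrix of probability draws, states by prediction points.
#' @export
predict_probability <- function(fit, Znew, Xnew = NULL,
                                mode = c("full", "mean"), seed = NULL) {
  mode <- match.arg(mode)
  if (fit$family != "binomial")
    stop("predict_probability requires a probit (binomial) fit")
  Znew <- as.matrix(Znew)
  P <- ncol(fit$data$X)
  h <- posterior_h_draws(fit, Znew, mode = mode, seed = seed)
  if (P > 0) {
    if (is.null(Xnew)) stop("Xnew required for probability-scale prediction")
    Xnew <- matrix(as.numeric(Xnew), ncol = P)
    if (nrow(Xnew) == 1 && nrow(Znew) > 1)
      Xnew <- Xnew[rep(1, nrow(Znew)), , drop = FALSE]
    xb <- fit$samples$beta %*% t(Xnew)   # S x p
    h <- h + xb
  }
  stats::pnorm(h)
}

#' Risk difference between two exposure settings (probit fits)
#'
#' Posterior of `P(Y = 1 | z_A, x) - P(Y = 1 | z_B, x)`, where setting A
#' fixes exposure `m` at quantile `q2` and setting B at `q1`, with all
#' other exposures at their `q_others` quantile, reported at each requested
#' covariate quantile.
#'
#' @param fit a probit-family [kmreg] fit.
#' @param m exposure index (or name) being contrasted.
#' @param q1,q2 quantiles of exposure `m` being compared (B vs A).
#' @param q_others quantile fixing the remaining exposures.
#' @param x_q quantiles of each covariate at which to report.
#' @param mode,seed passed to the posterior predictor.
#' @return data.frame with one row per covariate quantile: `x_q`, `mean`,
#'   `sd`, `lower`, `upper`; differences lie in \[-1, 1\].
#' @export
risk_difference <- function(fit, m, q1 = 0.5, q2 = 0.75, q_others = 0.5,
                            x_q = c(0.25, 0.75), mode = c("full", "mean"),
                            seed = NULL) {
  mode <- match.arg(mode)
  if (fit$family != "binomial")
    stop("risk_difference requires a probit (binomial) fit")
  Z <- fit$data$Z
  if (is.character(m)) m <- match(m, colnames(Z))
  A <- quantile_point(Z, q_others); A[m] <- stats::quantile(Z[, m], q2, type = 7)
  B <- quantile_point(Z, q_others); B[m] <- stats::quantile(Z[, m], q1, type = 7)
  if (is.null(seed)) seed <- fit$control$seed + 1L
  cd <- contrast_draws(fit, rbind(A, B), mode, seed)
  hA <- cd$draws[, cd$idx[1]]; hB <- cd$draws[, cd$idx[2]]
  P <- ncol(fit$data$X)
  out <- NULL
  for (xq in x_q) {
    xb <- if (P > 0)
      drop(fit$samples$beta %*% apply(fit$data$X, 2, stats::quantile, xq, type = 7))
    else 0
    rd <- stats::pnorm(hA + xb) - stats::pnorm(hB + xb)
    out <- rbind(out, cbind(data.frame(x_q = xq),
                            summarize_draws(matrix(rd, ncol = 1))))
  }
  rownames(out) <- NULL
  out
}

#' Convert probit coefficients to the logit scale
#'
#' Uses the standard approximation `logit(mu) ~ 1.6 * qnorm(mu)`, so that a
#' probit coefficient maps to `1.6 * beta` on the logit scale and
#' `exp(1.6 * beta)` as an odds ratio. The approximation is reliable only
#' when the outcome probability given the included predictors is not too
#' close to 0 or 1.
#'
#' @param beta_probit numeric vector of probit-scale coefficients.
#' @return data.frame with `beta_probit`, `beta_logit`, `odds_ratio`.
#' @examples
#' probit_to_logit(1)  # beta_logit 1.6, OR exp(1.6)
#' @export
probit_to_logit <- function(beta_probit) {
  stopifnot(is.numeric(beta_probit), all(is.finite(beta_probit)))
  data.frame(beta_probit = beta_probit,
             beta_logit = 1.6 * beta_probit,
             odds_ratio = exp(1.6 * beta_probit))
}

#' Parameter count of a saturated basis-expansion model
#'
#' Number of regression parameters needed to model M exposures with a
#' DF-degree-of-freedom basis per exposure plus all interactions among
#' basis functions: `(1 + DF)^M - 1`. The explosive growth of this count
#' is the motivation for regularizing the exposure-response surface with a
#' kernel instead.
#'
#' @param M number of exposures (positive integer).
#' @param DF degrees of freedom per exposure (positive integer).
#' @return integer-valued count.
#' @examples
#' saturated_model_parameter_count(4, 3)  # 255
#' saturated_model_parameter_count(5, 3)  # 1023
#' @export
saturated_model_parameter_count <- function(M, DF) {
  if (length(M) != 1 || length(DF) != 1 || M < 1 || DF < 1 ||
      M != round(M) || DF != round(DF))
    stop("M and DF must be positive integers")
  (1 + DF)^M - 1
}
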