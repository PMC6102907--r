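# Synthetic mixture datasets with known truth, for validation and
# parameter-recovery testing.

#' Build an exposure-response function from named terms
#'
#' Composes `h(z)` as a sum of named components so the truth can be
#' evaluated exactly at arbitrary points. Available types:
#' `linear` (`a * z_m`), `quadratic` (`a * (z_m^2 - 1)`, centered so the
#' term has mean 0 for standard-normal exposures), `plateau`
#' (`a * (2 * plogis(b * z_m) - 1)`, a saturating sigmoid), and `product`
#' (`a * z_m1 * z_m2`).
#'
#' @param terms list of term descriptors, each a list with `type`, `var`
#'   (or `vars` for `product`), coefficient `a`, and optional steepness `b`
#'   for `plateau`.
#' @return function mapping an n-by-M matrix to a length-n vector; the
#'   term list is attached as attribute `"terms"`.
#' @export
kmr_h_terms <- function(terms) {
  f <- function(Z) {
    Z <- as.matrix(Z)
    out <- numeric(nrow(Z))
    for (tm in terms) {
      out <- out + switch(tm$type,
        linear = tm$a * Z[, tm$var],
        quadratic = tm$a * (Z[, tm$var]^2 - 1),
        plateau = {
          b <- if (is.null(tm$b)) 2 else tm$b
          tm$a * (2 * stats::plogis(b * Z[, tm$var]) - 1)
        },
        product = tm$a * Z[, tm$vars[1]] * Z[, tm$vars[2]],
        stop("unknown term type: ", tm$type))
    }
    out
  }
  attr(f, "terms") <- terms
  f
}

# default truth for the continuous generator: 5 of 7 exposures active
# (z3, z6 inert), a saturating term in z7, positive linear terms in z1/z2,
# negative in z4/z5, and a z5 x z7 product interaction (internal)
default_continuous_terms <- function() {
  list(list(type = "plateau", var = 7, a = 1.5, b = 2),
       list(type = "linear", var = 1, a = 0.6),
       list(type = "linear", var = 2, a = 0.5),
       list(type = "linear", var = 4, a = -0.5),
       list(type = "linear", var = 5, a = -0.6),
       list(type = "product", vars = c(5, 7), a = -0.4))
}

# default truth for the binary generator: quadratic terms in z1..z4 and a
# z1 x z2 interaction (internal)
default_binary_terms <- function() {
  list(list(type = "quadratic", var = 1, a = 1.0),
       list(type = "quadratic", var = 2, a = 0.8),
       list(type = "quadratic", var = 3, a = 0.6),
       list(type = "quadratic", var = 4, a = 0.6),
       list(type = "product", vars = c(1, 2), a = 0.5))
}

# exchangeable correlation matrix with optional highly correlated pairs
# (internal)
build_corr <- function(M, rho, hi_pairs = NULL, hi_rho = 0.9) {
  Sig <- matrix(rho, M, M); diag(Sig) <- 1
  if (!is.null(hi_pairs)) {
    hi_pairs <- matrix(hi_pairs, ncol = 2)
    for (k in seq_len(nrow(hi_pairs))) {
      i <- hi_pairs[k, 1]; j <- hi_pairs[k, 2]
      Sig[i, j] <- Sig[j, i] <- hi_rho
    }
  }
  ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("correlation matrix is not positive definite")
  Sig
}

# simulate correlated standard-normal exposures (internal)
sim_exposures <- function(n, M, rho, hi_pairs, hi_rho) {
  Sig <- build_corr(M, rho, hi_pairs, hi_rho)
  Z <- matrix(stats::rnorm(n * M), n, M) %*% chol(Sig)
  colnames(Z) <- paste0("z", seq_len(M))
  Z
}

# active exposure indices implied by a term list (internal)
terms_active <- function(terms) {
  sort(unique(unlist(lapply(terms, function(tm)
    if (tm$type == "product") tm$vars else tm$var))))
}

#' Simulate a continuous-outcome mixture dataset
#'
#' Emulates a mixtures study with correlated exposures, a single covariate,
#' and a nonlinear, non-additive exposure-response function:
#' `y = h(Z) + beta * x + N(0, sd^2)`. The default dimensions are 7
#' exposures in 500 individuals with 5 active exposures (z3 and z6 inert);
#' the default truth combines a saturating term, positive and negative
#' linear terms, and a product interaction.
#'
#' @param n,M sample size and number of exposures.
#' @param rho exchangeable exposure correlation.
#' @param hi_pairs optional 2-column matrix (or length-2 vector) of exposure
#'   index pairs given correlation `hi_rho` (for grouped-selection demos).
#' @param hi_rho correlation for `hi_pairs`.
#' @param terms truth term list for [kmr_h_terms()] (default as above;
#'   terms must reference exposures `<= M`).
#' @param beta covariate coefficient (covariate is standard normal).
#' @param sd residual standard deviation.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments including the seed.
#' @return list with `data` (a [kmr_data] object) and `truth` (class
#'   `kmr_truth`: the evaluable `h_fun`, term list, active set, `beta`,
#'   `sd`, the realized `h`, and the simulated `Z`/`X` for empirical
#'   quantiles).
#' @export
kmr_sim_continuous <- function(n = 500, M = 7, rho = 0.3, hi_pairs = NULL,
                               hi_rho = 0.9, terms = NULL, beta = 1,
                               sd = 1, seed) {
  if (missing(seed)) stop("seed is required")
  if (is.null(terms)) {
    terms <- if (M >= 7) default_continuous_terms()
             else list(list(type = "linear", var = 1, a = 1))
  }
  if (max(terms_active(terms)) > M) stop("truth terms reference exposures > M")
  h_fun <- kmr_h_terms(terms)
  with_seed(seed, {
    Z <- sim_exposures(n, M, rho, hi_pairs, hi_rho)
    x <- matrix(stats::rnorm(n), ncol = 1, dimnames = list(NULL, "x"))
    h <- h_fun(Z)
    y <- h + beta * x[, 1] + sd * stats::rnorm(n)
    truth <- structure(list(h_fun = h_fun, terms = terms,
                            active = terms_active(terms), beta = beta,
                            sd = sd, h = h, Z = Z, X = x,
                            family = "gaussian", seed = seed),
                       class = "kmr_truth")
    list(data = kmr_data(outcome = y, exposures = Z, covariates = x,
                         family = "gaussian"),
         truth = truth)
  })
}

#' Simulate a binary-outcome (probit) mixture dataset
#'
#' Latent-variable probit generator: `y* = h(Z) + beta * x + N(0, 1)`,
#' `y = 1(y* > 0)`. Defaults emulate a larger mixture with 30 independent
#' exposures in 200 individuals whose outcome depends on quadratic terms of
#' four exposures and a linear interaction between two of these.
#'
#' @inheritParams kmr_sim_continuous
#' @return list with `data` and `truth` as in [kmr_sim_continuous()]; the
#'   truth record's `h_fun` is on the latent scale, so true outcome
#'   probabilities are `pnorm(h_fun(z) + beta * x)` exactly.
#' @export
kmr_sim_binary <- function(n = 200, M = 30, rho = 0, hi_pairs = NULL,
                           hi_rho = 0.9, terms = NULL, beta = 0.5, seed) {
  if (missing(seed)) stop("seed is required")
  if (is.null(terms)) {
    terms <- if (M >= 4) default_binary_terms()
             else list(list(type = "quadratic", var = 1, a = 1))
  }
  if (max(terms_active(terms)) > M) stop("truth terms reference exposures > M")
  h_fun <- kmr_h_terms(terms)
  with_seed(seed, {
    Z <- sim_exposures(n, M, rho, hi_pairs, hi_rho)
    x <- matrix(stats::rnorm(n), ncol = 1, dimnames = list(NULL, "x"))
    h <- h_fun(Z)
    ystar <- h + beta * x[, 1] + stats::rnorm(n)
    y <- as.numeric(ystar > 0)
    if (all(y == 0) || all(y == 1))
      stop("degenerate binary outcome (all ", y[1],
           "); rescale the truth coefficients")
    truth <- structure(list(h_fun = h_fun, terms = terms,
                            active = terms_active(terms), beta = beta,
                            sd = 1, h = h, Z = Z, X = x,
                            family = "binomial", seed = seed),
                       class = "kmr_truth")
    list(data = kmr_data(outcome = y, exposures = Z, covariates = x,
                         family = "binomial"),
         truth = truth)
  })
}

#' Simulate a clustered continuous-outcome dataset
#'
#' Adds a cluster-level random intercept `b_i ~ N(0, tau_b^2)` to the
#' continuous generator: `y_ij = h(z_ij) + b_i + beta * x_ij + eps_ij`.
#' With `tau_b = 0` the output equals [kmr_sim_continuous()] under the
#' same seed.
#'
#' @param n_clusters number of clusters (>= 2).
#' @param cluster_size observations per cluster.
#' @param tau_b random-intercept standard deviation.
#' @inheritParams kmr_sim_continuous
#' @return list with `data` (including cluster `id`) and `truth` (which
#'   additionally records `b` and `tau_b`).
#' @export
kmr_sim_clustered <- function(n_clusters = 10, cluster_size = 20, tau_b = 1,
                              M = 7, rho = 0.3, terms = NULL, beta = 1,
                              sd = 1, seed) {
  if (missing(seed)) stop("seed is required")
  if (n_clusters < 2) stop("need at least 2 clusters")
  n <- n_clusters * cluster_size
  base <- kmr_sim_continuous(n = n, M = M, rho = rho, terms = terms,
                             beta = beta, sd = sd, seed = seed)
  id <- rep(seq_len(n_clusters), each = cluster_size)
  b <- with_seed(seed + 1L, tau_b * stats::rnorm(n_clusters))
  y <- base$data$y + b[id]
  truth <- base$truth
  truth$b <- b; truth$tau_b <- tau_b; truth$id <- id
  list(data = kmr_data(outcome = y, exposures = base$data$Z,
                       covariates = base$data$X, id = id,
                       family = "gaussian"),
       truth = truth)
}

#' True effect estimands from a truth record
#'
#' Evaluates the estimands reported by [overall_effect()],
#' [single_exposure_effects()], [interactive_effects()] and (for probit
#' truths) [risk_difference()] exactly under the generator's `h_fun`,
#' using the empirical type-7 quantiles of the simulated exposures — the
#' same convention the estimators use. Probit risk differences use the
#' closed form `pnorm(h + beta * x)` implied by the latent-normal model.
#'
#' @param truth a `kmr_truth` record from a generator.
#' @param q1,q2 contrast quantiles (defaults 0.25, 0.75).
#' @param q_fix conditioning quantiles for single-exposure effects.
#' @param rd_m exposure index for the risk difference (probit truths).
#' @param rd_q the two quantiles of exposure `rd_m` compared (B vs A).
#' @param x_q covariate quantiles at which risk differences are evaluated.
#' @return list with data.frames `overall`, `single`, `interactive` and
#'   (probit) `rd`, mirroring the estimator outputs with column `truth`.
#' @export
true_contrasts <- function(truth, q1 = 0.25, q2 = 0.75,
                           q_fix = c(0.25, 0.5, 0.75),
                           rd_m = 2, rd_q = c(0.5, 0.75),
                           x_q = c(0.25, 0.75)) {
  stopifnot(inherits(truth, "kmr_truth"))
  Z <- truth$Z; M <- ncol(Z); h <- truth$h_fun
  qp <- function(q) quantile_point(Z, q)
  overall <- data.frame(q = q2, q_ref = q1,
                        truth = h(rbind(qp(q2))) - h(rbind(qp(q1))))
  single_one <- function(m, qf) {
    lo <- qp(qf); hi <- qp(qf)
    lo[m] <- stats::quantile(Z[, m], q1, type = 7)
    hi[m] <- stats::quantile(Z[, m], q2, type = 7)
    h(rbind(hi)) - h(rbind(lo))
  }
  single <- do.call(rbind, lapply(q_fix, function(qf)
    data.frame(exposure = colnames(Z), q_fix = qf,
               truth = vapply(seq_len(M), single_one, 0, qf = qf))))
  interactive <- data.frame(
    exposure = colnames(Z),
    truth = vapply(seq_len(M), function(m)
      single_one(m, 0.75) - single_one(m, 0.25), 0))
  out <- list(overall = overall, single = single, interactive = interactive)
  if (truth$family == "binomial") {
    A <- qp(0.5); A[rd_m] <- stats::quantile(Z[, rd_m], rd_q[2], type = 7)
    B <- qp(0.5); B[rd_m] <- stats::quantile(Z[, rd_m], rd_q[1], type = 7)
    out$rd <- do.call(rbind, lapply(x_q, function(xq) {
      xv <- stats::quantile(truth$X[, 1], xq, type = 7)
      data.frame(x_q = xq,
                 truth = stats::pnorm(h(rbind(A)) + truth$beta * xv) -
                         stats::pnorm(h(rbind(B)) + truth$beta * xv))
    }))
  }
  out
}
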