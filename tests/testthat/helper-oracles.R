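# Independent oracles used across the suite. These deliberately use naive
# dense algebra (double loops, solve(), determinant()) rather than the
# package's optimized code paths.

# entry-by-entry Gaussian kernel
brute_kernel <- function(Z1, Z2, r) {
  Z1 <- as.matrix(Z1); Z2 <- as.matrix(Z2)
  K <- matrix(NA_real_, nrow(Z1), nrow(Z2))
  for (i in seq_len(nrow(Z1)))
    for (j in seq_len(nrow(Z2)))
      K[i, j] <- exp(-sum(r * (Z1[i, ] - Z2[j, ])^2))
  K
}

# dense multivariate-normal log-density via solve()/determinant()
dense_mvn_logpdf <- function(x, mu, Sigma) {
  n <- length(x)
  e <- x - mu
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld + drop(t(e) %*% solve(Sigma, e)))
}

# Brute-force sampler for the Gaussian model with the surface values h
# sampled explicitly (conjugate Gibbs), at fixed kernel weights r and
# fixed variance ratio lam. Priors match the package defaults:
# beta flat, sigma2 ~ IG(a0, b0), h | sigma2 ~ N(0, lam * sigma2 * K).
explicit_h_sampler <- function(y, Z, X, lam, r, n_iter, seed,
                               a0 = 0.001, b0 = 0.001) {
  set.seed(seed)
  n <- length(y); P <- ncol(X)
  K <- brute_kernel(Z, Z, r) + 1e-8 * diag(n)
  Kinv <- solve(K)
  beta <- if (P) drop(qr.solve(X, y)) else numeric(0)
  sigma2 <- stats::var(y)
  h <- rep(0, n)
  A <- solve(diag(n) + Kinv / lam)      # posterior cov of h = sigma2 * A
  XtXinv <- if (P) solve(crossprod(X)) else NULL
  h_draws <- matrix(NA_real_, n_iter, n)
  for (it in seq_len(n_iter)) {
    resid0 <- if (P) y - drop(X %*% beta) else y
    mu_h <- drop(A %*% resid0)
    h <- mu_h + drop(crossprod(chol(sigma2 * A + 1e-12 * diag(n)),
                               rnorm(n)))
    if (P) {
      mb <- drop(XtXinv %*% crossprod(X, y - h))
      beta <- mb + drop(crossprod(chol(sigma2 * XtXinv), rnorm(P)))
    }
    e <- y - h - (if (P) drop(X %*% beta) else 0)
    rate <- b0 + 0.5 * (sum(e^2) + drop(t(h) %*% Kinv %*% h) / lam)
    sigma2 <- 1 / rgamma(1, shape = a0 + n, rate = rate)
    h_draws[it, ] <- h
  }
  h_draws
}

# construct a kmreg-shaped object holding externally chosen states, for
# testing the posterior summary layer in isolation
fake_fit <- function(y, Z, X = NULL, family = "gaussian",
                     beta = NULL, sigma2 = 1, lam = 1, r = NULL,
                     S = 1, ystar = NULL, delta = NULL) {
  dat <- kmr_data(outcome = y, exposures = Z, covariates = X, family = family)
  P <- ncol(dat$X); M <- ncol(dat$Z)
  if (is.null(r)) r <- rep(0.5, M)
  rep_row <- function(v) matrix(rep(v, each = S), nrow = S)
  samples <- list(
    beta = if (P) {
      b <- rep_row(beta); colnames(b) <- colnames(dat$X); b
    } else matrix(numeric(0), S, 0),
    sigma2 = rep(sigma2, S), lam = rep(lam, S),
    r = rep_row(r),
    delta = if (is.null(delta)) rep_row(as.integer(r > 0)) else delta,
    tau_b2 = NULL,
    ystar = if (!is.null(ystar)) rep_row(ystar) else NULL,
    loglik = rep(0, S))
  colnames(samples$r) <- colnames(dat$Z)
  colnames(samples$delta) <- colnames(dat$Z)
  structure(list(samples = samples,
                 acceptance = list(lambda = NA_real_, r = rep(NA_real_, 4)),
                 data = dat, Zstd = dat$Z,
                 std = list(center = stats::setNames(rep(0, M), colnames(dat$Z)),
                            scale = stats::setNames(rep(1, M), colnames(dat$Z)),
                            standardize = FALSE),
                 knots = NULL, nugget = 1e-6, family = family,
                 varsel = TRUE, groups = NULL, priors = kmr_priors(),
                 control = kmr_control(n_iter = 2, seed = 1),
                 n_stored = S, call = NULL, time = NA_real_),
            class = "kmreg")
}
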