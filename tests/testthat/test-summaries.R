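# The posterior-summary layer: PIPs, h prediction, cross-sections, and
# effect estimands.

test_that("component-wise PIPs are posterior selection frequencies", {
  y <- rnorm(10); Z <- matrix(rnorm(30), 10, 3)
  delta <- cbind(z1 = rep(1L, 10), z2 = rep(0L, 10),
                 z3 = rep(c(1L, 0L), 5))
  fit <- fake_fit(y, Z, S = 10, delta = delta)
  pips <- extract_pips(fit)
  expect_equal(pips$pip, c(1, 0, 0.5), ignore_attr = TRUE)
  fit$varsel <- FALSE
  expect_error(extract_pips(fit), "without variable selection")
})

test_that("hierarchical PIPs follow the counting definition", {
  y <- rnorm(8); Z <- matrix(rnorm(8 * 3), 8, 3)
  S <- 100
  # group {z1, z2} active in 40 states; z1 the active member in 30 of those
  d1 <- c(rep(1L, 30), rep(0L, 70))
  d2 <- c(rep(0L, 30), rep(1L, 10), rep(0L, 60))
  d3 <- rbinom(S, 1, 0.2)
  delta <- cbind(z1 = d1, z2 = d2, z3 = d3)
  fit <- fake_fit(y, Z, S = S, delta = delta)
  fit$groups <- c("g", "g", NA)
  pips <- extract_pips(fit)
  expect_equal(pips$pip[1:2], c(0.4, 0.4))
  expect_equal(pips$cond_pip[1:2], c(0.75, 0.25))
  expect_equal(sum(pips$cond_pip[1:2]), 1)
  expect_equal(pips$pip[3], mean(d3))
})

test_that("h prediction matches the dense GP-conditional oracle", {
  set.seed(31)
  n <- 10
  Z <- matrix(rnorm(n * 2), n, 2)
  X <- matrix(rnorm(n), n, 1)
  y <- rnorm(n)
  st <- list(beta = 0.7, sigma2 = 0.8, lam = 1.3, r = c(0.5, 0.9))
  fit <- fake_fit(y, Z, X, beta = st$beta, sigma2 = st$sigma2, lam = st$lam,
                  r = st$r, S = 1)
  Znew <- matrix(rnorm(6), 3, 2)
  K <- brute_kernel(Z, Z, st$r)
  Kc <- brute_kernel(Z, Znew, st$r)
  Kn <- brute_kernel(Znew, Znew, st$r)
  V <- diag(n) + st$lam * K
  e <- y - st$beta * X[, 1]
  mu_oracle <- st$lam * drop(t(Kc) %*% solve(V, e))
  mu_pkg <- drop(posterior_h_draws(fit, Znew, mode = "mean"))
  expect_equal(mu_pkg, mu_oracle, tolerance = 1e-8)
  # conditional covariance via the empirical covariance of repeated draws
  Sig_oracle <- st$sigma2 * (st$lam * Kn -
                             st$lam^2 * t(Kc) %*% solve(V, Kc))
  fitS <- fake_fit(y, Z, X, beta = st$beta, sigma2 = st$sigma2, lam = st$lam,
                   r = st$r, S = 4000)
  dr <- posterior_h_draws(fitS, Znew, mode = "full", seed = 5)
  expect_equal(colMeans(dr), mu_oracle,
               tolerance = max(4 * sqrt(diag(Sig_oracle) / 4000)) + 1e-9,
               ignore_attr = TRUE)
  expect_equal(cov(dr), as.matrix(Sig_oracle), tolerance = 0.15,
               ignore_attr = TRUE)
})

test_that("null kernel and interpolation limits of h prediction", {
  set.seed(32)
  n <- 8
  Z <- matrix(rnorm(n * 2), n, 2)
  y <- rnorm(n)
  fit0 <- fake_fit(y, Z, lam = 0, S = 3)
  dr <- posterior_h_draws(fit0, Z[1:4, ], mode = "full")
  expect_true(all(dr == 0))
  # large lambda: prediction at a training point approaches its residual
  fitI <- fake_fit(y, Z, lam = 1e6, r = c(0.5, 0.5), S = 1)
  mu <- drop(posterior_h_draws(fitI, Z, mode = "mean"))
  expect_equal(mu, y, tolerance = 1e-3)
  expect_error(posterior_h_draws(fit0, matrix(0, 1, 3)), "exposure columns")
})

test_that("GPP-mode prediction agrees with exact prediction under
           saturating knots", {
  set.seed(33)
  sim <- kmr_sim_continuous(n = 50, M = 3,
                            terms = list(list(type = "linear", var = 1, a = 1)),
                            seed = 33)
  ct <- kmr_control(n_iter = 200, seed = 33)
  fit <- kmreg(sim$data, control = ct)
  gfit <- kmreg(sim$data, knots = sim$data$Z, control = ct)
  Znew <- sim$data$Z[1:5, ]
  expect_equal(posterior_h_draws(gfit, Znew, mode = "mean"),
               posterior_h_draws(fit, Znew, mode = "mean"), tolerance = 1e-3)
})

test_that("overall effect is a quantile contrast with exact-zero null", {
  fit <- additive_fit()
  oe0 <- overall_effect(fit, q = 0.5, q_ref = 0.5)
  expect_equal(oe0$mean, 0)
  expect_equal(oe0$sd, 0)
  expect_equal(oe0$lower, 0)
  # linear additive truth: Delta_tot(25,75) = sum_m a_m (z75_m - z25_m)
  tr <- true_contrasts(additive_fixture()$truth)
  oe <- overall_effect(fit, q = 0.75, q_ref = 0.25, seed = 1)
  expect_gt(oe$upper, tr$overall$truth)
  expect_lt(oe$lower - 0.2, tr$overall$truth)
  # ladder is monotone under a monotone-increasing truth (z1 up, z2 down
  # cancels; use the recovered surface ordering statistically)
  lad <- overall_effect(fit, q = seq(0.25, 0.75, 0.05), q_ref = 0.5,
                        mode = "mean")
  expect_true(all(diff(lad$mean) > -0.1))
})

test_that("single-exposure effects recover signs, nulls, and additivity", {
  fit <- additive_fit()
  tr <- true_contrasts(additive_fixture()$truth)
  se <- single_exposure_effects(fit, seed = 2)
  # strongly active exposures: sign matches the truth at every q_fix
  z1 <- se[se$exposure == "z1", ]
  z2 <- se[se$exposure == "z2", ]
  expect_true(all(z1$mean > 0))
  expect_true(all(z2$mean < 0))
  # inert exposure: interval covers 0 at the median conditioning
  z3 <- se[se$exposure == "z3" & se$q_fix == 0.5, ]
  expect_lte(z3$lower, 0)
  expect_gte(z3$upper, 0)
  # additive truth: z1 contrast is stable across conditioning quantiles
  expect_lt(max(z1$mean) - min(z1$mean), 0.5)
  # truth covered at median conditioning
  tr50 <- tr$single[tr$single$q_fix == 0.5, ]
  cover <- mapply(function(m, lo, hi) {
    t <- tr50$truth[tr50$exposure == m]
    t >= lo - 0.1 & t <= hi + 0.1
  }, z1$exposure[1], z1$lower[1], z1$upper[1])
  expect_true(all(cover))
})

test_that("interactive effects vanish under additive truth and equal the
           definitional draw-wise difference", {
  fit <- additive_fit()
  ie <- interactive_effects(fit, seed = 7)
  expect_true(all(ie$lower <= 0 & ie$upper >= 0))
  # definitional identity in deterministic (mean) mode
  ie_mean <- interactive_effects(fit, mode = "mean")
  d_hi <- kmrmix:::single_effect_draws(fit, 0.75, 0.25, 0.75, "mean", NULL)
  d_lo <- kmrmix:::single_effect_draws(fit, 0.25, 0.25, 0.75, "mean", NULL)
  manual <- kmrmix:::summarize_draws(d_hi - d_lo)
  expect_equal(ie_mean$mean, manual$mean)
  expect_equal(ie_mean$lower, manual$lower)
})

test_that("univariate cross-section recovers a linear truth and warns on
           extrapolation", {
  fit <- additive_fit()
  cs <- univariate_cross_section(fit, 1, ngrid = 20, mode = "mean")
  slope <- coef(lm(est ~ z, data = cs))[2]
  expect_gt(slope, 0.6)
  expect_lt(slope, 1.4)
  # degenerate one-point grid
  cs1 <- univariate_cross_section(fit, 1, grid = 0)
  expect_equal(nrow(cs1), 1)
  expect_warning(univariate_cross_section(fit, 1, grid = c(0, 100)),
                 "extrapolat")
  # bands widen toward the data edge relative to the center
  csf <- univariate_cross_section(fit, 1, ngrid = 21, mode = "full", seed = 4)
  w <- csf$upper - csf$lower
  expect_gt(mean(w[c(1, 21)]), w[11])
})

test_that("bivariate cross-sections are symmetric and nearly additive for
           additive truth", {
  fit <- additive_fit()
  s12 <- bivariate_cross_section(fit, 1, 2, ngrid = 6)
  s21 <- bivariate_cross_section(fit, 2, 1, ngrid = 6)
  merged <- merge(s12, s21, by.x = c("z1", "z2"), by.y = c("z2", "z1"))
  expect_equal(merged$est.x, merged$est.y, tolerance = 1e-10)
  expect_error(bivariate_cross_section(fit, 1, 1), "distinct")
  # panels across a third (inert) exposure differ only by ~constant shifts
  s3 <- bivariate_cross_section(fit, 1, 2, m3 = 3, ngrid = 5)
  panels <- split(s3$est, s3$q3)
  d1 <- panels[[3]] - panels[[1]]
  expect_lt(sd(d1), 0.25)
})

test_that("every credible interval brackets its posterior mean", {
  fit <- additive_fit()
  for (df in list(overall_effect(fit, q = c(0.3, 0.7), seed = 8),
                  single_exposure_effects(fit, q_fix = 0.5, seed = 8),
                  interactive_effects(fit, seed = 8))) {
    expect_true(all(df$lower <= df$mean & df$mean <= df$upper))
  }
})

test_that("saturated parameter count follows the combinatorial formula", {
  expect_equal(saturated_model_parameter_count(4, 3), 255)
  expect_equal(saturated_model_parameter_count(5, 3), 1023)
  expect_equal(saturated_model_parameter_count(1, 1), 1)
  expect_error(saturated_model_parameter_count(0, 3), "positive integers")
  expect_error(saturated_model_parameter_count(3, 1.5), "positive integers")
})
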