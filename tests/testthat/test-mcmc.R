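# The marginalized likelihood and the sampler blocks, checked against
# closed forms and dense-algebra oracles.

toy_ctx <- function(n = 6, M = 2, P = 1, seed = 1, id = NULL,
                    family = "gaussian", knots = NULL) {
  set.seed(seed)
  Z <- matrix(rnorm(n * M), n, M)
  X <- matrix(rnorm(n * P), n, P)
  y <- rnorm(n)
  list(y = y, Z = Z, X = X,
       ctx = kmrmix:::build_ctx(y, Z, X, id, family, knots = knots))
}

test_that("marginal log-likelihood reduces to iid normals when lambda = 0", {
  tc <- toy_ctx(n = 8)
  st <- list(beta = 0.5, sigma2 = 1.7, lam = 0, r = c(0.5, 0.5),
             delta = c(1L, 1L))
  e <- tc$y - 0.5 * tc$X[, 1]
  expect_equal(kmrmix:::marginal_loglik(st, tc$ctx),
               sum(dnorm(e, 0, sqrt(1.7), log = TRUE)))
})

test_that("marginal log-likelihood matches a dense MVN oracle and is
           exchangeable under joint row permutation", {
  tc <- toy_ctx(n = 4, M = 2, seed = 2)
  st <- list(beta = -0.3, sigma2 = 0.9, lam = 1.4, r = c(0.7, 0.2),
             delta = c(1L, 1L))
  K <- brute_kernel(tc$Z, tc$Z, st$r)
  Sigma <- st$sigma2 * (diag(4) + st$lam * K)
  expect_equal(kmrmix:::marginal_loglik(st, tc$ctx),
               dense_mvn_logpdf(tc$y, st$beta * tc$X[, 1], Sigma),
               tolerance = 1e-8)
  perm <- c(3, 1, 4, 2)
  ctx_p <- kmrmix:::build_ctx(tc$y[perm], tc$Z[perm, ], tc$X[perm, , drop = FALSE],
                              NULL, "gaussian")
  expect_equal(kmrmix:::marginal_loglik(st, ctx_p),
               kmrmix:::marginal_loglik(st, tc$ctx), tolerance = 1e-10)
})

test_that("clustered covariance adds the block term and nests the base model", {
  n <- 8
  id <- rep(1:2, each = 4)
  tc <- toy_ctx(n = n, seed = 3)
  ctx_c <- kmrmix:::build_ctx(tc$y, tc$Z, tc$X, id, "gaussian")
  st <- list(beta = 0.2, sigma2 = 1.1, lam = 0.6, r = c(0.4, 0.9),
             delta = c(1L, 1L), lam_b = 0.8)
  K <- brute_kernel(tc$Z, tc$Z, st$r)
  B <- outer(id, id, "==") * 1
  Sigma <- st$sigma2 * (diag(n) + st$lam * K + st$lam_b * B)
  expect_equal(kmrmix:::marginal_loglik(st, ctx_c),
               dense_mvn_logpdf(tc$y, st$beta * tc$X[, 1], Sigma),
               tolerance = 1e-8)
  # lam_b = 0 boundary: same value as the unclustered model
  st0 <- st; st0$lam_b <- 0
  st_base <- st; st_base$lam_b <- NULL
  expect_equal(kmrmix:::marginal_loglik(st0, ctx_c),
               kmrmix:::marginal_loglik(st_base, tc$ctx), tolerance = 1e-10)
})

test_that("GPP likelihood equals the exact one when knots saturate the data", {
  set.seed(4)
  n <- 25
  Z <- matrix(rnorm(n * 3), n, 3)
  X <- matrix(rnorm(n), n, 1)
  y <- rnorm(n)
  ctx_ex <- kmrmix:::build_ctx(y, Z, X, NULL, "gaussian")
  ctx_gpp <- kmrmix:::build_ctx(y, Z, X, NULL, "gaussian", knots = Z,
                                nugget = 1e-8)
  for (s in 1:5) {
    set.seed(s)
    st <- list(beta = rnorm(1), sigma2 = runif(1, 0.5, 2),
               lam = runif(1, 0.1, 3), r = runif(3, 0, 1))
    st$delta <- as.integer(st$r > 0)
    expect_equal(kmrmix:::marginal_loglik(st, ctx_gpp),
                 kmrmix:::marginal_loglik(st, ctx_ex), tolerance = 1e-6)
  }
})

test_that("beta update draws from the GLS conditional", {
  set.seed(5)
  n <- 30
  Z <- matrix(rnorm(n * 2), n, 2)
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- rnorm(n)
  ctx <- kmrmix:::build_ctx(y, Z, X, NULL, "gaussian")
  st <- list(beta = c(0, 0), sigma2 = 1.3, lam = 0.8, r = c(0.5, 0.3),
             delta = c(1L, 1L))
  kp <- kmrmix:::kparts_init(ctx, st$r)
  fac <- kmrmix:::make_fac(ctx, kp, st$lam)
  V <- diag(n) + st$lam * kmrmix:::kparts_init(ctx, st$r)$K
  Vi <- solve(V)
  gls_mean <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  gls_cov <- st$sigma2 * solve(t(X) %*% Vi %*% X)
  draws <- t(replicate(4000, kmrmix:::update_beta(st, ctx, fac)$beta))
  se <- sqrt(diag(gls_cov) / 4000)
  expect_true(all(abs(colMeans(draws) - drop(gls_mean)) < 3 * se))
  expect_equal(cov(draws), gls_cov, tolerance = 0.15, ignore_attr = TRUE)
  # P = 0 is a no-op
  ctx0 <- kmrmix:::build_ctx(y, Z, matrix(numeric(0), n, 0), NULL, "gaussian")
  expect_identical(kmrmix:::update_beta(st, ctx0, fac), st)
})

test_that("sigma2 update is the conjugate inverse-gamma draw", {
  set.seed(6)
  n <- 20
  Z <- matrix(rnorm(n * 2), n, 2)
  X <- matrix(rnorm(n), n, 1)
  y <- rnorm(n, sd = 2)
  ctx <- kmrmix:::build_ctx(y, Z, X, NULL, "gaussian")
  pr <- kmr_priors()
  st <- list(beta = 0.4, sigma2 = 1, lam = 0, r = c(0.2, 0.2),
             delta = c(1L, 1L))
  kp <- kmrmix:::kparts_init(ctx, st$r)
  fac <- kmrmix:::make_fac(ctx, kp, 0)
  e <- y - 0.4 * X[, 1]
  shape <- pr$sigma2_shape + n / 2
  rate <- pr$sigma2_rate + sum(e^2) / 2
  draws <- replicate(5000, kmrmix:::update_sigma2(st, ctx, fac, pr)$sigma2)
  ks <- ks.test(1 / draws, pgamma, shape = shape, rate = rate)
  expect_gt(ks$p.value, 0.01)
  # probit family keeps sigma2 frozen at 1
  ctxp <- kmrmix:::build_ctx(round(plogis(y)), Z, X, NULL, "binomial")
  stp <- st; stp$ystar <- y
  expect_equal(kmrmix:::update_sigma2(stp, ctxp, fac, pr)$sigma2, 1)
})

test_that("lambda MH ratio matches a hand-computed value on a frozen state", {
  tc <- toy_ctx(n = 10, seed = 7)
  pr <- kmr_priors()
  ct <- kmr_control(n_iter = 10)
  st <- list(beta = 0.1, sigma2 = 1.2, lam = 0.9, r = c(0.6, 0.4),
             delta = c(1L, 1L))
  kp <- kmrmix:::kparts_init(tc$ctx, st$r)
  fac <- kmrmix:::make_fac(tc$ctx, kp, st$lam)
  set.seed(99)
  z <- rnorm(1)
  lam_new <- st$lam * exp(ct$sd_log_lambda * z)
  ll <- function(lam) {
    K <- brute_kernel(tc$Z, tc$Z, st$r)
    dense_mvn_logpdf(tc$y, st$beta * tc$X[, 1],
                     st$sigma2 * (diag(10) + lam * K))
  }
  expected <- ll(lam_new) - ll(st$lam) +
    dgamma(lam_new, pr$lambda_shape, rate = pr$lambda_rate, log = TRUE) -
    dgamma(st$lam, pr$lambda_shape, rate = pr$lambda_rate, log = TRUE) +
    log(lam_new) - log(st$lam)
  set.seed(99)
  up <- kmrmix:::update_lambda(st, tc$ctx, kp, fac, pr, ct)
  expect_equal(up$log_ratio, expected, tolerance = 1e-8)
})

test_that("run bookkeeping: store count, finiteness, seed determinism", {
  sim <- kmr_sim_continuous(n = 10, M = 2,
                            terms = list(list(type = "linear", var = 1, a = 1)),
                            seed = 1)
  ct <- kmr_control(n_iter = 50, burn = 0, thin = 1, seed = 5)
  fit <- suppressWarnings(kmreg(sim$data, control = ct))
  expect_equal(fit$n_stored, 50)
  expect_true(all(is.finite(fit$samples$r)))
  expect_true(all(is.finite(fit$samples$sigma2)))
  expect_true(all(is.finite(fit$samples$loglik)))
  fit2 <- suppressWarnings(kmreg(sim$data, control = ct))
  expect_identical(fit$samples, fit2$samples)
  # thinning and burn-in bookkeeping
  ct2 <- kmr_control(n_iter = 100, burn = 0.5, thin = 5, seed = 5)
  fit3 <- suppressWarnings(kmreg(sim$data, control = ct2))
  expect_equal(fit3$n_stored, 10)
})

test_that("spike/slab consistency: r is zero exactly when delta is zero", {
  sim <- kmr_sim_continuous(n = 60, M = 3,
                            terms = list(list(type = "linear", var = 1, a = 1)),
                            seed = 2)
  fit <- kmreg(sim$data, control = kmr_control(n_iter = 400, seed = 2))
  expect_true(all((fit$samples$r == 0) == (fit$samples$delta == 0)))
  # without variable selection everything stays active
  fit0 <- kmreg(sim$data, varsel = FALSE,
                control = kmr_control(n_iter = 100, seed = 2))
  expect_true(all(fit0$samples$delta == 1))
  expect_true(all(fit0$samples$r > 0))
})

test_that("posterior mean of beta matches GLS at fixed kernel parameters", {
  set.seed(8)
  n <- 40
  Z <- matrix(rnorm(n * 2), n, 2)
  X <- cbind(x1 = rnorm(n))
  y <- drop(Z %*% c(1, 0)) + 0.8 * X[, 1] + rnorm(n, sd = 0.5)
  lam <- 1.2; rfix <- 0.3
  fit <- kmreg(y, Z, X, varsel = FALSE, standardize = FALSE,
               control = kmr_control(n_iter = 3000, seed = 8,
                                     update_lambda = FALSE, update_r = FALSE,
                                     lambda_start = lam, r_start = rfix))
  K <- brute_kernel(Z, Z, rep(rfix, 2))
  Vi <- solve(diag(n) + lam * K)
  gls_mean <- drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y))
  b <- fit$samples$beta[, 1]
  mcse <- sd(b) / sqrt(length(b) / 5)  # conservative autocorrelation factor
  expect_lt(abs(mean(b) - gls_mean), 3 * mcse)
})

test_that("with a flat likelihood the selection indicators revert to the
           Bernoulli prior", {
  set.seed(9)
  n <- 40
  Z <- matrix(rnorm(n * 3), n, 3)
  y <- rnorm(n)
  # lambda = 0 makes the likelihood independent of (r, delta)
  fit <- suppressWarnings(
    kmreg(y, Z, control = kmr_control(n_iter = 4000, burn = 0.25, seed = 9,
                                      update_lambda = FALSE,
                                      lambda_start = 0)))
  pips <- colMeans(fit$samples$delta)
  expect_true(all(abs(pips - 0.5) < 0.08))
})

test_that("selection concentrates on the truly active exposure", {
  set.seed(10)
  sim <- kmr_sim_continuous(n = 100, M = 3, rho = 0,
                            terms = list(list(type = "linear", var = 1, a = 1.5)),
                            beta = 0, sd = 0.5, seed = 10)
  fit <- kmreg(sim$data, control = kmr_control(n_iter = 1500, seed = 10))
  pips <- extract_pips(fit)$pip
  expect_gt(pips[1], pips[2])
  expect_gt(pips[1], pips[3])
})

test_that("hierarchical selection keeps at most one active member per group", {
  sim <- kmr_sim_continuous(n = 80, M = 4, rho = 0.2,
                            hi_pairs = c(1, 2),
                            terms = list(list(type = "linear", var = 1, a = 1.2)),
                            seed = 11)
  fit <- kmreg(sim$data, groups = c("a", "a", "b", "b"),
               control = kmr_control(n_iter = 800, seed = 11))
  d <- fit$samples$delta
  expect_true(all(d[, 1] + d[, 2] <= 1))
  expect_true(all(d[, 3] + d[, 4] <= 1))
  # correlated pair holding the signal gets the higher group PIP
  pips <- extract_pips(fit)
  expect_gt(pips$pip[1], pips$pip[3])
  expect_error(kmreg(sim$data, groups = c("a", "a", "b", "b"), varsel = FALSE),
               "varsel")
})

test_that("marginalized sampler agrees with an explicit-h Gibbs sampler", {
  set.seed(12)
  n <- 15
  Z <- matrix(rnorm(n * 2), n, 2)
  X <- matrix(rnorm(n), n, 1)
  y <- drop(Z %*% c(1, -0.5)) + 0.5 * X[, 1] + rnorm(n, sd = 0.5)
  lam <- 1; rfix <- 0.4
  fit <- kmreg(y, Z, X, varsel = FALSE, standardize = FALSE,
               control = kmr_control(n_iter = 4000, seed = 12,
                                     update_lambda = FALSE, update_r = FALSE,
                                     lambda_start = lam, r_start = rfix))
  h_marg <- posterior_h_draws(fit, Z, mode = "full")
  h_expl <- explicit_h_sampler(y, Z, X, lam, rep(rfix, 2),
                               n_iter = 6000, seed = 13)[-(1:1000), ]
  se <- sqrt(apply(h_marg, 2, var) / (nrow(h_marg) / 5) +
             apply(h_expl, 2, var) / (nrow(h_expl) / 5))
  diff <- abs(colMeans(h_marg) - colMeans(h_expl))
  expect_true(all(diff < 3 * se))
})
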