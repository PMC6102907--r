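# Block updates of the hybrid Gibbs/Metropolis-Hastings sampler.
# Update order per iteration: (probit) latent y* -> beta -> sigma^2 ->
# lambda -> r/delta sweep -> (clustered) lambda_b.

# Gibbs draw of beta from its GLS conditional under the flat prior (internal)
update_beta <- function(state, ctx, fac) {
  if (ctx$P == 0L) return(state)
  resp <- ctx_resp(state, ctx)
  Vi <- fac$solve(cbind(ctx$X, resp))
  XtVX <- crossprod(ctx$X, Vi[, seq_len(ctx$P), drop = FALSE])
  XtVy <- crossprod(ctx$X, Vi[, ctx$P + 1L])
  R <- tryCatch(chol(XtVX), error = function(e)
    stop("X' V^-1 X is singular; covariate columns appear collinear: ",
         paste(colnames(ctx$X), collapse = ", ")))
  mu <- backsolve(R, backsolve(R, XtVy, transpose = TRUE))
  state$beta <- drop(mu + sqrt(state$sigma2) * backsolve(R, stats::rnorm(ctx$P)))
  state
}

# conjugate inverse-gamma draw of sigma^2 (gaussian family only) (internal)
update_sigma2 <- function(state, ctx, fac, priors) {
  if (ctx$family == "binomial") return(state)
  resp <- ctx_resp(state, ctx)
  e <- if (ctx$P > 0) resp - drop(ctx$X %*% state$beta) else resp
  q <- sum(e * fac$solve(e))
  shape <- priors$sigma2_shape + ctx$n / 2
  rate <- priors$sigma2_rate + q / 2
  state$sigma2 <- 1 / stats::rgamma(1, shape = shape, rate = rate)
  state
}

# random-walk MH on log(lambda) with Jacobian correction (internal)
update_lambda <- function(state, ctx, kp, fac, priors, control) {
  ll_cur <- marginal_loglik(state, ctx, fac = fac)
  lam_new <- state$lam * exp(control$sd_log_lambda * stats::rnorm(1))
  cand <- state; cand$lam <- lam_new
  fac_new <- make_fac(ctx, kp, lam_new, state$lam_b)
  ll_new <- marginal_loglik(cand, ctx, fac = fac_new)
  log_ratio <- ll_new - ll_cur +
    stats::dgamma(lam_new, priors$lambda_shape, rate = priors$lambda_rate, log = TRUE) -
    stats::dgamma(state$lam, priors$lambda_shape, rate = priors$lambda_rate, log = TRUE) +
    log(lam_new) - log(state$lam)
  accepted <- log(stats::runif(1)) < log_ratio
  if (accepted) {
    state <- cand
    fac <- fac_new
  }
  list(state = state, fac = fac, accepted = accepted, log_ratio = log_ratio)
}

# random-walk MH on log(lambda_b), the random-intercept variance ratio (internal)
update_lambda_b <- function(state, ctx, kp, fac, priors, control) {
  ll_cur <- marginal_loglik(state, ctx, fac = fac)
  lb_new <- state$lam_b * exp(control$sd_log_lambda_b * stats::rnorm(1))
  cand <- state; cand$lam_b <- lb_new
  fac_new <- make_fac(ctx, kp, state$lam, lb_new)
  ll_new <- marginal_loglik(cand, ctx, fac = fac_new)
  log_ratio <- ll_new - ll_cur +
    stats::dgamma(lb_new, priors$lambda_b_shape, rate = priors$lambda_b_rate, log = TRUE) -
    stats::dgamma(state$lam_b, priors$lambda_b_shape, rate = priors$lambda_b_rate, log = TRUE) +
    log(lb_new) - log(state$lam_b)
  accepted <- log(stats::runif(1)) < log_ratio
  if (accepted) {
    state <- cand
    fac <- fac_new
  }
  list(state = state, fac = fac, accepted = accepted, log_ratio = log_ratio)
}

# One sweep of spike-and-slab / slab-walk moves over all components (or
# group units in hierarchical mode), in random order (internal).
# Returns state, kp, fac and per-move acceptance counts.
update_r_sweep <- function(state, ctx, kp, fac, priors, control,
                           groups_info = NULL, varsel = TRUE) {
  acc <- c(birth = 0, death = 0, swap = 0, walk = 0)
  prop <- c(birth = 0, death = 0, swap = 0, walk = 0)
  ll_cur <- marginal_loglik(state, ctx, fac = fac)

  try_move <- function(r_changes, log_prior_prop) {
    # r_changes: named list idx -> new value; returns TRUE if accepted
    kp_new <- kp
    for (j in seq_along(r_changes$idx)) {
      m <- r_changes$idx[j]
      kp_new <- kparts_shift(ctx, kp_new, m, r_changes$val[j], state$r[m])
    }
    fac_new <- make_fac(ctx, kp_new, state$lam, state$lam_b)
    cand <- state
    cand$r[r_changes$idx] <- r_changes$val
    cand$delta[r_changes$idx] <- as.integer(r_changes$val > 0)
    ll_new <- marginal_loglik(cand, ctx, fac = fac_new)
    if (log(stats::runif(1)) < ll_new - ll_cur + log_prior_prop) {
      state <<- cand; kp <<- kp_new; fac <<- fac_new; ll_cur <<- ll_new
      TRUE
    } else FALSE
  }

  slab_walk <- function(m) {
    prop["walk"] <<- prop["walk"] + 1
    r_old <- state$r[m]
    r_new <- r_old * exp(control$sd_log_r * stats::rnorm(1))
    lpp <- dslab_log(r_new, priors) - dslab_log(r_old, priors) +
      log(r_new) - log(r_old)
    if (!is.finite(lpp)) return(invisible())   # outside slab support
    if (try_move(list(idx = m, val = r_new), lpp))
      acc["walk"] <<- acc["walk"] + 1
  }

  update_component <- function(m) {
    if (!varsel) { slab_walk(m); return(invisible()) }
    if (state$delta[m] == 1L) {
      if (stats::runif(1) < 0.5) {  # death
        prop["death"] <<- prop["death"] + 1
        lpp <- log(1 - priors$pi) - log(priors$pi) -
          dslab_log(state$r[m], priors) + dbirth_log(state$r[m], priors) -
          log(0.5)
        if (try_move(list(idx = m, val = 0), lpp))
          acc["death"] <<- acc["death"] + 1
      } else slab_walk(m)
    } else {  # birth
      prop["birth"] <<- prop["birth"] + 1
      r_new <- rbirth(priors)
      lpp <- log(priors$pi) - log(1 - priors$pi) +
        dslab_log(r_new, priors) - dbirth_log(r_new, priors) + log(0.5)
      if (is.finite(lpp) && try_move(list(idx = m, val = r_new), lpp))
        acc["birth"] <<- acc["birth"] + 1
    }
  }

  update_group <- function(g) {
    act <- g[state$delta[g] == 1L]
    ng <- length(g)
    p_death <- if (ng > 1) 1 / 3 else 1 / 2
    if (!length(act)) {  # group off: birth
      prop["birth"] <<- prop["birth"] + 1
      j <- if (ng > 1) g[sample.int(ng, 1)] else g
      r_new <- rbirth(priors)
      lpp <- log(priors$pi) + dslab_log(r_new, priors) - log(1 - priors$pi) +
        log(p_death) - dbirth_log(r_new, priors)
      if (is.finite(lpp) && try_move(list(idx = j, val = r_new), lpp))
        acc["birth"] <<- acc["birth"] + 1
    } else {
      mA <- act[1]
      u <- stats::runif(1)
      if (u < p_death) {  # death
        prop["death"] <<- prop["death"] + 1
        lpp <- log(1 - priors$pi) - log(priors$pi) - dslab_log(state$r[mA], priors) +
          dbirth_log(state$r[mA], priors) - log(p_death)
        if (try_move(list(idx = mA, val = 0), lpp))
          acc["death"] <<- acc["death"] + 1
      } else if (ng > 1 && u < 2 * p_death) {  # swap active member
        prop["swap"] <<- prop["swap"] + 1
        others <- setdiff(g, mA)
        j <- if (length(others) > 1) others[sample.int(length(others), 1)] else others
        r_new <- rbirth(priors)
        lpp <- dslab_log(r_new, priors) - dslab_log(state$r[mA], priors) +
          dbirth_log(state$r[mA], priors) - dbirth_log(r_new, priors)
        if (is.finite(lpp) &&
            try_move(list(idx = c(mA, j), val = c(0, r_new)), lpp))
          acc["swap"] <<- acc["swap"] + 1
      } else slab_walk(mA)
    }
  }

  if (is.null(groups_info)) {
    for (m in sample.int(ctx$M)) update_component(m)
  } else {
    units <- c(groups_info$groups,
               as.list(groups_info$singletons))
    is_group <- c(rep(TRUE, length(groups_info$groups)),
                  rep(FALSE, length(groups_info$singletons)))
    ord <- sample.int(length(units))
    for (k in ord) {
      if (is_group[k]) update_group(units[[k]]) else update_component(units[[k]])
    }
  }
  list(state = state, kp = kp, fac = fac, acc = acc, prop = prop)
}

# draw from a one-sided truncated normal, robust far into the tail (internal)
rtnorm_above <- function(mu, sd, lower) {
  alpha <- (lower - mu) / sd
  logS <- log(stats::runif(1)) +
    stats::pnorm(alpha, lower.tail = FALSE, log.p = TRUE)
  mu + sd * stats::qnorm(logS, lower.tail = FALSE, log.p = TRUE)
}

rtnorm_below <- function(mu, sd, upper) {
  -rtnorm_above(-mu, sd, -upper)
}

# Element-wise Gibbs sweep over the latent probit response y*, using the
# precision of the h-marginalized covariance V = I + lambda K (internal).
# Each y*_i is drawn from its full conditional truncated to y*_i > 0 when
# y_i = 1 and y*_i <= 0 when y_i = 0.
update_latent <- function(state, ctx, fac) {
  Omega <- fac$omega()
  xb <- if (ctx$P > 0) drop(ctx$X %*% state$beta) else numeric(ctx$n)
  d <- state$ystar - xb
  for (i in seq_len(ctx$n)) {
    oii <- Omega[i, i]
    mu_i <- xb[i] - (sum(Omega[i, ] * d) - oii * d[i]) / oii
    sd_i <- 1 / sqrt(oii)
    if (!is.finite(mu_i)) stop("non-finite latent conditional mean at i = ", i)
    yi <- if (ctx$y[i] == 1) rtnorm_above(mu_i, sd_i, 0)
          else rtnorm_below(mu_i, sd_i, 0)
    d[i] <- yi - xb[i]
    state$ystar[i] <- yi
  }
  state
}

#' Fit a Bayesian kernel machine regression model
#'
#' Estimates the flexible multivariable exposure-response function
#' `h(z_1, ..., z_M)` in the model `y = h(z) + x'beta + eps` (or its probit
#' latent-variable analogue for binary outcomes) by MCMC, with the
#' subject-level surface values marginalized out of the sampler. Variable
#' selection uses a spike-and-slab prior on the kernel weights `r_m`:
#' `r_m = 0` excludes exposure m from `h`, and the posterior frequency of
#' inclusion is the exposure's posterior inclusion probability (PIP).
#' Hierarchical selection over groups of highly correlated exposures is
#' available through `groups`, with exactly one member active within an
#' active group. Clustered outcomes are handled by a marginalized random
#' intercept, and large samples by a Gaussian-predictive-process (GPP)
#' low-rank approximation over a set of knots.
#'
#' @param y outcome vector, or a [kmr_data] object (in which case `Z`, `X`,
#'   `id` and `family` are taken from it).
#' @param Z n-by-M exposure matrix.
#' @param X optional n-by-P covariate matrix (entered linearly).
#' @param family `"gaussian"` or `"binomial"` (probit); for probit the
#'   residual variance is fixed at 1 for identifiability.
#' @param id optional cluster labels for a random intercept.
#' @param varsel logical: run spike-and-slab variable selection. With
#'   `varsel = FALSE` all exposures stay in `h` and only slab walks are made.
#' @param groups optional length-M vector of group labels (NA = ungrouped)
#'   requesting hierarchical selection.
#' @param knots GPP knots: `NULL` for the exact fit, an integer number of
#'   knots (selected by k-means on the standardized exposures), or a matrix
#'   of knot locations on the original exposure scale.
#' @param priors a [kmr_priors] object.
#' @param control a [kmr_control] object (iterations, burn-in, thinning,
#'   seed, proposal scales).
#' @param standardize center/scale exposures internally (default TRUE);
#'   all reporting stays on the original exposure scale.
#' @return An object of class `kmreg` with components `samples` (post
#'   burn-in, thinned draws of beta, sigma2, lambda, r, delta, tau_b2 and,
#'   for probit, the latent response), `acceptance` rates per MH block, the
#'   data and standardization constants, and the fitting configuration.
#'   Methods: [print.kmreg()], [summary.kmreg()], [coef.kmreg()],
#'   [predict.kmreg()], [plot.kmreg()], [fitted.kmreg()],
#'   [residuals.kmreg()].
#' @examples
#' sim <- kmr_sim_continuous(n = 60, M = 3, seed = 1)
#' fit <- kmreg(sim$data, control = kmr_control(n_iter = 200, seed = 1))
#' fit
#' @export
kmreg <- function(y, Z = NULL, X = NULL, family = c("gaussian", "binomial"),
                  id = NULL, varsel = TRUE, groups = NULL, knots = NULL,
                  priors = kmr_priors(), control = kmr_control(),
                  standardize = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  if (inherits(y, "kmr_data")) {
    dat <- y
  } else {
    family <- match.arg(family)
    dat <- kmr_data(outcome = y, exposures = Z, covariates = X, id = id,
                    family = family)
  }
  stopifnot(inherits(priors, "kmr_priors"), inherits(control, "kmr_control"))
  family <- dat$family
  n <- length(dat$y); M <- ncol(dat$Z); P <- ncol(dat$X)
  groups_info <- check_groups(groups, M)
  if (!is.null(groups_info) && !varsel)
    stop("hierarchical selection (groups) requires varsel = TRUE")

  std <- if (standardize) standardize_exposures(dat$Z)
         else list(Z = dat$Z, center = rep(0, M), scale = rep(1, M))
  Zs <- std$Z

  set.seed(control$seed)
  knmat <- NULL
  if (!is.null(knots)) {
    if (is.matrix(knots) || is.data.frame(knots)) {
      knmat <- apply_standardize(as.matrix(knots), std$center, std$scale)
    } else {
      knmat <- select_knots(Zs, as.integer(knots), method = "kmeans",
                            seed = control$seed)
    }
  }
  ctx <- build_ctx(dat$y, Zs, dat$X, dat$id, family, knots = knmat)

  # --- initialization ---
  beta0 <- if (P > 0) {
    resp0 <- if (family == "binomial") dat$y - mean(dat$y) else dat$y
    drop(qr.solve(ctx$X, resp0))
  } else numeric(0)
  sigma20 <- if (family == "binomial") 1
             else if (!is.null(control$sigma2_start)) control$sigma2_start
             else {
               e0 <- if (P > 0) dat$y - drop(ctx$X %*% beta0) else dat$y
               max(stats::var(e0), 1e-8)
             }
  r_start <- if (is.null(control$r_start)) 0.25 / M else control$r_start
  r0 <- rep(r_start, M)
  delta0 <- rep(1L, M)
  if (!is.null(groups_info)) {
    # start each group with its first member active
    for (g in groups_info$groups) {
      off <- setdiff(g, g[1])
      r0[off] <- 0; delta0[off] <- 0L
    }
  }
  state <- list(beta = beta0, sigma2 = sigma20, lam = control$lambda_start,
                r = r0, delta = delta0,
                lam_b = if (!is.null(dat$id)) control$lambda_b_start else NULL)
  if (family == "binomial")
    state$ystar <- ifelse(dat$y == 1, 0.5, -0.5) + 0.1 * stats::rnorm(n)

  kp <- kparts_init(ctx, state$r)
  fac <- make_fac(ctx, kp, state$lam, state$lam_b)

  # --- storage ---
  burn_n <- floor(control$n_iter * control$burn)
  keep <- seq_len(control$n_iter)
  keep <- keep[keep > burn_n & (keep - burn_n) %% control$thin == 0L]
  S <- length(keep)
  out <- list(beta = matrix(NA_real_, S, P,
                            dimnames = list(NULL, colnames(dat$X))),
              sigma2 = numeric(S), lam = numeric(S),
              r = matrix(NA_real_, S, M, dimnames = list(NULL, colnames(dat$Z))),
              delta = matrix(NA_integer_, S, M,
                             dimnames = list(NULL, colnames(dat$Z))),
              tau_b2 = if (!is.null(dat$id)) numeric(S) else NULL,
              ystar = if (family == "binomial") matrix(NA_real_, S, n) else NULL,
              loglik = numeric(S))
  acc <- list(lambda = c(0, 0), lambda_b = c(0, 0),
              r_acc = c(birth = 0, death = 0, swap = 0, walk = 0),
              r_prop = c(birth = 0, death = 0, swap = 0, walk = 0))

  s_idx <- 0L
  for (iter in seq_len(control$n_iter)) {
    if (family == "binomial")
      state <- update_latent(state, ctx, fac)
    if (control$update_beta && P > 0)
      state <- update_beta(state, ctx, fac)
    if (control$update_sigma2)
      state <- update_sigma2(state, ctx, fac, priors)
    if (control$update_lambda) {
      up <- update_lambda(state, ctx, kp, fac, priors, control)
      state <- up$state; fac <- up$fac
      acc$lambda <- acc$lambda + c(up$accepted, 1)
    }
    if (control$update_r) {
      up <- update_r_sweep(state, ctx, kp, fac, priors, control,
                           groups_info = groups_info, varsel = varsel)
      state <- up$state; kp <- up$kp; fac <- up$fac
      acc$r_acc <- acc$r_acc + up$acc
      acc$r_prop <- acc$r_prop + up$prop
    }
    if (!is.null(dat$id)) {
      up <- update_lambda_b(state, ctx, kp, fac, priors, control)
      state <- up$state; fac <- up$fac
      acc$lambda_b <- acc$lambda_b + c(up$accepted, 1)
    }
    if (iter > burn_n && (iter - burn_n) %% control$thin == 0L) {
      s_idx <- s_idx + 1L
      if (P > 0) out$beta[s_idx, ] <- state$beta
      out$sigma2[s_idx] <- state$sigma2
      out$lam[s_idx] <- state$lam
      out$r[s_idx, ] <- state$r
      out$delta[s_idx, ] <- state$delta
      if (!is.null(out$tau_b2)) out$tau_b2[s_idx] <- state$lam_b * state$sigma2
      if (!is.null(out$ystar)) out$ystar[s_idx, ] <- state$ystar
      out$loglik[s_idx] <- marginal_loglik(state, ctx, fac = fac)
    }
    if (control$verbose && iter %% control$report_every == 0L)
      message(sprintf("iter %d/%d  loglik %.2f  acc(lambda) %.2f",
                      iter, control$n_iter,
                      marginal_loglik(state, ctx, fac = fac),
                      if (acc$lambda[2] > 0) acc$lambda[1] / acc$lambda[2] else NA))
  }

  rate <- function(x) if (x[2] > 0) x[1] / x[2] else NA_real_
  structure(list(
    samples = out,
    acceptance = list(
      lambda = rate(acc$lambda),
      lambda_b = if (!is.null(dat$id)) rate(acc$lambda_b) else NULL,
      r = ifelse(acc$r_prop > 0, acc$r_acc / acc$r_prop, NA_real_)),
    data = dat, Zstd = Zs,
    std = list(center = std$center, scale = std$scale,
               standardize = standardize),
    knots = knmat, nugget = ctx$nugget,
    family = family, varsel = varsel, groups = groups,
    priors = priors, control = control,
    n_stored = S, call = match.call(),
    time = proc.time()[["elapsed"]] - t0), class = "kmreg")
}
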