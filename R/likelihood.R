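# Internal machinery for the marginalized BKMR likelihood.
#
# With h integrated out, the working response (y, or the latent y* under
# probit) is multivariate normal with mean X beta and covariance
#   Sigma = sigma^2 * V,   V = I + lambda * K_r [+ lambda_b * B],
# where K_r is the component-weighted Gaussian kernel, B the cluster
# block-indicator matrix, lambda = tau^2/sigma^2 and
# lambda_b = tau_b^2/sigma^2. In Gaussian predictive process (GPP) mode
# K_r is replaced by the knot projection Ktilde = P P', and V = I + W W'
# with W = [sqrt(lambda) P, sqrt(lambda_b) C]; Woodbury identities then
# reduce every solve and log-determinant to the knot dimension.

# Build the static fitting context shared by all updates (internal).
build_ctx <- function(y, Z, X, id, family, knots = NULL, nugget = 1e-6,
                      ystar = NULL) {
  n <- length(y); M <- ncol(Z); P <- ncol(X)
  ctx <- list(y = y, Z = Z, X = X, n = n, M = M, P = P, family = family,
              nugget = nugget, gpp = !is.null(knots), knots = knots)
  if (ctx$gpp) {
    K <- nrow(knots)
    ctx$DU <- lapply(seq_len(M), function(m) outer(Z[, m], knots[, m], "-")^2)
    ctx$DA <- lapply(seq_len(M), function(m) outer(knots[, m], knots[, m], "-")^2)
    ctx$nknots <- K
  } else {
    ctx$Dlist <- lapply(seq_len(M), function(m) outer(Z[, m], Z[, m], "-")^2)
  }
  if (!is.null(id)) {
    G <- max(id)
    C <- matrix(0, n, G)
    C[cbind(seq_len(n), id)] <- 1
    ctx$Cmat <- C
    if (!ctx$gpp) ctx$B <- tcrossprod(C)
    ctx$id <- id
  }
  ctx
}

# Kernel parts for a given weight vector r (internal). Maintains the
# weighted squared-distance sums so single-component updates are cheap.
kparts_init <- function(ctx, r) {
  if (ctx$gpp) {
    SU <- matrix(0, ctx$n, ctx$nknots); SA <- matrix(0, ctx$nknots, ctx$nknots)
    for (m in which(r > 0)) {
      SU <- SU + r[m] * ctx$DU[[m]]
      SA <- SA + r[m] * ctx$DA[[m]]
    }
    list(SU = SU, SA = SA, U = exp(-SU),
         A = exp(-SA) + ctx$nugget * diag(ctx$nknots))
  } else {
    S <- matrix(0, ctx$n, ctx$n)
    for (m in which(r > 0)) S <- S + r[m] * ctx$Dlist[[m]]
    list(S = S, K = exp(-S))
  }
}

# Shift component m's weight from r_old to r_new (internal).
kparts_shift <- function(ctx, kp, m, r_new, r_old) {
  d <- r_new - r_old
  if (ctx$gpp) {
    kp$SU <- kp$SU + d * ctx$DU[[m]]
    kp$SA <- kp$SA + d * ctx$DA[[m]]
    kp$U <- exp(-kp$SU)
    kp$A <- exp(-kp$SA) + ctx$nugget * diag(ctx$nknots)
  } else {
    kp$S <- kp$S + d * ctx$Dlist[[m]]
    kp$K <- exp(-kp$S)
  }
  kp
}

# Factorization of V for given (lambda, lambda_b) (internal). Returns
# solve(), logdet and omega() = dense V^{-1}.
make_fac <- function(ctx, kp, lam, lam_b = NULL) {
  n <- ctx$n
  if (!ctx$gpp) {
    V <- diag(n) + lam * kp$K
    if (!is.null(ctx$B)) V <- V + lam_b * ctx$B
    R <- chol_psd(V)
    list(kind = "dense", R = R, logdet = 2 * sum(log(diag(R))),
         solve = function(x) backsolve(R, backsolve(R, x, transpose = TRUE)),
         omega = function() chol2inv(R))
  } else {
    RA <- chol_psd(kp$A)
    Pm <- t(backsolve(RA, t(kp$U), transpose = TRUE))
    W <- sqrt(lam) * Pm
    if (!is.null(ctx$Cmat)) W <- cbind(W, sqrt(lam_b) * ctx$Cmat)
    q <- ncol(W)
    if (q == 0L || (lam == 0 && is.null(ctx$Cmat))) {
      return(list(kind = "gpp", logdet = 0, solve = identity,
                  omega = function() diag(n)))
    }
    Mq <- diag(q) + crossprod(W)
    Rq <- chol_psd(Mq)
    solve_fun <- function(x)
      x - W %*% backsolve(Rq, backsolve(Rq, crossprod(W, x), transpose = TRUE))
    list(kind = "gpp", Rq = Rq, W = W,
         logdet = 2 * sum(log(diag(Rq))),
         solve = solve_fun,
         omega = function() {
           diag(n) - W %*% backsolve(Rq, backsolve(Rq, t(W), transpose = TRUE))
         })
  }
}

# working response: y for gaussian, current latent y* for probit (internal)
ctx_resp <- function(state, ctx) {
  if (ctx$family == "binomial") state$ystar else ctx$y
}

# Marginal log-likelihood of the current state (internal). `fac`/`kp` may
# be supplied to reuse a cached factorization.
marginal_loglik <- function(state, ctx, fac = NULL, kp = NULL) {
  if (is.null(fac)) {
    if (is.null(kp)) kp <- kparts_init(ctx, state$r)
    fac <- make_fac(ctx, kp, state$lam, state$lam_b)
  }
  resp <- ctx_resp(state, ctx)
  e <- if (ctx$P > 0) resp - drop(ctx$X %*% state$beta) else resp
  q <- sum(e * fac$solve(e))
  ll <- -0.5 * (ctx$n * log(2 * pi * state$sigma2) + fac$logdet + q / state$sigma2)
  if (!is.finite(ll))
    stop("non-finite marginal log-likelihood (sigma2 = ", state$sigma2,
         ", lambda = ", state$lam, ")")
  ll
}
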