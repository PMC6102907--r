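# Convergence monitoring for kmreg fits.

# flatten stored samples into one numeric matrix with the persisted column
# schema: beta.*, sigma2, lam, r.*, delta.*, tau_b2 (internal)
flatten_samples <- function(fit) {
  sm <- fit$samples
  P <- ncol(sm$beta); M <- ncol(sm$r)
  cols <- list()
  if (P > 0) {
    b <- sm$beta
    colnames(b) <- paste0("beta.", seq_len(P))
    cols$beta <- b
  }
  cols$sigma2 <- matrix(sm$sigma2, ncol = 1, dimnames = list(NULL, "sigma2"))
  cols$lam <- matrix(sm$lam, ncol = 1, dimnames = list(NULL, "lam"))
  r <- sm$r; colnames(r) <- paste0("r.", seq_len(M))
  d <- sm$delta; colnames(d) <- paste0("delta.", seq_len(M))
  cols$r <- r; cols$delta <- d
  if (!is.null(sm$tau_b2))
    cols$tau_b2 <- matrix(sm$tau_b2, ncol = 1, dimnames = list(NULL, "tau_b2"))
  do.call(cbind, cols)
}

#' Extract parameter traces
#'
#' Returns the stored post-burn-in traces for the requested parameters,
#' in iteration order, using the persisted column schema (`beta.1`, ...,
#' `sigma2`, `lam`, `r.1`, ..., `delta.1`, ..., `tau_b2`).
#'
#' @param fit a [kmreg] fit.
#' @param pars character vector of parameter names; `NULL` returns all.
#' @return numeric matrix, one column per requested parameter.
#' @export
extract_traces <- function(fit, pars = NULL) {
  flat <- flatten_samples(fit)
  if (is.null(pars)) return(flat)
  unknown <- setdiff(pars, colnames(flat))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(colnames(flat), collapse = ", "))
  flat[, pars, drop = FALSE]
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-rank-normalized) PSRF comparing between- and within-chain
#' variance: `sqrt(((L-1)/L * W + B/L) / W)`, where `W` is the mean
#' within-chain variance and `B` the between-chain variance of the chain
#' means (times L). Values near 1 indicate the chains agree; values well
#' above 1 indicate non-convergence.
#'
#' The statistic is floored at 1: values below 1 can only arise from the
#' finite-sample (L-1)/L correction when the chains agree essentially
#' perfectly, and carry no diagnostic information.
#'
#' @param chains a list of numeric vectors (one per chain, equal lengths),
#'   or a list of matrices with matching columns (PSRF computed per column).
#' @return named numeric vector of PSRF values (>= 1).
#' @export
gelman_rubin <- function(chains) {
  stopifnot(is.list(chains))
  if (length(chains) < 2) stop("gelman_rubin needs at least 2 chains")
  if (is.matrix(chains[[1]])) {
    cn <- colnames(chains[[1]])
    out <- vapply(seq_len(ncol(chains[[1]])), function(j)
      gelman_rubin(lapply(chains, function(ch) ch[, j])), 0)
    names(out) <- cn
    return(out)
  }
  L <- unique(lengths(chains))
  if (length(L) != 1) stop("chains must have equal lengths")
  if (L < 10) stop("chains too short (need length >= 10)")
  means <- vapply(chains, mean, 0)
  W <- mean(vapply(chains, stats::var, 0))
  B <- L * stats::var(means)
  max(1, sqrt(((L - 1) / L * W + B / L) / W))
}

#' Posterior estimates table
#'
#' Posterior mean, standard deviation and quantiles (2.5, 25, 50, 75,
#' 97.5%) for every stored scalar parameter of a fit.
#'
#' @param fit a [kmreg] fit.
#' @return data.frame with one row per parameter.
#' @export
posterior_estimates <- function(fit) {
  flat <- flatten_samples(fit)
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  out <- data.frame(
    param = colnames(flat),
    mean = colMeans(flat),
    sd = apply(flat, 2, stats::sd),
    t(apply(flat, 2, stats::quantile, qs, type = 7)))
  names(out)[4:8] <- c("q2.5", "q25", "q50", "q75", "q97.5")
  rownames(out) <- NULL
  out
}
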