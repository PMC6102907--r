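#' Component-weighted Gaussian kernel matrix
#'
#' Computes `K[i, j] = exp(-sum_m r_m (Z1[i, m] - Z2[j, m])^2)`. A weight
#' `r_m = 0` removes exposure m from the distance entirely, which is how the
#' spike-and-slab selection excludes an exposure from the fitted surface.
#' Distances are the unscaled weighted sum of squared coordinate
#' differences (no division by M).
#'
#' @param Z1 n1-by-M numeric matrix.
#' @param Z2 n2-by-M numeric matrix; defaults to `Z1` (symmetric case).
#' @param r length-M vector of nonnegative weights.
#' @return n1-by-n2 matrix with entries in (0, 1].
#' @examples
#' gaussian_kernel(rbind(c(1, 0)), rbind(c(0, 0)), r = c(1, 1))  # exp(-1)
#' @export
gaussian_kernel <- function(Z1, Z2 = NULL, r) {
  Z1 <- as.matrix(Z1)
  if (is.null(Z2)) Z2 <- Z1 else Z2 <- as.matrix(Z2)
  if (ncol(Z1) != length(r) || ncol(Z2) != length(r))
    stop("column count of Z1/Z2 must equal length(r)")
  if (any(r < 0)) stop("kernel weights r must be nonnegative")
  S <- matrix(0, nrow(Z1), nrow(Z2))
  for (m in which(r > 0))
    S <- S + r[m] * outer(Z1[, m], Z2[, m], "-")^2
  exp(-S)
}

#' Select knots covering the exposure space
#'
#' Picks K representative points in exposure space for the Gaussian
#' predictive process approximation, either as k-means centroids (default;
#' a reproducible space-covering choice) or as a random subset of rows.
#'
#' @param Z n-by-M exposure matrix (usually standardized).
#' @param n_knots number of knots, 1 <= n_knots <= n.
#' @param method `"kmeans"` or `"random"`.
#' @param seed integer seed making the selection deterministic.
#' @return n_knots-by-M matrix of knot locations.
#' @export
select_knots <- function(Z, n_knots, method = c("kmeans", "random"), seed = 1) {
  method <- match.arg(method)
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (n_knots < 1 || n_knots > n)
    stop("n_knots must be between 1 and nrow(Z)")
  if (n_knots == n) {
    kn <- unique(Z)
    dimnames(kn) <- NULL
    return(kn)
  }
  with_seed(seed, {
    if (method == "random") {
      kn <- Z[sample.int(n, n_knots), , drop = FALSE]
    } else {
      km <- stats::kmeans(Z, centers = n_knots, nstart = 3, iter.max = 100)
      kn <- km$centers
    }
    dimnames(kn) <- NULL
    kn
  })
}

# Cholesky with a symmetric-eigenvalue fallback that clips small/negative
# eigenvalues at eps (internal)
chol_psd <- function(A, eps = 1e-10) {
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    ee <- eigen((A + t(A)) / 2, symmetric = TRUE)
    vals <- pmax(ee$values, eps)
    A2 <- ee$vectors %*% (vals * t(ee$vectors))
    R <- chol((A2 + t(A2)) / 2 + eps * diag(nrow(A)))
  }
  R
}

#' Low-rank (Gaussian predictive process) kernel factorization
#'
#' Builds the projection of the kernel onto the space spanned by a knot set:
#' `Ktilde = K_{Z,knots} (K_{knots,knots} + nugget I)^{-1} K_{knots,Z}`,
#' returned through a factor `P` with `Ktilde = P %*% t(P)` so that all
#' downstream likelihood algebra solves only knot-dimension systems.
#'
#' @param Z n-by-M matrix of exposures.
#' @param knots K-by-M knot matrix.
#' @param r length-M nonnegative kernel weights.
#' @param nugget small positive ridge added to the knot kernel for
#'   factorization stability, in (0, 1e-4].
#' @return list with `P` (n-by-K factor), `U` (= K_{Z,knots}), `A`
#'   (= K_{knots,knots} + nugget I) and `RA` (Cholesky factor of `A`).
#' @export
low_rank_kernel <- function(Z, knots, r, nugget = 1e-6) {
  Z <- as.matrix(Z); knots <- as.matrix(knots)
  if (ncol(Z) != ncol(knots)) stop("knots must have the same columns as Z")
  if (nugget <= 0 || nugget > 1e-4) stop("nugget must be in (0, 1e-4]")
  if (!nrow(knots)) stop("knots must be nonempty")
  U <- gaussian_kernel(Z, knots, r)
  A <- gaussian_kernel(knots, NULL, r) + nugget * diag(nrow(knots))
  RA <- tryCatch(chol(A), error = function(e)
    stop("knot kernel is singular even after the nugget; ",
         "use fewer or duplicate-free knots"))
  P <- t(backsolve(RA, t(U), transpose = TRUE))
  list(P = P, U = U, A = A, RA = RA)
}
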