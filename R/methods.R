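# S3 methods for kmreg fits.

#' @export
print.kmreg <- function(x, ...) {
  cat("Bayesian kernel machine regression fit\n")
  cat(sprintf("  family: %s%s\n", x$family,
              if (!is.null(x$data$id)) " (random intercept)" else ""))
  cat(sprintf("  n = %d, M = %d exposures, P = %d covariates\n",
              length(x$data$y), ncol(x$data$Z), ncol(x$data$X)))
  if (!is.null(x$knots))
    cat(sprintf("  Gaussian predictive process, %d knots\n", nrow(x$knots)))
  cat(sprintf("  %d stored states (n_iter = %d, burn = %.0f%%, thin = %d, seed = %d)\n",
              x$n_stored, x$control$n_iter, 100 * x$control$burn,
              x$control$thin, x$control$seed))
  cat(sprintf("  acceptance: lambda %.2f", x$acceptance$lambda))
  if (!is.null(x$acceptance$lambda_b))
    cat(sprintf(", lambda_b %.2f", x$acceptance$lambda_b))
  rr <- x$acceptance$r
  cat(sprintf(", r moves [%s]\n",
              paste(sprintf("%s %.2f", names(rr), rr)[!is.na(rr)],
                    collapse = ", ")))
  if (x$varsel) {
    pips <- extract_pips(x)
    cat("  posterior inclusion probabilities:\n")
    print(utils::head(pips[order(-pips$pip), ], 10), row.names = FALSE)
  }
  invisible(x)
}

#' Summarize a kmreg fit
#'
#' @param object a [kmreg] fit.
#' @param ... unused.
#' @return list with posterior estimates of the scalar parameters, PIPs
#'   (if variable selection was used) and acceptance rates.
#' @export
summary.kmreg <- function(object, ...) {
  est <- posterior_estimates(object)
  keep <- !grepl("^delta\\.", est$param)
  structure(list(estimates = est[keep, ],
                 pips = if (object$varsel) extract_pips(object) else NULL,
                 acceptance = object$acceptance,
                 family = object$family,
                 n = length(object$data$y),
                 M = ncol(object$data$Z)),
            class = "summary.kmreg")
}

#' @export
print.summary.kmreg <- function(x, ...) {
  cat(sprintf("kmreg summary (%s family, n = %d, M = %d)\n\n",
              x$family, x$n, x$M))
  cat("Posterior estimates:\n")
  print(x$estimates, row.names = FALSE, digits = 3)
  if (!is.null(x$pips)) {
    cat("\nPosterior inclusion probabilities:\n")
    print(x$pips, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
coef.kmreg <- function(object, ...) {
  if (!ncol(object$samples$beta)) return(numeric(0))
  stats::setNames(colMeans(object$samples$beta), colnames(object$data$X))
}

#' Posterior-mean fitted values
#'
#' Posterior mean of `h` at the training exposures plus the covariate
#' contribution; for probit fits, returned on the probability scale.
#'
#' @param object a [kmreg] fit.
#' @param ... unused.
#' @export
fitted.kmreg <- function(object, ...) {
  h <- colMeans(posterior_h_draws(object, object$data$Z, mode = "mean"))
  xb <- if (ncol(object$data$X)) drop(object$data$X %*% coef(object)) else 0
  if (object$family == "binomial") stats::pnorm(h + xb) else h + xb
}

#' @export
residuals.kmreg <- function(object, ...) {
  object$data$y - fitted(object)
}

#' Plot a kmreg fit
#'
#' `type = "trace"` draws MCMC trace plots for selected parameters;
#' `type = "h"` draws the univariate cross-section of the fitted surface
#' for exposure `m` with 95% credible bands.
#'
#' @param x a [kmreg] fit.
#' @param type `"trace"` or `"h"`.
#' @param pars parameters for trace plots (default `"lam"` and `"sigma2"`).
#' @param m exposure index for `type = "h"`.
#' @param ... passed to the underlying plotting calls.
#' @export
plot.kmreg <- function(x, type = c("trace", "h"), pars = c("lam", "sigma2"),
                       m = 1, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    tr <- extract_traces(x, pars)
    op <- graphics::par(mfrow = c(length(pars), 1), mar = c(3, 4, 2, 1))
    on.exit(graphics::par(op))
    for (j in seq_len(ncol(tr)))
      graphics::plot(tr[, j], type = "l", ylab = colnames(tr)[j],
                     xlab = "stored iteration", ...)
  } else {
    cs <- univariate_cross_section(x, m, mode = "full")
    graphics::plot(cs$z, cs$est, type = "l", ylim = range(cs$lower, cs$upper),
                   xlab = colnames(x$data$Z)[m], ylab = "h", ...)
    graphics::lines(cs$z, cs$lower, lty = 2)
    graphics::lines(cs$z, cs$upper, lty = 2)
  }
  invisible(x)
}
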