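#' @export
print.gamma_fit <- function(x, digits = 4, ...) {
  cat("Gamma interference model fit (", x$method, ")\n", sep = "")
  se_txt <- if (is.finite(x$se_nu)) sprintf(" (SE %.3g)", x$se_nu) else ""
  cat(sprintf("  nu (shape, interference strength): %s%s\n",
              format(x$nu, digits = digits), se_txt))
  cat(sprintf("  scale: %s   n = %d gaps   logLik = %.4g\n",
              format(x$scale, digits = digits), x$n, x$loglik))
  cat("  (nu = 1 corresponds to no interference)\n")
  invisible(x)
}

#' Coefficients of a gamma interference fit
#'
#' @param object A `gamma_fit` object.
#' @param ... Unused.
#' @return Named vector `c(shape = nu, scale = scale)`.
#' @export
coef.gamma_fit <- function(object, ...) {
  c(shape = object$nu, scale = object$scale)
}

#' @export
logLik.gamma_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n, class = "logLik")
}

#' Variance-covariance matrix of a gamma interference MLE
#'
#' Inverse of the observed Fisher information of the two-parameter gamma
#' model; only available for `method = "mle"` fits.
#'
#' @param object A `gamma_fit` object.
#' @param ... Unused.
#' @return 2x2 matrix over `(shape, scale)`.
#' @export
vcov.gamma_fit <- function(object, ...) {
  if (object$method != "mle")
    stop("vcov is only defined for maximum-likelihood fits")
  k <- object$nu; th <- object$scale; n <- object$n
  info <- n * matrix(c(trigamma(k), 1 / th, 1 / th, k / th^2), 2, 2)
  v <- solve(info)
  dimnames(v) <- list(c("shape", "scale"), c("shape", "scale"))
  v
}

#' Wald confidence interval for the interference parameter
#'
#' @param object A `gamma_fit` object with a finite SE.
#' @param parm Ignored; the interval is for the shape.
#' @param level Confidence level.
#' @param ... Unused.
#' @return Length-2 vector (lower, upper).
#' @export
confint.gamma_fit <- function(object, parm = "shape", level = 0.95, ...) {
  if (!is.finite(object$se_nu))
    stop("no standard error available for this fit method")
  z <- qnorm(1 - (1 - level) / 2)
  setNames(object$nu + c(-1, 1) * z * object$se_nu,
           c(sprintf("%.1f%%", 100 * (1 - level) / 2),
             sprintf("%.1f%%", 100 * (1 + level) / 2)))
}

#' @export
summary.gamma_fit <- function(object, ...) {
  cv <- sd(object$distances) / mean(object$distances)
  out <- list(fit = object, mean_gap = mean(object$distances), cv = cv,
              mom_nu = if (cv > 0) 1 / cv^2 else Inf,
              ci = tryCatch(confint.gamma_fit(object), error = function(e) NULL))
  class(out) <- "summary.gamma_fit"
  out
}

#' @export
print.summary.gamma_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  gap mean %.4g, CV %.3g (method-of-moments nu = %.4g)\n",
              x$mean_gap, x$cv, x$mom_nu))
  if (!is.null(x$ci))
    cat(sprintf("  95%% CI for nu: [%.4g, %.4g]\n", x$ci[[1]], x$ci[[2]]))
  invisible(x)
}

#' Histogram of observed distances with the fitted gamma density
#'
#' Reproduces the standard interference figure: relative-frequency histogram
#' of adjacent-focus distances (percent of SC length) overlaid with the
#' fitted gamma density.
#'
#' @param x A `gamma_fit` object.
#' @param breaks Passed to [graphics::hist()].
#' @param main,xlab Plot annotation.
#' @param ... Further arguments to `hist`.
#' @export
plot.gamma_fit <- function(x, breaks = "Sturges",
                           main = "Inter-focus distances and fitted gamma model",
                           xlab = "Distance between adjacent foci (% of SC length)",
                           ...) {
  hist(x$distances, breaks = breaks, freq = FALSE, main = main, xlab = xlab,
       col = "grey85", border = "grey40", ...)
  shape <- x$nu; scale <- x$scale
  curve(dgamma(x, shape = shape, scale = scale), add = TRUE,
        col = "red", lwd = 2, n = 400)
  legend("topright", bty = "n",
         legend = sprintf("gamma fit: nu = %.2f (%s)", x$nu, x$method))
  invisible(x)
}

#' Simulate inter-focus distances from a fitted gamma model
#'
#' @param object A `gamma_fit` object.
#' @param nsim Number of gap draws.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Numeric vector of simulated distances.
#' @export
simulate.gamma_fit <- function(object, nsim = object$n, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  rgamma(nsim, shape = object$nu, scale = object$scale)
}

#' Quantile residuals of a gamma interference fit
#'
#' Maps each observed distance through the fitted gamma CDF and the standard
#' normal quantile function; residuals should be close to standard normal
#' when the model fits.
#'
#' @param object A `gamma_fit` object.
#' @param ... Unused.
#' @return Numeric vector of quantile residuals.
#' @export
residuals.gamma_fit <- function(object, ...) {
  qnorm(pgamma(object$distances, shape = object$nu, scale = object$scale))
}
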