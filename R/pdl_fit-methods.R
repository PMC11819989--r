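# S3 methods for the fitted-model object.

#' @export
print.pdl_fit <- function(x, digits = 4, ...) {
  cat("Hyperelastic PDL model fit (", curve_label(x$curve), ")\n", sep = "")
  cat("  free coefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("  Vf = %s (fixed), R^2 = %s, residual norm = %s MPa\n",
              format(x$vf, digits = 5),
              format(x$r_squared, digits = 6),
              format(x$residual_norm, digits = 3)))
  if (!x$converged) cat("  ** optimizer did not report convergence **\n")
  invisible(x)
}

#' Extract fitted model coefficients
#'
#' @param object a `"pdl_fit"`.
#' @param full if `TRUE`, return all six coefficients plus `vf` and `vm`
#'   (constraint-expanded); otherwise the free coefficients actually
#'   optimised.
#' @param ... unused.
#' @return named numeric vector.
#' @export
coef.pdl_fit <- function(object, full = FALSE, ...) {
  if (!full) return(object$coefficients)
  p <- object$params
  c(c1 = p$c1, c2 = p$c2, c3 = p$c3, c4 = p$c4, c5 = p$c5, c6 = p$c6,
    vf = p$vf, vm = p$vm)
}

#' @export
residuals.pdl_fit <- function(object, ...) object$residuals

#' @export
fitted.pdl_fit <- function(object, ...) object$fitted.values

#' Predict Cauchy stress from a fitted PDL model
#'
#' @param object a `"pdl_fit"`.
#' @param newdata stretch values to predict at; defaults to the fitted
#'   curve's grid. A data frame with a `stretch` column is also accepted.
#' @param ... unused.
#' @return numeric vector of predicted \eqn{\sigma_{11}}, MPa.
#' @export
predict.pdl_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  stretch <- if (is.data.frame(newdata)) newdata$stretch else newdata
  cauchy_stress_uniaxial(stretch, object$params)
}

#' Summarise a fitted PDL model
#'
#' @param object a `"pdl_fit"`.
#' @param ... unused.
#' @return a `"summary.pdl_fit"` list with the full coefficient set,
#'   goodness of fit and residual diagnostics.
#' @export
summary.pdl_fit <- function(object, ...) {
  r <- object$residuals
  out <- list(
    coefficients = coef(object, full = TRUE),
    free         = object$coefficients,
    constrained  = !is.null(object$constraints),
    r_squared    = object$r_squared,
    residual_norm = object$residual_norm,
    sigma        = sqrt(sum(r^2) / max(1, length(r) - length(object$coefficients))),
    resid_range  = range(r),
    n_points     = object$n_points,
    converged    = object$converged,
    niter        = object$niter,
    diagnostics  = energy_diagnostics(
      object$params,
      stretch = seq(min(object$curve$stretch),
                    max(object$curve$stretch), length.out = 100)),
    label        = curve_label(object$curve)
  )
  class(out) <- "summary.pdl_fit"
  out
}

#' @export
print.summary.pdl_fit <- function(x, digits = 5, ...) {
  cat("Hyperelastic PDL model fit (", x$label, ")\n", sep = "")
  cat(if (x$constrained) "  three free coefficients, affine constraints\n"
      else "  unconstrained six-coefficient fit\n")
  cat("  coefficients (c1, c2 in MPa; c3..c6 dimensionless):\n")
  print(round(x$coefficients, digits))
  cat(sprintf("  n = %d, R^2 = %s, residual sd = %s MPa, iterations = %d\n",
              x$n_points, format(x$r_squared, digits = 6),
              format(x$sigma, digits = 3), x$niter))
  if (x$diagnostics$energy_negative) {
    cat("  note: strain energy is negative over part of the fitted range\n")
  }
  if (!x$converged) cat("  ** optimizer did not report convergence **\n")
  invisible(x)
}

#' Plot a fitted PDL model over its data
#'
#' Observed Cauchy stresses as points and the fitted closed-form curve as a
#' line, on the stretch axis.
#'
#' @param x a `"pdl_fit"`.
#' @param n number of grid points for the fitted line.
#' @param ... passed to [plot.stress_strain_curve()].
#' @export
plot.pdl_fit <- function(x, n = 200, ...) {
  plot(x$curve, ...)
  grid <- seq(min(x$curve$stretch), max(x$curve$stretch), length.out = n)
  graphics::lines(grid, predict(x, grid), col = "firebrick", lwd = 2)
  graphics::legend("topleft", bty = "n",
                   legend = c("observed", "fitted model"),
                   pch = c(1, NA), lty = c(NA, 1),
                   col = c("black", "firebrick"))
  invisible(x)
}

#' Simulate stress-stretch curves from a fitted PDL model
#'
#' Draws new curves on the fitted stretch grid: model prediction plus
#' additive Gaussian noise with standard deviation estimated from the fit's
#' residuals (or supplied).
#'
#' @param object a `"pdl_fit"`.
#' @param nsim number of curves.
#' @param seed optional integer seed.
#' @param noise_sd noise standard deviation, MPa; default is the fit's
#'   residual standard deviation.
#' @param ... unused.
#' @return a list of `nsim` [stress_strain_curve()] objects.
#' @export
simulate.pdl_fit <- function(object, nsim = 1, seed = NULL,
                             noise_sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_sd)) {
    noise_sd <- sqrt(sum(object$residuals^2) /
                     max(1, length(object$residuals) -
                           length(object$coefficients)))
  }
  lapply(seq_len(nsim), function(i) {
    generate_curve(object$params, stretch = object$curve$stretch,
                   noise_sd = noise_sd,
                   region = attr(object$curve, "region"),
                   tooth = attr(object$curve, "tooth"),
                   rate = attr(object$curve, "rate"))
  })
}
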