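# Constrained least-squares estimation of the model coefficients from one
# stress-stretch curve. The six-coefficient model is redundant on uniaxial
# data, so fitting is done over the free triplet (c1, c3, c5) with the
# dependent coefficients tied by affine constraints
#   c2 = 0.39571 c1 + 6.30991
#   c4 = -5.38351 c3 - 8.07826
#   c6 = -5.53492 c5 + 4.62974
# (the defaults of constraint_set()). The fiber fraction Vf is a measured
# input, never a fitted quantity. An unconstrained six-coefficient mode is
# available for comparison via constraints = NULL.

#' Affine constraints tying the dependent coefficients to the free triplet
#'
#' The dependent coefficients are affine functions of the free ones:
#' `c2 = slope_c2 * c1 + intercept_c2`, and likewise for `c4(c3)` and
#' `c6(c5)`. Defaults are the non-redundant three-parameter reduction of the
#' six-coefficient model.
#'
#' @param slope_c2,intercept_c2 map from `c1` to `c2`.
#' @param slope_c4,intercept_c4 map from `c3` to `c4`.
#' @param slope_c6,intercept_c6 map from `c5` to `c6`.
#' @return an object of class `"constraint_set"`.
#' @examples
#' constraint_set()  # the default reduction
#' @export
constraint_set <- function(slope_c2 = 0.39571, intercept_c2 = 6.30991,
                           slope_c4 = -5.38351, intercept_c4 = -8.07826,
                           slope_c6 = -5.53492, intercept_c6 = 4.62974) {
  vals <- c(slope_c2, intercept_c2, slope_c4, intercept_c4,
            slope_c6, intercept_c6)
  stopifnot(is.numeric(vals), length(vals) == 6L, all(is.finite(vals)))
  structure(
    list(slope_c2 = slope_c2, intercept_c2 = intercept_c2,
         slope_c4 = slope_c4, intercept_c4 = intercept_c4,
         slope_c6 = slope_c6, intercept_c6 = intercept_c6),
    class = "constraint_set"
  )
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("Linear coefficient constraints:\n")
  cat(sprintf("  c2 = %g * c1 + %g\n", x$slope_c2, x$intercept_c2))
  cat(sprintf("  c4 = %g * c3 + %g\n", x$slope_c4, x$intercept_c4))
  cat(sprintf("  c6 = %g * c5 + %g\n", x$slope_c6, x$intercept_c6))
  invisible(x)
}

#' Expand a free coefficient triplet to the full parameter set
#'
#' Applies the affine constraints to obtain `c2`, `c4`, `c6` from
#' `(c1, c3, c5)` and attaches the measured fiber fraction.
#'
#' @param free numeric vector `(c1, c3, c5)`.
#' @param vf fiber volume fraction in `[0, 1]`.
#' @param constraints a [constraint_set()].
#' @return a [material_params()] object satisfying the constraints exactly.
#' @examples
#' expand_constraints(c(25.57, 9.76, -6.61), vf = 0.60312)
#' @export
expand_constraints <- function(free, vf, constraints = constraint_set()) {
  stopifnot(is.numeric(free), length(free) == 3L)
  if (!inherits(constraints, "constraint_set")) {
    stop("constraints must be a constraint_set()", call. = FALSE)
  }
  material_params(
    c1 = free[1],
    c2 = constraints$slope_c2 * free[1] + constraints$intercept_c2,
    c3 = free[2],
    c4 = constraints$slope_c4 * free[2] + constraints$intercept_c4,
    c5 = free[3],
    c6 = constraints$slope_c6 * free[3] + constraints$intercept_c6,
    vf = vf
  )
}

# params from a free vector: triplet + constraints, or all six unconstrained
params_from_free <- function(free, vf, constraints) {
  if (is.null(constraints)) {
    stopifnot(length(free) == 6L)
    material_params(free[1], free[2], free[3], free[4], free[5], free[6],
                    vf = vf)
  } else {
    expand_constraints(free, vf, constraints)
  }
}

#' Model-minus-data residuals for a coefficient vector
#'
#' Expands `free` to a full parameter set, evaluates the closed-form Cauchy
#' stress on the curve's stretch grid, and returns `model - observed` in
#' MPa. This is the (unweighted) least-squares objective vector of
#' [fit_pdl()].
#'
#' @param curve a [stress_strain_curve()].
#' @param free free coefficient vector: `(c1, c3, c5)` with constraints, or
#'   all six with `constraints = NULL`.
#' @inheritParams expand_constraints
#' @return numeric residual vector, MPa.
#' @export
pdl_residuals <- function(curve, free, vf, constraints = constraint_set()) {
  if (!inherits(curve, "stress_strain_curve")) {
    curve <- stress_strain_curve(curve$stretch, curve$stress)
  }
  p <- params_from_free(free, vf, constraints)
  cauchy_stress_uniaxial(curve$stretch, p) - curve$stress
}

#' Coefficient of determination between observed and predicted stress
#'
#' \eqn{R^2 = 1 - \sum (obs - pred)^2 / \sum (obs - \bar{obs})^2},
#' computed on Cauchy stress. Can be negative for a model worse than the
#' observed mean.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2);
#'   `observed` must have nonzero variance.
#' @return a single number in \eqn{(-\infty, 1]}.
#' @examples
#' r_squared(c(0, 1, 2), c(0, 1, 3))  # 0.5
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(is.numeric(observed), is.numeric(predicted))
  if (length(observed) != length(predicted) || length(observed) < 2L) {
    stop("observed and predicted must have equal length >= 2", call. = FALSE)
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("observed stress has zero variance; R^2 undefined", call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Fit the hyperelastic model to a stress-stretch curve
#'
#' Levenberg-Marquardt least squares over the free coefficient triplet
#' `(c1, c3, c5)`, with `c2`, `c4`, `c6` tied by affine constraints and the
#' fiber volume fraction fixed at its measured value. The objective is the
#' unweighted sum of squared Cauchy-stress residuals over the curve. The
#' exponential model can have local minima, so an optional seeded multistart
#' refits from jittered initial triplets and keeps the best solution; with a
#' given `init` (and `multistart = 1`) the fit is fully deterministic.
#'
#' @param curve a [stress_strain_curve()] (or data frame with `stretch` and
#'   `stress` columns) with at least 4 points spanning stretches above 1.
#' @param vf measured fiber volume fraction in `[0, 1]` (region mean from
#'   sectioning; see [region_summary()]).
#' @param init initial free coefficients; default `c(1, 1, 1)` (length 6
#'   when `constraints = NULL`).
#' @param constraints a [constraint_set()], or `NULL` for the unconstrained
#'   six-coefficient fit.
#' @param bounds box half-width on every free coefficient (the search is
#'   confined to `[-bounds, bounds]`); fitted PDL coefficients have
#'   magnitudes well below the default 100.
#' @param multistart number of starts; starts beyond the first perturb
#'   `init` with seeded Gaussian jitter (sd 5).
#' @param seed integer seed for the multistart jitter (ignored when
#'   `multistart = 1`).
#' @param control passed to [minpack.lm::nls.lm.control()].
#' @return an object of class `"pdl_fit"`; see [print.pdl_fit()],
#'   [summary.pdl_fit()], [coef.pdl_fit()], [predict.pdl_fit()],
#'   [plot.pdl_fit()], [simulate.pdl_fit()].
#' @examples
#' p <- pdl_region_presets()[["apex_central"]]
#' curve <- generate_curve(p, noise_sd = 0)
#' fit <- fit_pdl(curve, vf = p$vf)
#' coef(fit)
#' @export
fit_pdl <- function(curve, vf, init = NULL, constraints = constraint_set(),
                    bounds = 100, multistart = 1L, seed = NULL,
                    control = minpack.lm::nls.lm.control(maxiter = 200)) {
  if (!inherits(curve, "stress_strain_curve")) {
    curve <- stress_strain_curve(curve$stretch, curve$stress)
  }
  if (nrow(curve) < 4L) {
    stop("need at least 4 curve points to fit 3 free coefficients",
         call. = FALSE)
  }
  if (all(curve$stretch == 1)) {
    stop("degenerate curve: all stretches equal 1", call. = FALSE)
  }
  if (!is.numeric(vf) || length(vf) != 1L || vf < 0 || vf > 1) {
    stop("vf must be a single fraction in [0, 1]", call. = FALSE)
  }
  n_free <- if (is.null(constraints)) 6L else 3L
  if (is.null(init)) init <- rep(1, n_free)
  stopifnot(is.numeric(init), length(init) == n_free)
  stopifnot(is.numeric(bounds), length(bounds) == 1L, bounds > 0)

  obj <- function(free) {
    # out-of-range coefficient proposals during the search are penalised,
    # not fatal: LM may step into overflow territory transiently
    r <- tryCatch(pdl_residuals(curve, free, vf, constraints),
                  error = function(e) rep(1e6, nrow(curve)))
    r
  }

  starts <- list(init)
  if (multistart > 1L) {
    if (!is.null(seed)) set.seed(seed)
    for (k in seq_len(multistart - 1L)) {
      starts[[k + 1L]] <- init + stats::rnorm(n_free, sd = 5)
    }
  }

  best <- NULL
  for (st in starts) {
    res <- minpack.lm::nls.lm(
      par = st, fn = obj,
      lower = rep(-bounds, n_free), upper = rep(bounds, n_free),
      control = control
    )
    if (is.null(best) || res$deviance < best$deviance) {
      best <- res
      best_start <- st
    }
  }

  free <- unname(coef(best))
  params <- params_from_free(free, vf, constraints)
  fitted_stress <- cauchy_stress_uniaxial(curve$stretch, params)
  resid <- fitted_stress - curve$stress
  free_names <- if (is.null(constraints)) {
    c("c1", "c2", "c3", "c4", "c5", "c6")
  } else {
    c("c1", "c3", "c5")
  }
  names(free) <- free_names

  out <- list(
    coefficients  = free,
    params        = params,
    vf            = vf,
    constraints   = constraints,
    r_squared     = r_squared(curve$stress, fitted_stress),
    residuals     = resid,
    fitted.values = fitted_stress,
    residual_norm = sqrt(sum(resid^2)),
    n_points      = nrow(curve),
    converged     = best$info %in% 1:4,
    info          = best$info,
    message       = best$message,
    niter         = best$niter,
    deviance      = best$deviance,
    init          = best_start,
    multistart    = as.integer(multistart),
    seed          = seed,
    curve         = curve,
    call          = match.call()
  )
  class(out) <- "pdl_fit"
  if (!out$converged) {
    warning("Levenberg-Marquardt did not report convergence: ",
            best$message, call. = FALSE)
  }
  out
}
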