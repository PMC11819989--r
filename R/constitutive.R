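# Two-phase exponential strain-energy function for the PDL and its
# closed-form uniaxial Cauchy stress.
#
# W = Vm * c1 * (exp(Q1) - 1) + Vf * c2 * (exp(Q2) - 1)
# Q1 = c3 * (I1 - 3)^2 + c4 * (lambda - 1)^4   (matrix phase)
# Q2 = c5 * (I1 - 3)^2 + c6 * (lambda - 1)^4   (fiber phase)
#
# c1, c2 carry stress units (MPa); the exponent coefficients c3..c6 are
# dimensionless. The fiber exponent uses (lambda - 1)^4 in both phases: the
# derivative structure of the closed-form stress (terms in (lambda - 1)^3)
# requires it.

# |Q| beyond this makes exp(Q) meaningless in double precision; the model is
# only intended for lambda in roughly [1, 1.3].
.Q_OVERFLOW <- 700

#' Construct a material parameter set
#'
#' Bundles the six coefficients of the two-phase exponential strain-energy
#' function with the phase volume fractions. `c1` and `c2` are stress scales
#' in MPa for the matrix and fiber phases; `c3`, `c4` (matrix) and `c5`, `c6`
#' (fiber) are dimensionless exponent coefficients. The fiber volume fraction
#' `vf` weights the fiber phase; the matrix fraction is `1 - vf`. No sign
#' restriction is placed on the coefficients: fitted PDL parameter sets can
#' have negative stress scales, and [energy_diagnostics()] reports whether a
#' set produces negative strain energy on a stretch range instead.
#'
#' @param c1,c2 stress-scale coefficients, MPa.
#' @param c3,c4,c5,c6 dimensionless exponent coefficients.
#' @param vf fiber volume fraction in `[0, 1]`.
#' @return an object of class `"material_params"` (a named list with
#'   elements `c1`..`c6`, `vf`, `vm`).
#' @examples
#' material_params(c1 = 1, c2 = 1, c3 = 1, c4 = 0, c5 = 1, c6 = 0, vf = 0.5)
#' @export
material_params <- function(c1, c2, c3, c4, c5, c6, vf) {
  vals <- c(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, c6 = c6, vf = vf)
  if (!is.numeric(vals) || length(vals) != 7L || any(!is.finite(vals))) {
    stop("all material parameters must be finite numeric scalars", call. = FALSE)
  }
  if (vf < 0 || vf > 1) {
    stop("fiber volume fraction vf must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, c6 = c6,
         vf = vf, vm = 1 - vf),
    class = "material_params"
  )
}

#' @export
print.material_params <- function(x, digits = 5, ...) {
  cat("PDL hyperelastic material parameters\n")
  cat(sprintf("  matrix: c1 = %s MPa, c3 = %s, c4 = %s (Vm = %s)\n",
              format(x$c1, digits = digits), format(x$c3, digits = digits),
              format(x$c4, digits = digits), format(x$vm, digits = digits)))
  cat(sprintf("  fiber : c2 = %s MPa, c5 = %s, c6 = %s (Vf = %s)\n",
              format(x$c2, digits = digits), format(x$c5, digits = digits),
              format(x$c6, digits = digits), format(x$vf, digits = digits)))
  invisible(x)
}

as_material_params <- function(p) {
  if (inherits(p, "material_params")) return(p)
  if (is.list(p) || is.numeric(p)) {
    p <- as.list(p)
    need <- c("c1", "c2", "c3", "c4", "c5", "c6", "vf")
    if (all(need %in% names(p))) {
      return(do.call(material_params, p[need]))
    }
  }
  stop("expected a 'material_params' object (see material_params())",
       call. = FALSE)
}

#' Exponent terms of the strain-energy function
#'
#' Evaluates the two dimensionless exponents
#' \eqn{Q_1 = c_3 (I_1 - 3)^2 + c_4 (\lambda - 1)^4} (matrix) and
#' \eqn{Q_2 = c_5 (I_1 - 3)^2 + c_6 (\lambda - 1)^4} (fiber) at the
#' incompressible uniaxial state, where \eqn{I_1 = \lambda^2 + 2/\lambda}
#' and the fiber elongation equals \eqn{\lambda}.
#'
#' @param stretch numeric vector of stretches, all > 0.
#' @param params a [material_params()] object.
#' @return a list with numeric vectors `Q1` and `Q2`.
#' @export
exponents <- function(stretch, params) {
  params <- as_material_params(params)
  check_stretch(stretch)
  i1m3 <- stretch^2 + 2 / stretch - 3
  am1  <- (stretch - 1)^4
  list(Q1 = params$c3 * i1m3^2 + params$c4 * am1,
       Q2 = params$c5 * i1m3^2 + params$c6 * am1)
}

# exp(Q) with an explicit overflow guard naming the offending state
guarded_exp <- function(Q, stretch, which) {
  bad <- abs(Q) > .Q_OVERFLOW
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf(
      "exponent %s = %.3g at stretch = %.6g is outside the representable range; the model is out of its intended stretch range",
      which, Q[i], stretch[i]), call. = FALSE)
  }
  exp(Q)
}

#' Strain-energy density of the two-phase PDL model
#'
#' \eqn{W = V_m c_1 (e^{Q_1} - 1) + V_f c_2 (e^{Q_2} - 1)} in MPa
#' (energy per unit reference volume), evaluated on the incompressible
#' uniaxial path. `W(1) = 0`: the reference state stores no energy.
#'
#' @inheritParams exponents
#' @return numeric vector of energy densities, MPa.
#' @examples
#' p <- material_params(1, 1, 1, 0, 1, 0, vf = 0.5)
#' strain_energy(c(1, 1.1), p)
#' @export
strain_energy <- function(stretch, params) {
  params <- as_material_params(params)
  q <- exponents(stretch, params)
  e1 <- guarded_exp(q$Q1, stretch, "Q1")
  e2 <- guarded_exp(q$Q2, stretch, "Q2")
  params$vm * params$c1 * (e1 - 1) + params$vf * params$c2 * (e2 - 1)
}

#' Incompressibility pressure of uniaxial tension
#'
#' The Lagrange pressure enforcing zero lateral Cauchy stress
#' (\eqn{\sigma_{22} = \sigma_{33} = 0}):
#' \deqn{p = \frac{1}{\lambda}\left[4 V_m c_1 e^{Q_1} c_3 (I_1 - 3)
#'   + 4 V_f c_2 e^{Q_2} c_5 (I_1 - 3)\right].}
#'
#' @inheritParams exponents
#' @return numeric vector of pressures, MPa.
#' @export
pressure_term <- function(stretch, params) {
  params <- as_material_params(params)
  q <- exponents(stretch, params)
  i1m3 <- stretch^2 + 2 / stretch - 3
  e1 <- guarded_exp(q$Q1, stretch, "Q1")
  e2 <- guarded_exp(q$Q2, stretch, "Q2")
  (4 * params$vm * params$c1 * e1 * params$c3 * i1m3 +
   4 * params$vf * params$c2 * e2 * params$c5 * i1m3) / stretch
}

#' Closed-form uniaxial Cauchy stress
#'
#' The axial Cauchy stress of the incompressible uniaxial extension,
#' \deqn{\sigma_{11} = \left(\lambda^2 - \tfrac{1}{\lambda}\right)
#'   \left[4 V_m c_1 e^{Q_1} c_3 (I_1 - 3) + 4 V_f c_2 e^{Q_2} c_5 (I_1 - 3)\right]
#'   + 4 c_4 \lambda (\lambda - 1)^3 V_m c_1 e^{Q_1}
#'   + 4 c_6 \lambda (\lambda - 1)^3 V_f c_2 e^{Q_2},}
#' which equals \eqn{\lambda \, dW/d\lambda} along the uniaxial path and the
#' push-forward of the second Piola-Kirchhoff stress (see
#' [cauchy_via_tensor()]). \eqn{\sigma_{11}(1) = 0} for every parameter set.
#'
#' @inheritParams exponents
#' @return numeric vector of Cauchy stresses \eqn{\sigma_{11}}, MPa.
#' @examples
#' p <- material_params(1, 1, 1, 0, 1, 0, vf = 0.5)
#' cauchy_stress_uniaxial(c(1, 1.1), p)
#' @export
cauchy_stress_uniaxial <- function(stretch, params) {
  params <- as_material_params(params)
  q <- exponents(stretch, params)
  i1m3 <- stretch^2 + 2 / stretch - 3
  e1 <- guarded_exp(q$Q1, stretch, "Q1")
  e2 <- guarded_exp(q$Q2, stretch, "Q2")
  iso <- (stretch^2 - 1 / stretch) *
    (4 * params$vm * params$c1 * e1 * params$c3 * i1m3 +
     4 * params$vf * params$c2 * e2 * params$c5 * i1m3)
  fib <- 4 * stretch * (stretch - 1)^3 *
    (params$c4 * params$vm * params$c1 * e1 +
     params$c6 * params$vf * params$c2 * e2)
  iso + fib
}

#' Predict a stress-stretch curve from a parameter set
#'
#' Vectorised [cauchy_stress_uniaxial()] over a stretch grid, packaged as a
#' [stress_strain_curve()] with optional region/tooth/rate labels.
#'
#' @param stretch strictly increasing stretch grid with `stretch[1] >= 1`.
#' @param params a [material_params()] object.
#' @param region,tooth,rate optional labels carried on the curve.
#' @return a `"stress_strain_curve"` object.
#' @export
curve_predict <- function(stretch, params, region = NA_character_,
                          tooth = NA_character_, rate = NA_character_) {
  stress <- cauchy_stress_uniaxial(stretch, params)
  stress_strain_curve(stretch, stress, region = region, tooth = tooth,
                      rate = rate)
}

#' Diagnose a parameter set over a stretch range
#'
#' Fitted PDL coefficients are not sign-restricted, so a parameter set can
#' in principle store negative energy or soften over part of the tested
#' range. This reports where (if anywhere) `W < 0` or the stress is
#' decreasing on a stretch grid, rather than forbidding such sets.
#'
#' @param params a [material_params()] object.
#' @param stretch stretch grid to scan (default 200 points on `[1, 1.25]`).
#' @return a list with logical flags `energy_negative`, `stress_decreasing`
#'   and the offending stretch values (possibly empty).
#' @export
energy_diagnostics <- function(params,
                               stretch = seq(1, 1.25, length.out = 200)) {
  W <- strain_energy(stretch, params)
  s <- cauchy_stress_uniaxial(stretch, params)
  neg <- stretch[W < -1e-12]
  dec <- stretch[-1][diff(s) < 0]
  list(
    energy_negative   = length(neg) > 0,
    stress_decreasing = length(dec) > 0,
    negative_energy_at   = neg,
    decreasing_stress_at = dec
  )
}
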