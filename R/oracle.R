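# Independent re-derivations of the uniaxial Cauchy stress, used to verify
# the closed form: (i) the full continuum pipeline S = 2 dW/dC - p C^-1
# pushed forward to sigma = F S F^T, and (ii) central finite differences of
# the energy, sigma11 = lambda dW/dlambda. The three routes must agree; the
# tensor route is exact algebra (tol ~1e-9 relative), the difference route
# is second-order in the step.

#' Partial derivatives of the strain energy w.r.t. the invariants
#'
#' \deqn{\partial W/\partial I_1 = 2 (I_1 - 3)\left[V_m c_1 e^{Q_1} c_3 +
#'   V_f c_2 e^{Q_2} c_5\right]}
#' \deqn{\partial W/\partial I_4 = 2 I_4^{-1/2} (\sqrt{I_4} - 1)^3
#'   \left[V_m c_1 e^{Q_1} c_4 + V_f c_2 e^{Q_2} c_6\right]}
#' evaluated on the incompressible uniaxial path where \eqn{I_4 = \lambda^2}.
#'
#' @inheritParams exponents
#' @return list with numeric vectors `dW_dI1` and `dW_dI4`, MPa.
#' @export
energy_partials <- function(stretch, params) {
  params <- as_material_params(params)
  q <- exponents(stretch, params)
  e1 <- guarded_exp(q$Q1, stretch, "Q1")
  e2 <- guarded_exp(q$Q2, stretch, "Q2")
  i1m3 <- stretch^2 + 2 / stretch - 3
  i4 <- stretch^2
  list(
    dW_dI1 = 2 * i1m3 * (params$vm * params$c1 * e1 * params$c3 +
                         params$vf * params$c2 * e2 * params$c5),
    dW_dI4 = 2 * i4^(-1 / 2) * (sqrt(i4) - 1)^3 *
      (params$vm * params$c1 * e1 * params$c4 +
       params$vf * params$c2 * e2 * params$c6)
  )
}

#' Second Piola-Kirchhoff stress of uniaxial tension
#'
#' Assembles \eqn{S = 2\,\partial W/\partial I_1\, E + 2\,\partial W/\partial
#' I_4\, N \otimes N - p\, C^{-1}} at a single stretch, with the pressure
#' from [pressure_term()]. `C` is diagonal here, so its inverse is taken
#' analytically. The push-forward \eqn{F S F^T} has vanishing lateral
#' components: that is the defining property of the pressure.
#'
#' @param stretch a single stretch > 0.
#' @param params a [material_params()] object.
#' @return an object of class `"pk2_stress"`: list with the 3x3 matrix `S`
#'   (MPa), pressure `p` (MPa), and the `"deformation_state"` used.
#' @export
second_pk_stress <- function(stretch, params) {
  params <- as_material_params(params)
  if (length(stretch) != 1L) {
    stop("second_pk_stress() takes a single stretch", call. = FALSE)
  }
  def <- uniaxial_deformation(stretch)
  pd  <- energy_partials(stretch, params)
  p   <- pressure_term(stretch, params)
  Cinv <- diag(c(1 / stretch^2, stretch, stretch))  # exact diagonal inverse
  NN <- tcrossprod(def$N)
  S <- 2 * pd$dW_dI1 * diag(3) + 2 * pd$dW_dI4 * NN - p * Cinv
  structure(list(S = S, p = p, deformation = def), class = "pk2_stress")
}

#' @export
print.pk2_stress <- function(x, ...) {
  cat("Second Piola-Kirchhoff stress (MPa), p =", format(x$p), "\n")
  print(x$S)
  invisible(x)
}

#' Cauchy stress via the tensor pipeline
#'
#' Pushes the second Piola-Kirchhoff stress forward,
#' \eqn{\sigma = F S F^T} (volume ratio J = 1), and returns the axial
#' component. Agrees with [cauchy_stress_uniaxial()] to floating-point
#' accuracy; the lateral components vanish by construction of the pressure.
#'
#' @inheritParams exponents
#' @param full logical; if `TRUE` return the full 3x3 Cauchy tensor(s)
#'   (a list for vector input) instead of just \eqn{\sigma_{11}}.
#' @return numeric vector of \eqn{\sigma_{11}} values (MPa), or 3x3
#'   matrices when `full = TRUE`.
#' @export
cauchy_via_tensor <- function(stretch, params, full = FALSE) {
  params <- as_material_params(params)
  check_stretch(stretch)
  one <- function(l) {
    pk2 <- second_pk_stress(l, params)
    F_ <- pk2$deformation$F
    F_ %*% pk2$S %*% t(F_)
  }
  if (full) {
    out <- lapply(stretch, one)
    if (length(out) == 1L) out[[1L]] else out
  } else {
    vapply(stretch, function(l) one(l)[1, 1], numeric(1))
  }
}

#' Cauchy stress via finite differences of the energy
#'
#' On the incompressible uniaxial path the axial Cauchy stress equals
#' \eqn{\lambda \, dW/d\lambda}; this evaluates it by central differences,
#' \eqn{\lambda (W(\lambda + h) - W(\lambda - h)) / (2h)}. Second-order
#' accurate in `h`; the default step balances truncation against round-off
#' for stresses of order 1 MPa.
#'
#' @inheritParams exponents
#' @param h difference step, in `(0, 1e-3]`; must satisfy `stretch - h > 0`.
#' @return numeric vector of \eqn{\sigma_{11}} approximations, MPa.
#' @export
cauchy_via_finite_difference <- function(stretch, params, h = 1e-6) {
  params <- as_material_params(params)
  check_stretch(stretch)
  if (!is.numeric(h) || length(h) != 1L || h <= 0 || h > 1e-3) {
    stop("h must be a single step in (0, 1e-3]", call. = FALSE)
  }
  if (any(stretch - h <= 0)) {
    stop("stretch - h must stay positive", call. = FALSE)
  }
  stretch * (strain_energy(stretch + h, params) -
             strain_energy(stretch - h, params)) / (2 * h)
}

#' Triangle-agreement report for the three stress routes
#'
#' Evaluates the closed form, the tensor pipeline and the finite-difference
#' derivative of the energy over a stretch grid and reports the worst
#' pairwise discrepancies, plus the largest lateral Cauchy stress magnitude
#' (which should vanish). This is the package's self-verification surface.
#'
#' Discrepancies are reported relative to the larger stress magnitude, with
#' a floor of `stress_floor` (default 1e-3 MPa = 1 kPa, far below any
#' resolvable PDL stress): below the floor a central difference of the
#' energy is dominated by round-off of order 1e-10 MPa and a pure relative
#' measure would be meaningless. `max_abs_closed_vs_fd` carries the plain
#' absolute discrepancy for reference.
#'
#' @param params a [material_params()] object.
#' @param stretch stretch grid (default 25 points on `[1.001, 1.25]`).
#' @param h finite-difference step.
#' @param stress_floor stress scale (MPa) below which discrepancies are
#'   measured absolutely rather than relatively.
#' @return an object of class `"stress_triangle"`: list with
#'   `max_rel_closed_vs_tensor`, `max_rel_closed_vs_fd`,
#'   `max_rel_tensor_vs_fd`, `max_abs_closed_vs_fd`, `max_abs_lateral` and
#'   the evaluated grid.
#' @examples
#' p <- material_params(1, 1, 1, 0.5, 1, 0.5, vf = 0.5)
#' verify_stress_triangle(p)
#' @export
verify_stress_triangle <- function(params,
                                   stretch = seq(1.001, 1.25,
                                                 length.out = 25),
                                   h = 1e-6, stress_floor = 1e-3) {
  params <- as_material_params(params)
  closed <- cauchy_stress_uniaxial(stretch, params)
  tens   <- cauchy_via_tensor(stretch, params)
  fd     <- cauchy_via_finite_difference(stretch, params, h = h)
  lateral <- vapply(stretch, function(l) {
    sig <- cauchy_via_tensor(l, params, full = TRUE)
    max(abs(c(sig[2, 2], sig[3, 3])))
  }, numeric(1))
  # relative on the stress scale, floored for near-zero stresses
  rel <- function(a, b) max(abs(a - b) / pmax(abs(a), abs(b), stress_floor))
  structure(
    list(
      max_rel_closed_vs_tensor = rel(closed, tens),
      max_rel_closed_vs_fd     = rel(closed, fd),
      max_rel_tensor_vs_fd     = rel(tens, fd),
      max_abs_closed_vs_fd     = max(abs(closed - fd)),
      max_abs_lateral          = max(lateral),
      stretch = stretch, closed = closed, tensor = tens,
      finite_difference = fd
    ),
    class = "stress_triangle"
  )
}

#' @export
print.stress_triangle <- function(x, ...) {
  cat("Stress-route triangle agreement over", length(x$stretch),
      "stretches in [", format(min(x$stretch)), ",",
      format(max(x$stretch)), "]\n")
  cat(sprintf("  closed form vs tensor pipeline : %.3g (rel.)\n",
              x$max_rel_closed_vs_tensor))
  cat(sprintf("  closed form vs finite diff     : %.3g (rel.)\n",
              x$max_rel_closed_vs_fd))
  cat(sprintf("  tensor vs finite diff          : %.3g (rel.)\n",
              x$max_rel_tensor_vs_fd))
  cat(sprintf("  max |lateral Cauchy stress|    : %.3g MPa\n",
              x$max_abs_lateral))
  invisible(x)
}
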