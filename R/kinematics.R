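# Kinematics of incompressible uniaxial tension along the fiber axis.
# The fiber direction is fixed to the loading axis N = (1, 0, 0): after
# preconditioning, PDL collagen bundles align with the applied force, so the
# transversely isotropic axis and the tensile axis coincide.

#' Convert Green strain to stretch
#'
#' The stretch (strain ratio) \eqn{\lambda} and the Green strain
#' \eqn{\varepsilon} are related by \eqn{\lambda = \sqrt{1 + 2\varepsilon}}.
#' Tensile curves are sometimes logged as strain; all modelling here is done
#' in \eqn{\lambda}.
#'
#' @param strain numeric vector of Green strains (dimensionless). Must exceed
#'   -0.5, the collapse limit below which no real stretch exists.
#' @return numeric vector of stretches \eqn{\lambda > 0}.
#' @seealso [green_strain_from_stretch()] for the inverse map.
#' @examples
#' stretch_from_green_strain(0)    # 1: undeformed
#' stretch_from_green_strain(0.1)  # sqrt(1.2), the usual preconditioning strain
#' @export
stretch_from_green_strain <- function(strain) {
  stopifnot(is.numeric(strain))
  if (any(!is.finite(strain)) || any(strain <= -0.5)) {
    stop("Green strain must be finite and > -0.5 (non-physical collapse)",
         call. = FALSE)
  }
  sqrt(1 + 2 * strain)
}

#' @rdname stretch_from_green_strain
#' @param stretch numeric vector of principal stretches, all > 0.
#' @export
green_strain_from_stretch <- function(stretch) {
  check_stretch(stretch)
  (stretch^2 - 1) / 2
}

# shared domain check: lambda strictly positive and finite
check_stretch <- function(stretch) {
  stopifnot(is.numeric(stretch))
  if (any(!is.finite(stretch)) || any(stretch <= 0)) {
    stop("stretch must be finite and > 0", call. = FALSE)
  }
  invisible(stretch)
}

#' Deformation state of incompressible uniaxial tension
#'
#' Builds the diagonal deformation gradient \eqn{F = diag(\lambda,
#' \lambda^{-1/2}, \lambda^{-1/2})} of an incompressible uniaxial extension,
#' the right Cauchy-Green tensor \eqn{C = F^T F}, the volume ratio
#' \eqn{J = \det F} (identically 1 by construction) and the fiber direction
#' \eqn{N = (1, 0, 0)}.
#'
#' @param stretch a single principal stretch \eqn{\lambda > 0} along the
#'   loading axis.
#' @return an object of class `"deformation_state"`: a list with elements
#'   `F`, `C` (3x3 matrices), `J` (scalar) and `N` (unit vector).
#' @examples
#' uniaxial_deformation(1.2)$C   # diag(1.44, 1/1.2, 1/1.2)
#' @export
uniaxial_deformation <- function(stretch) {
  check_stretch(stretch)
  if (length(stretch) != 1L) {
    stop("uniaxial_deformation() takes a single stretch", call. = FALSE)
  }
  lat <- stretch^(-1 / 2)                 # lateral stretches from J = 1
  F_ <- diag(c(stretch, lat, lat))
  C_ <- diag(c(stretch^2, 1 / stretch, 1 / stretch))
  structure(
    list(F = F_, C = C_, J = det(F_), N = c(1, 0, 0)),
    class = "deformation_state"
  )
}

#' @export
print.deformation_state <- function(x, ...) {
  cat("Incompressible uniaxial deformation state\n")
  cat("  lambda =", format(x$F[1, 1]), " J =", format(x$J), "\n")
  cat("  diag(C) =", paste(format(diag(x$C)), collapse = ", "), "\n")
  invisible(x)
}

#' Strain invariants of incompressible uniaxial tension
#'
#' For a stretch \eqn{\lambda} along the fiber axis with incompressible
#' lateral contraction, the first invariant is
#' \eqn{I_1 = \lambda^2 + 2/\lambda} and the fiber invariant is
#' \eqn{I_4 = N \cdot C \cdot N^T = \lambda^2}, so the fiber elongation is
#' \eqn{\alpha = \sqrt{I_4} = \lambda}. \eqn{I_1 \ge 3} with equality only at
#' \eqn{\lambda = 1}.
#'
#' @param stretch numeric vector of stretches, all > 0.
#' @return a data frame of class `"uniaxial_state"` with columns `stretch`,
#'   `green_strain`, `I1`, `I4` and `alpha`, one row per stretch.
#' @examples
#' invariants_uniaxial(c(1, 1.1, 2))
#' @export
invariants_uniaxial <- function(stretch) {
  check_stretch(stretch)
  out <- data.frame(
    stretch      = stretch,
    green_strain = green_strain_from_stretch(stretch),
    I1           = stretch^2 + 2 / stretch,
    I4           = stretch^2,
    alpha        = stretch
  )
  class(out) <- c("uniaxial_state", "data.frame")
  out
}
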