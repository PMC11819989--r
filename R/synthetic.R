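# Seeded generators for synthetic study inputs: tensile stress-stretch
# curves drawn from the constitutive model plus additive Gaussian noise,
# and binary fiber masks with an exactly prescribed fiber fraction.

#' Generate a synthetic stress-stretch curve
#'
#' Evaluates the closed-form Cauchy stress of `params` on a stretch grid
#' and adds homoscedastic Gaussian noise,
#' \eqn{\sigma_i = \sigma_{11}(\lambda_i) + e_i}, \eqn{e_i \sim N(0,
#' \texttt{noise\_sd}^2)}. The defaults emulate the tensile protocol the
#' model targets: 30 points over stretches 1 to 1.20 (the regime where PDL
#' stress stays below ~1.4 MPa) and a noise floor of 0.01 MPa, well under
#' the peak stresses so that parameter recovery is well-posed but not
#' trivial. Identical `seed` and arguments reproduce the curve exactly.
#'
#' @param params a [material_params()] object (e.g. a [pdl_region_presets()]
#'   entry).
#' @param stretch strictly increasing grid starting at >= 1.
#' @param noise_sd additive noise standard deviation, MPa, >= 0.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @param region,tooth,rate labels for the curve; region/tooth default to
#'   the preset's attributes when present.
#' @return a [stress_strain_curve()].
#' @examples
#' p <- pdl_region_presets()[["middle_central"]]
#' generate_curve(p, noise_sd = 0.01, seed = 42)
#' @export
generate_curve <- function(params,
                           stretch = seq(1, 1.20, length.out = 30),
                           noise_sd = 0.01, seed = NULL,
                           region = attr(params, "region"),
                           tooth = attr(params, "tooth"),
                           rate = NA_character_) {
  params <- as_material_params(params)
  stopifnot(is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd >= 0)
  clean <- cauchy_stress_uniaxial(stretch, params)
  if (!is.null(seed)) set.seed(seed)
  noise <- if (noise_sd > 0) stats::rnorm(length(stretch), 0, noise_sd) else 0
  stress_strain_curve(stretch, clean + noise,
                      region = if (is.null(region)) NA_character_ else region,
                      tooth = if (is.null(tooth)) NA_character_ else tooth,
                      rate = rate)
}

#' Generate a binary fiber mask with an exact target fraction
#'
#' Places exactly `round(target_vf * h * w)` fiber pixels uniformly at
#' random (seeded) in an `h x w` frame, so that [mask_fraction()] over the
#' full frame recovers `round(target_vf * h * w) / (h * w)` exactly. This
#' emulates the segmented output of stained-section image analysis, not the
#' spatial texture of real fiber bundles.
#'
#' @param target_vf fiber fraction in `[0, 1]`.
#' @param shape integer vector `c(height, width)`, both >= 1.
#' @param seed optional integer seed.
#' @return logical `height x width` matrix, `TRUE` = fiber.
#' @examples
#' m <- generate_fiber_mask(0.52, shape = c(64, 64), seed = 7)
#' mask_fraction(m)
#' @export
generate_fiber_mask <- function(target_vf, shape = c(512, 512),
                                seed = NULL) {
  if (!is.numeric(target_vf) || length(target_vf) != 1L ||
      target_vf < 0 || target_vf > 1) {
    stop("target_vf must be a single fraction in [0, 1]", call. = FALSE)
  }
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(is.na(shape)) || any(shape < 1L)) {
    stop("shape must be two positive integers c(height, width)",
         call. = FALSE)
  }
  n <- prod(shape)
  n_fiber <- round(target_vf * n)
  if (!is.null(seed)) set.seed(seed)
  mask <- logical(n)
  mask[sample.int(n, n_fiber)] <- TRUE
  matrix(mask, nrow = shape[1], ncol = shape[2])
}
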