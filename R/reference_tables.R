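# Published reference measurements for the anterior-tooth PDL study system:
# specimen geometry, per-section fiber fractions, and the fitted free
# coefficient triplets per region/tooth. These are inputs to the package's
# fixtures, presets and worked examples.

#' Specimen dimensions of the alveolar bone-PDL-dentin samples
#'
#' Rectangular tensile specimens cut perpendicular to the tooth long axis,
#' one per root region (neck / middle / apex) and tooth (central / lateral
#' incisor). The cross-section used for stress conversion is
#' `length x width`; the 0.25 mm slice thickness is not part of it.
#'
#' @return data frame with columns `region`, `tooth`, `length_mm`,
#'   `width_mm`, `thickness_mm`.
#' @examples
#' d <- pdl_sample_dimensions()
#' area_from_dimensions(d$length_mm, d$width_mm)
#' @export
pdl_sample_dimensions <- function() {
  data.frame(
    region = rep(c("neck", "middle", "apex"), 2),
    tooth  = rep(c("central", "lateral"), each = 3),
    length_mm = c(2.53, 2.60, 2.23, 2.27, 2.40, 2.57),
    width_mm  = c(2.16, 2.08, 2.20, 2.22, 1.96, 2.03),
    thickness_mm = rep(0.25, 6)
  )
}

#' Per-section collagen fiber fractions by root region
#'
#' Fiber area fractions (percent) measured on five Masson-stained sections
#' per root region. Regional means: neck 60.312, middle 63.142, apex
#' 51.988 percent.
#'
#' @return data frame with columns `region`, `section_id`, `vf` (percent).
#' @examples
#' region_summary(pdl_section_fractions())
#' @export
pdl_section_fractions <- function() {
  data.frame(
    region = rep(c("neck", "middle", "apex"), each = 5),
    section_id = rep(1:5, 3),
    vf = c(60.007, 51.991, 53.889, 67.895, 67.78,
           58.249, 65.771, 65.65, 61.369, 64.669,
           62.198, 59.01, 41.2, 51.417, 46.116)
  )
}

# regional mean fiber fractions as fractions of 1, derived from the section
# table (not hard-coded separately, so the two surfaces cannot drift)
region_mean_vf <- function() {
  s <- region_summary(pdl_section_fractions())
  stats::setNames(s$mean_vf / 100, s$region)
}

#' Fitted free-coefficient presets per region and tooth
#'
#' The six region/tooth parameter sets of the constrained three-coefficient
#' model: free triplets `(c1, c3, c5)` with `c2`, `c4`, `c6` expanded
#' through the default [constraint_set()] and the fiber fraction set to the
#' regional mean of [pdl_section_fractions()]. These presets drive the
#' synthetic curve generator and the worked examples.
#'
#' @param constraints a [constraint_set()] used for the expansion.
#' @return a named list of six [material_params()] objects, names like
#'   `"neck_central"`, each with attributes `region`, `tooth` and `free`
#'   (the generating triplet).
#' @examples
#' pdl_region_presets()[["apex_central"]]
#' @export
pdl_region_presets <- function(constraints = constraint_set()) {
  triplets <- list(
    neck_central   = c(25.57, 9.76, -6.61),
    neck_lateral   = c(-7.13, 40.93, 55.60),
    middle_central = c(24.30, -15.23, 18.00),
    middle_lateral = c(35.33, -16.01, 20.90),
    apex_central   = c(8.12, 0.58, 1.69),
    apex_lateral   = c(8.31, 7.05, -4.27)
  )
  vf <- region_mean_vf()
  out <- lapply(names(triplets), function(nm) {
    region <- sub("_.*$", "", nm)
    p <- expand_constraints(triplets[[nm]], vf = vf[[region]],
                            constraints = constraints)
    attr(p, "region") <- region
    attr(p, "tooth") <- sub("^.*_", "", nm)
    attr(p, "free") <- triplets[[nm]]
    p
  })
  stats::setNames(out, names(triplets))
}
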