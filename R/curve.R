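# The stress_strain_curve container: paired (stretch, stress) samples from
# one tensile test, with region/tooth/rate metadata. A plain data frame
# underneath so base tools keep working.

#' Construct a stress-stretch curve
#'
#' A validated container for one uniaxial tensile curve: an ordered stretch
#' grid and the matching axial Cauchy stresses in MPa, labelled by root
#' region (neck / middle / apex), tooth (central / lateral incisor) and
#' loading rate. Loading rate is metadata only: the hyperelastic model is
#' rate-independent.
#'
#' @param stretch strictly increasing numeric vector with `stretch[1] >= 1`.
#' @param stress numeric vector of Cauchy stresses, MPa, same length.
#' @param region,tooth,rate optional character labels.
#' @return a data frame of class `"stress_strain_curve"` with columns
#'   `stretch` and `stress` and attributes `region`, `tooth`, `rate`.
#' @examples
#' stress_strain_curve(c(1, 1.1, 1.2), c(0, 0.05, 0.3), region = "apex")
#' @export
stress_strain_curve <- function(stretch, stress, region = NA_character_,
                                tooth = NA_character_, rate = NA_character_) {
  stopifnot(is.numeric(stretch), is.numeric(stress))
  if (length(stretch) == 0L) stop("empty curve", call. = FALSE)
  if (length(stretch) != length(stress)) {
    stop("stretch and stress must have equal length", call. = FALSE)
  }
  if (any(!is.finite(stretch)) || any(!is.finite(stress))) {
    stop("curve contains non-finite values", call. = FALSE)
  }
  if (stretch[1] < 1) {
    stop("curve must start at stretch >= 1 (tensile loading)", call. = FALSE)
  }
  if (length(stretch) > 1L && any(diff(stretch) <= 0)) {
    stop("stretch must be strictly increasing", call. = FALSE)
  }
  structure(
    data.frame(stretch = stretch, stress = stress),
    region = as.character(region), tooth = as.character(tooth),
    rate = as.character(rate),
    class = c("stress_strain_curve", "data.frame")
  )
}

curve_label <- function(curve) {
  lab <- c(attr(curve, "region"), attr(curve, "tooth"), attr(curve, "rate"))
  lab <- lab[!is.na(lab) & lab != "NA"]
  if (length(lab) == 0) "unlabelled" else paste(lab, collapse = ", ")
}

#' @export
print.stress_strain_curve <- function(x, ...) {
  cat(sprintf("Stress-stretch curve (%s): %d points, stretch [%g, %g], peak stress %.4g MPa\n",
              curve_label(x), nrow(x), min(x$stretch), max(x$stretch),
              max(x$stress)))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' @export
plot.stress_strain_curve <- function(x, ...,
                                     xlab = "stretch (strain ratio)",
                                     ylab = expression(sigma[11] ~ (MPa)),
                                     main = NULL) {
  if (is.null(main)) main <- curve_label(x)
  graphics::plot(x$stretch, x$stress, xlab = xlab, ylab = ylab,
                 main = main, ...)
  invisible(x)
}
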