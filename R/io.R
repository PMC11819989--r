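# Readers/writers and specimen-geometry utilities. Curve files are
# delimited text with a mandatory header, decimal point, UTF-8; the stretch
# column may alternatively be given as Green strain and is converted on
# read.

#' Cross-sectional area from specimen dimensions
#'
#' The reference cross-section used for stress conversion is the in-plane
#' product `length x width` in mm^2 (slice thickness is not part of it).
#' Reported to 4 decimals in specimen tables.
#'
#' @param length,width specimen dimensions in mm, > 0 (vectorised).
#' @return area in mm^2.
#' @examples
#' area_from_dimensions(2.53, 2.16)  # 5.4648
#' @export
area_from_dimensions <- function(length, width) {
  stopifnot(is.numeric(length), is.numeric(width))
  if (any(!is.finite(length)) || any(!is.finite(width)) ||
      any(length <= 0) || any(width <= 0)) {
    stop("dimensions must be finite and > 0", call. = FALSE)
  }
  length * width
}

#' First Piola-Kirchhoff (engineering) stress from measured force
#'
#' `P = Fu / A0`: tensile force over the undeformed cross-section. N over
#' mm^2 gives MPa directly.
#'
#' @param force tensile force, N.
#' @param area0 undeformed cross-sectional area, mm^2, > 0.
#' @return engineering stress, MPa.
#' @export
pk1_from_force <- function(force, area0) {
  stopifnot(is.numeric(force), is.numeric(area0))
  if (any(!is.finite(area0)) || any(area0 <= 0)) {
    stop("area0 must be finite and > 0", call. = FALSE)
  }
  force / area0
}

#' Cauchy stress from measured force
#'
#' Under incompressibility (J = 1) the true stress relates to the
#' engineering stress by \eqn{\sigma_{11} = \lambda F_u / A_0}: the current
#' cross-section shrinks by the factor \eqn{1/\lambda}.
#'
#' @param stretch stretch \eqn{\lambda} at which the force was recorded.
#' @param force tensile force, N.
#' @param area0 undeformed cross-sectional area, mm^2, > 0.
#' @return Cauchy stress \eqn{\sigma_{11}}, MPa.
#' @examples
#' cauchy_from_force(1.1, 1, 5.4648)
#' @export
cauchy_from_force <- function(stretch, force, area0) {
  check_stretch(stretch)
  stretch * pk1_from_force(force, area0)
}

#' Read a stress-stretch curve from delimited text
#'
#' Expects a header with a `stress` (or `stress_MPa`) column and either a
#' `stretch` column or a Green-`strain` column; strain is converted through
#' \eqn{\lambda = \sqrt{1 + 2\varepsilon}}. Region/tooth/rate labels may be
#' passed or recovered from columns of the same names (first value used).
#'
#' @param path file path.
#' @param delimiter field separator, default comma.
#' @param region,tooth,rate optional label overrides.
#' @return a [stress_strain_curve()].
#' @seealso [write_curve()]
#' @export
read_curve <- function(path, delimiter = ",", region = NULL, tooth = NULL,
                       rate = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  if (nrow(df) == 0L) stop("empty curve: ", path, call. = FALSE)
  names(df) <- tolower(names(df))
  stress_col <- intersect(c("stress", "stress_mpa"), names(df))
  if (length(stress_col) == 0L) {
    stop("missing stress column (stress or stress_MPa) in ", path,
         call. = FALSE)
  }
  stress <- df[[stress_col[1]]]
  if ("stretch" %in% names(df)) {
    stretch <- df$stretch
  } else if ("strain" %in% names(df)) {
    stretch <- stretch_from_green_strain(df$strain)
  } else {
    stop("missing stretch or strain column in ", path, call. = FALSE)
  }
  bad <- which(!is.finite(stretch) | !is.finite(stress))
  if (length(bad)) {
    stop("non-numeric or missing values at data line(s) ",
         paste(bad, collapse = ", "), " of ", path, call. = FALSE)
  }
  grab <- function(override, col) {
    if (!is.null(override)) return(override)
    if (col %in% names(df)) as.character(df[[col]][1]) else NA_character_
  }
  stress_strain_curve(stretch, stress,
                      region = grab(region, "region"),
                      tooth = grab(tooth, "tooth"),
                      rate = grab(rate, "rate"))
}

#' Write a stress-stretch curve to delimited text
#'
#' Columns `stretch`, `stress` plus any non-missing labels; reading the
#' file back reproduces the curve exactly (doubles are written at full
#' precision).
#'
#' @param curve a [stress_strain_curve()].
#' @param path output file path.
#' @param delimiter field separator, default comma.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, delimiter = ",") {
  stopifnot(inherits(curve, "stress_strain_curve"))
  df <- data.frame(stretch = format(curve$stretch, digits = 17),
                   stress = format(curve$stress, digits = 17))
  for (lab in c("region", "tooth", "rate")) {
    v <- attr(curve, lab)
    if (!is.na(v) && v != "NA") df[[lab]] <- v
  }
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a binary mask from a PNG or TIFF image
#'
#' Convenience reader for segmented-section masks. Requires the `png` or
#' `tiff` package for the respective format. Pixels above `threshold`
#' (on the 0-1 intensity scale) are foreground.
#'
#' @param path image path ending in `.png`, `.tif` or `.tiff`.
#' @param threshold intensity cut, default 0.5.
#' @return logical matrix.
#' @export
read_mask <- function(path, threshold = 0.5) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG masks requires the 'png' package", call. = FALSE)
    }
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF masks requires the 'tiff' package", call. = FALSE)
    }
    tiff::readTIFF(path)
  } else {
    stop("unsupported mask format: .", ext, call. = FALSE)
  }
  as_mask(img >= threshold, "mask")
}

#' Write a fit report to JSON
#'
#' Serialises a fitted model: free and full coefficients, fixed fiber
#' fraction, goodness of fit, residual diagnostics, convergence record and
#' the initial point, so a run is auditable from its report.
#'
#' @param fit a `"pdl_fit"`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "pdl_fit"))
  report <- list(
    label = curve_label(fit$curve),
    free = as.list(fit$coefficients),
    coefficients = as.list(coef(fit, full = TRUE)),
    vf = fit$vf,
    constrained = !is.null(fit$constraints),
    r_squared = fit$r_squared,
    residual_norm = fit$residual_norm,
    n_points = fit$n_points,
    converged = fit$converged,
    iterations = fit$niter,
    init = fit$init,
    multistart = fit$multistart
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
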