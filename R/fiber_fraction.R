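# Collagen fiber volume fraction from segmented histology sections.
# Masson staining renders collagen blue; segmentation (done upstream, e.g.
# interactively in ImageJ) yields a binary fiber mask and a region of
# interest (ROI). The "volume" fraction is measured as an area fraction on
# 2-D sections, with no stereological correction: Vf = Px / PI for fiber
# pixel count Px inside an ROI of PI pixels.

#' Fiber volume fraction from pixel counts
#'
#' `Vf = Px / PI`: fiber area over ROI area, both in the same units
#' (typically pixel counts on one section). This count-based entry point is
#' strict: fiber area exceeding the ROI area is an error (it means the
#' segmentation leaked outside the ROI).
#'
#' @param px fiber area (pixel count), `0 <= px <= pi_area`.
#' @param pi_area ROI area (pixel count), > 0.
#' @return fiber fraction(s) in `[0, 1]`.
#' @examples
#' volume_fraction(6, 10)  # 0.6
#' @export
volume_fraction <- function(px, pi_area) {
  stopifnot(is.numeric(px), is.numeric(pi_area))
  if (any(!is.finite(px)) || any(!is.finite(pi_area))) {
    stop("areas must be finite", call. = FALSE)
  }
  if (any(pi_area <= 0)) stop("ROI area must be > 0", call. = FALSE)
  if (any(px < 0)) stop("fiber area must be >= 0", call. = FALSE)
  if (any(px > pi_area)) {
    stop("fiber area exceeds ROI area (segmentation outside ROI)",
         call. = FALSE)
  }
  px / pi_area
}

# coerce an image-like object (logical/numeric matrix or array) to a
# logical matrix; nonzero means foreground
as_mask <- function(m, what) {
  if (is.array(m) && length(dim(m)) == 3L) m <- m[, , 1L]  # first channel
  if (!is.matrix(m)) stop(what, " must be a matrix", call. = FALSE)
  if (is.logical(m)) return(m)
  if (is.numeric(m)) return(m != 0)
  stop(what, " must be logical or numeric", call. = FALSE)
}

#' Fiber fraction from binary masks
#'
#' Counts fiber pixels inside the ROI and divides by the ROI pixel count.
#' Fiber pixels outside the ROI are clipped, not treated as an error:
#' interactively traced ROIs routinely overlap a segmentation computed on
#' the whole frame. With `roi_mask = NULL` the whole image is the ROI.
#'
#' @param fiber_mask logical/0-1 matrix (or array, first channel used);
#'   `TRUE`/nonzero marks collagen fiber.
#' @param roi_mask matching matrix marking the region of interest, with at
#'   least one `TRUE` pixel, or `NULL` for the full frame.
#' @return fiber fraction in `[0, 1]`.
#' @examples
#' m <- matrix(c(1, 1, 0, 0), 2, 2)
#' mask_fraction(m)  # 0.5
#' @export
mask_fraction <- function(fiber_mask, roi_mask = NULL) {
  fiber <- as_mask(fiber_mask, "fiber_mask")
  if (is.null(roi_mask)) {
    roi <- matrix(TRUE, nrow(fiber), ncol(fiber))
  } else {
    roi <- as_mask(roi_mask, "roi_mask")
  }
  if (!identical(dim(fiber), dim(roi))) {
    stop("fiber_mask and roi_mask dimensions differ", call. = FALSE)
  }
  n_roi <- sum(roi)
  if (n_roi == 0L) stop("ROI mask is empty", call. = FALSE)
  sum(fiber & roi) / n_roi
}

#' Aggregate per-section fiber fractions by root region
#'
#' Averages the per-section fiber fractions within each root region (neck /
#' middle / apex). Input values are averaged on whatever scale they come in
#' (fractions or percentages); the mean always lies between the per-section
#' extremes.
#'
#' @param measurements a data frame with columns `region` and `vf`
#'   (per-section fiber fraction), and optionally `section_id`.
#' @return a data frame of class `"region_fraction_summary"`: one row per
#'   region with `n_sections`, `mean_vf`, `min_vf`, `max_vf`. Means are
#'   reported to full precision; printing rounds to 3 decimals.
#' @examples
#' m <- data.frame(region = "neck",
#'                 vf = c(60.007, 51.991, 53.889, 67.895, 67.78))
#' region_summary(m)  # mean 60.312 (percent scale in, percent scale out)
#' @export
region_summary <- function(measurements) {
  if (!is.data.frame(measurements) ||
      !all(c("region", "vf") %in% names(measurements))) {
    stop("measurements must be a data frame with columns 'region' and 'vf'",
         call. = FALSE)
  }
  if (nrow(measurements) == 0L) stop("no sections supplied", call. = FALSE)
  if (any(!is.finite(measurements$vf))) {
    stop("non-finite fiber fractions", call. = FALSE)
  }
  regions <- unique(as.character(measurements$region))
  out <- do.call(rbind, lapply(regions, function(r) {
    v <- measurements$vf[measurements$region == r]
    data.frame(region = r, n_sections = length(v), mean_vf = mean(v),
               min_vf = min(v), max_vf = max(v))
  }))
  class(out) <- c("region_fraction_summary", "data.frame")
  out
}

#' @export
print.region_fraction_summary <- function(x, ...) {
  cat("Fiber volume fraction by root region\n")
  y <- as.data.frame(x)
  y$mean_vf <- round(y$mean_vf, 3)
  y$min_vf <- round(y$min_vf, 3)
  y$max_vf <- round(y$max_vf, 3)
  print(y, row.names = FALSE)
  invisible(x)
}
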