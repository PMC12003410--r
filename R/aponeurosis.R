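#' Binarize an aponeurosis region
#'
#' Thresholds the pixels inside an aponeurosis ROI with Otsu's method
#' (computed on the ROI pixels only), then applies morphological closing
#' and hole filling to consolidate the band. The result is true only inside
#' the ROI.
#'
#' @param image A [bmode_image()].
#' @param roi An [roi()] of an aponeurosis kind.
#' @param threshold Either `"otsu"` (default) or a fixed numeric threshold
#'   in \[0, 1\].
#' @param closing_radius Side of the square structuring element used for
#'   closing (default 3); 0 disables morphology.
#' @return Logical matrix.
#' @export
binarize_aponeurosis <- function(image, roi, threshold = "otsu",
                                 closing_radius = 3) {
  if (!roi$kind %in% c("superficial_aponeurosis", "deep_aponeurosis")) {
    stop("ROI kind must be an aponeurosis kind, got '", roi$kind, "'",
         call. = FALSE)
  }
  vals <- image$pixels[roi$mask]
  thr <- if (identical(threshold, "otsu")) {
    otsu_threshold(vals)
  } else {
    as.numeric(threshold)
  }
  mask <- image$pixels > thr & roi$mask
  if (!any(mask)) {
    stop(sprintf(
      "aponeurosis not detected in ROI '%s' (threshold %.4f left an empty mask)",
      roi$kind, thr), call. = FALSE)
  }
  if (closing_radius > 0) {
    kern <- EBImage::makeBrush(as.integer(closing_radius), shape = "box")
    m <- EBImage::Image(t(mask) * 1)
    m <- EBImage::closing(m, kern)
    m <- EBImage::fillHull(m)
    mask <- t(EBImage::imageData(m)) > 0.5 & roi$mask
  }
  mask
}

#' Otsu threshold of an intensity sample
#'
#' Histogram-based Otsu threshold on values in \[0, 1\] (256 bins),
#' maximizing between-class variance. Errors when the sample has no
#' spread (a threshold would be meaningless).
#'
#' @param vals Numeric vector of intensities in \[0, 1\].
#' @param levels Number of histogram bins.
#' @return Scalar threshold.
#' @export
otsu_threshold <- function(vals, levels = 256L) {
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L || diff(range(vals)) < .Machine$double.eps) {
    stop("cannot threshold a constant-intensity region", call. = FALSE)
  }
  breaks <- seq(0, 1, length.out = levels + 1L)
  h <- tabulate(pmin(pmax(findInterval(vals, breaks, all.inside = TRUE), 1L),
                     levels), nbins = levels)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  breaks[which.max(sb) + 1L]  # upper edge: `> threshold` excludes the bin
}

#' Remove small connected components
#'
#' Drops 8-connected components with fewer than `min_area_px` pixels,
#' mirroring the exclusion of small regions discontinuous with the
#' aponeurosis. If every component is below the threshold, the single
#' largest component is retained instead, so a non-empty input never
#' becomes empty.
#'
#' @param mask Logical matrix, non-empty.
#' @param min_area_px Minimum component area in pixels.
#' @return Logical matrix.
#' @export
remove_small_regions <- function(mask, min_area_px = 100) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  lab <- label_components(mask, connectivity = 8)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area_px)
  if (length(keep) == 0L) keep <- which.max(areas)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Extract the column-wise midline of a band mask
#'
#' For every column containing foreground, the midline point is
#' `(min_row + max_row) / 2` of the foreground pixels in that column
#' (robust to interior holes); empty columns are skipped. Coordinates are
#' 0-based with x = column, y = row.
#'
#' @param mask Logical matrix, non-empty.
#' @return Tibble with columns `x`, `y`, ordered by strictly increasing `x`.
#' @export
extract_midline <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  cols <- which(colSums(mask) > 0L)
  y <- vapply(cols, function(j) {
    r <- range(which(mask[, j]))
    (r[1] + r[2]) / 2 - 1  # to 0-based
  }, numeric(1))
  tibble::tibble(x = as.numeric(cols - 1L), y = y)
}

#' Fit first- and second-order polynomials to a midline
#'
#' Ordinary least squares fits `y = m x + b` and
#' `y = a2 x^2 + a1 x + a0` in raster coordinates.
#'
#' @param midline Tibble or data frame with `x`, `y` columns.
#' @return List with `linear = c(slope, intercept)` and
#'   `quadratic = c(a2, a1, a0)`.
#' @export
fit_polynomials <- function(midline) {
  x <- midline$x; y <- midline$y
  if (length(unique(x)) < 3L) {
    stop("aponeurosis trace too short: need at least 3 distinct x values",
         call. = FALSE)
  }
  lin <- stats::lm.fit(cbind(1, x), y)$coefficients
  quad <- stats::lm.fit(cbind(1, x, x^2), y)$coefficients
  list(linear = c(slope = unname(lin[2]), intercept = unname(lin[1])),
       quadratic = c(a2 = unname(quad[3]), a1 = unname(quad[2]),
                     a0 = unname(quad[1])))
}

#' Fit an aponeurosis model from an image and ROI
#'
#' Runs the full aponeurosis pipeline: ROI binarization, small-region
#' removal, midline extraction, and polynomial fitting. The linear fit
#' feeds the pennation-angle and fascicle-length geometry; the quadratic
#' fit accounts for aponeurosis curvature in the thickness measurement.
#'
#' @param image A [bmode_image()].
#' @param roi Aponeurosis [roi()].
#' @param cfg Configuration list (see [default_config()]), `aponeurosis`
#'   section.
#' @return An `aponeurosis_model`: role, mask, midline, `linear`,
#'   `quadratic`, `x_extent`.
#' @export
fit_aponeurosis <- function(image, roi, cfg = default_config()) {
  acfg <- cfg$aponeurosis
  mask <- binarize_aponeurosis(image, roi,
                               threshold = acfg$threshold_method,
                               closing_radius = acfg$closing_radius)
  mask <- remove_small_regions(mask, acfg$min_area_px)
  midline <- extract_midline(mask)
  fits <- fit_polynomials(midline)
  role <- if (roi$kind == "superficial_aponeurosis") "superficial" else "deep"
  structure(
    list(role = role, mask = mask, midline = midline,
         linear = fits$linear, quadratic = fits$quadratic,
         x_extent = range(midline$x)),
    class = "aponeurosis_model"
  )
}

#' @export
print.aponeurosis_model <- function(x, ...) {
  cat(sprintf("<aponeurosis_model> %s: slope %.4f, intercept %.1f, x in [%g, %g]\n",
              x$role, x$linear["slope"], x$linear["intercept"],
              x$x_extent[1], x$x_extent[2]))
  invisible(x)
}

eval_linear <- function(fit, x) fit[["slope"]] * x + fit[["intercept"]]
eval_quadratic <- function(fit, x) fit[["a2"]] * x^2 + fit[["a1"]] * x + fit[["a0"]]

# y-up orientation angle (degrees) of a raster-coordinate slope
slope_to_angle_yup <- function(slope) atan(-slope) * 180 / pi
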