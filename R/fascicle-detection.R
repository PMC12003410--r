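#' Adaptive binarization of the parent region
#'
#' Local-mean adaptive thresholding of the muscle region: a pixel is
#' foreground iff its intensity strictly exceeds the mean of its square
#' neighborhood scaled by a sensitivity-derived factor
#' `1.15 - 0.2 * sensitivity`. Higher sensitivity admits more foreground;
#' at the default sensitivity 0.5 the factor is 1.05, slightly above the
#' neutral local mean — thresholding a featureless speckle region exactly
#' at its local mean would mark half of all pixels regardless of the noise
#' level and let noise percolate into large connected clumps. The window
#' side is the odd integer nearest to 1/8 of the smaller ROI bounding-box
#' dimension (minimum 3). The result is restricted to the parent ROI; an
#' all-false result is legal and simply yields zero fascicles downstream.
#'
#' @param image A [bmode_image()].
#' @param parent Parent [roi()].
#' @param sensitivity Real in \[0, 1\]; default 0.5.
#' @param window_divisor Window side = smaller ROI dimension / this
#'   (default 8), rounded to the nearest odd integer.
#' @return Logical matrix.
#' @export
binarize_roi <- function(image, parent, sensitivity = 0.5,
                         window_divisor = 8) {
  stopifnot(sensitivity >= 0, sensitivity <= 1)
  if (!any(parent$mask)) stop("parent ROI is empty", call. = FALSE)
  bb <- which(parent$mask, arr.ind = TRUE)
  dims <- c(diff(range(bb[, 1])) + 1L, diff(range(bb[, 2])) + 1L)
  w <- max(3L, round(min(dims) / window_divisor))
  if (w %% 2L == 0L) w <- w + 1L
  lm <- box_mean(image$pixels, w)
  factor <- 1.15 - 0.2 * sensitivity
  (image$pixels > lm * factor) & parent$mask
}

# Box mean with edge renormalization via integral images.
box_mean <- function(m, w) {
  h <- (w - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  # summed-area table with a zero top row / left column
  sat <- matrix(0, nr + 1L, nc + 1L)
  sat[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
  S <- sat[r2 + 1L, c2 + 1L] - sat[r1, c2 + 1L] -
       sat[r2 + 1L, c1] + sat[r1, c1]
  counts <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  S / counts
}

#' Trace hyperechoic regions and compute their properties
#'
#' Labels the 8-connected components of a binary mask and computes, for
#' each, the properties used by the fascicle filter: area, centroid,
#' orientation, eccentricity, and major-axis length of the ellipse with
#' identical normalized second central moments (regionprops convention,
#' including the 1/12 px single-pixel variance correction), plus the
#' ordered outer-boundary trace. Orientation is reported y-up in
#' (-90, 90]: positive angles rise toward the skin as x increases.
#' Moment-degenerate regions (perfect squares/discs) get orientation 0 and
#' eccentricity 0.
#'
#' @param mask Logical matrix.
#' @param trace_boundaries Include the ordered boundary contour of each
#'   region (list-column `boundary` of (x, y) matrices, 0-based).
#' @return Tibble with one row per region: `label`, `area_px`,
#'   `centroid_x`, `centroid_y`, `orientation_deg`, `eccentricity`,
#'   `major_axis_len_px`, and optionally `boundary`. Empty mask gives an
#'   empty tibble.
#' @export
trace_regions <- function(mask, trace_boundaries = TRUE) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  lab <- label_components(mask, connectivity = 8)
  n_reg <- max(lab)
  empty <- tibble::tibble(
    label = integer(0), area_px = integer(0),
    centroid_x = numeric(0), centroid_y = numeric(0),
    orientation_deg = numeric(0), eccentricity = numeric(0),
    major_axis_len_px = numeric(0)
  )
  if (n_reg == 0L) {
    if (trace_boundaries) empty$boundary <- list()
    return(empty)
  }
  idx <- which(lab > 0L)
  lb <- lab[idx]
  y <- ((idx - 1L) %% nrow(mask))        # 0-based row
  x <- ((idx - 1L) %/% nrow(mask))       # 0-based col
  props <- lapply(seq_len(n_reg), function(k) {
    sel <- lb == k
    region_moments(x[sel], y[sel])
  })
  out <- dplyr::bind_rows(props)
  out$label <- seq_len(n_reg)
  out <- out[, c("label", "area_px", "centroid_x", "centroid_y",
                 "orientation_deg", "eccentricity", "major_axis_len_px")]
  if (trace_boundaries) {
    oc <- EBImage::ocontour(EBImage::Image(t(lab)))
    # ocontour works on the transposed image, so its dim1 = original column;
    # coordinates come back 0-based as (x, y) already
    out$boundary <- lapply(seq_len(n_reg), function(k) {
      b <- oc[[k]]
      colnames(b) <- c("x", "y")
      b
    })
  }
  out
}

# Ellipse-equivalent properties from second central moments of pixel
# coordinates (0-based). The +1/12 terms are the variance of a unit pixel,
# so single-pixel-wide regions keep a finite minor axis.
region_moments <- function(x, y) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  uxx <- sum((x - xb)^2) / n + 1 / 12
  uyy <- sum((y - yb)^2) / n + 1 / 12
  uxy <- -sum((x - xb) * (y - yb)) / n  # y-up sign flip
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  major <- 2 * sqrt(2) * sqrt(uxx + uyy + common)
  minor <- 2 * sqrt(2) * sqrt(pmax(uxx + uyy - common, 0))
  degenerate <- common < 1e-12
  tibble::tibble(
    area_px = n,
    centroid_x = xb,
    centroid_y = yb,
    orientation_deg = if (degenerate) 0 else
      0.5 * atan2(2 * uxy, uxx - uyy) * 180 / pi,
    eccentricity = if (degenerate) 0 else
      sqrt(1 - (minor / major)^2),
    major_axis_len_px = major
  )
}

#' Fascicle candidate filter configuration
#'
#' Area between 75 and 6,000 px (inclusive), eccentricity at least 0.90,
#' and centroid strictly between the first-order aponeurosis fits.
#'
#' @param area_min_px,area_max_px Inclusive area bounds in pixels.
#' @param eccentricity_min Minimum eccentricity.
#' @return A list of class `fascicle_filter_config`.
#' @export
fascicle_filter_config <- function(area_min_px = 75, area_max_px = 6000,
                                   eccentricity_min = 0.90) {
  stopifnot(area_min_px > 0, area_min_px < area_max_px,
            eccentricity_min >= 0, eccentricity_min <= 1)
  structure(list(area_min_px = area_min_px, area_max_px = area_max_px,
                 eccentricity_min = eccentricity_min),
            class = "fascicle_filter_config")
}

#' Filter regions to line-like fascicle candidates
#'
#' Keeps regions with `area_min_px <= area <= area_max_px` (inclusive),
#' `eccentricity >= eccentricity_min`, and centroid strictly between the
#' first-order line fits of the superficial and deep aponeuroses
#' (`superficial_y(cx) < cy < deep_y(cx)` in raster coordinates). Input
#' order is preserved.
#'
#' @param regions Tibble from [trace_regions()].
#' @param superficial_linear,deep_linear Named vectors
#'   `c(slope =, intercept =)` of the aponeurosis linear fits.
#' @param cfg A [fascicle_filter_config()].
#' @return Filtered tibble.
#' @export
filter_fascicle_candidates <- function(regions, superficial_linear,
                                       deep_linear,
                                       cfg = fascicle_filter_config()) {
  if (nrow(regions) == 0L) return(regions)
  sup_y <- eval_linear(superficial_linear, regions$centroid_x)
  deep_y <- eval_linear(deep_linear, regions$centroid_x)
  keep <- regions$area_px >= cfg$area_min_px &
    regions$area_px <= cfg$area_max_px &
    regions$eccentricity >= cfg$eccentricity_min &
    sup_y < regions$centroid_y &
    regions$centroid_y < deep_y
  regions[keep, , drop = FALSE]
}
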