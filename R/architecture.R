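#' Pennation angle relative to the deep aponeurosis
#'
#' Absolute difference between the fascicle and deep-aponeurosis
#' orientations (both y-up, degrees), folded into \[0, 90\] — lines are
#' axial, so 160 deg apart means 20 deg apart. Measuring against the deep
#' aponeurosis (rather than the image horizontal) makes the angle invariant
#' to aponeurosis angulation during contraction.
#'
#' @param fascicle_orientation_deg,deep_orientation_deg y-up angles in
#'   (-90, 90\].
#' @return Angle in degrees in \[0, 90\].
#' @export
#' @examples
#' compute_pennation_angle(20, 5)    # 15
#' compute_pennation_angle(-80, 80)  # 20 (axial folding)
compute_pennation_angle <- function(fascicle_orientation_deg,
                                    deep_orientation_deg) {
  d <- abs(fascicle_orientation_deg - deep_orientation_deg) %% 180
  ifelse(d > 90, 180 - d, d)
}

#' Fascicle length from aponeurosis intersection points
#'
#' Euclidean distance between the two intersection points, converted to cm
#' via the pixel calibration:
#' `sqrt((x_deep - x_sup)^2 + (y_deep - y_sup)^2) / pixels_per_mm / 10`.
#'
#' @param p_superficial,p_deep Numeric `(x, y)` points in pixels.
#' @param calibration [calibration_info()] or pixels-per-mm scalar.
#' @return Length in cm.
#' @export
#' @examples
#' compute_fascicle_length(c(0, 0), c(300, 400), 10)  # 5 cm
compute_fascicle_length <- function(p_superficial, p_deep, calibration) {
  d_px <- sqrt(sum((p_deep - p_superficial)^2))
  if (d_px == 0) stop("intersection points coincide", call. = FALSE)
  px_to_cm(d_px, calibration)
}

#' Extrapolate a fascicle candidate to the aponeurosis fits
#'
#' The fascicle line passes through the region centroid with slope
#' `-tan(orientation)` (orientation is y-up; raster y grows downward) and
#' is intersected in closed form with the first-order fits of both
#' aponeuroses. The candidate is accepted iff both intersections exist
#' within the extrapolation domain. Extrapolation beyond the image extent
#' is expected — fascicle lengths routinely exceed the field of view in
#' linear-extrapolation methods — but the domain is finite, mirroring
#' segment-based intersection testing: with `x_bounds` the ROI x-extent
#' and a domain extension of `extend_widths` ROI widths on either side
#' (default 4, about 20 cm of reach at a 5 cm aperture, beyond the
#' physiologic fascicle range), a near-parallel line whose intersections
#' lie farther out is rejected rather than yielding a non-physical length.
#'
#' @param region One-row tibble from [trace_regions()] (or a list with
#'   `label`, `centroid_x`, `centroid_y`, `orientation_deg`).
#' @param superficial_linear,deep_linear Linear fits
#'   `c(slope =, intercept =)`.
#' @param calibration [calibration_info()] or pixels-per-mm scalar.
#' @param x_bounds ROI x-extent `c(x_min, x_max)` in pixels; `NULL`
#'   disables the domain bound (pure infinite-line intersection).
#' @param extend_widths Extrapolation domain extension in ROI widths.
#' @return A one-row tibble (`region_label`, `slope`, `intercept`,
#'   `x_superficial`, `y_superficial`, `x_deep`, `y_deep`,
#'   `orientation_deg`, `pennation_deg`, `fascicle_length_cm`); on
#'   rejection, a zero-row tibble whose `rejection` attribute is
#'   `"parallel"` (fascicle parallel to an aponeurosis fit) or
#'   `"out_of_domain"` (an intersection falls outside the extrapolation
#'   domain).
#' @export
extrapolate_and_intersect <- function(region, superficial_linear, deep_linear,
                                      calibration, x_bounds = NULL,
                                      extend_widths = 4) {
  theta <- region$orientation_deg
  m_f <- -tan(theta * pi / 180)
  b_f <- region$centroid_y - m_f * region$centroid_x
  p_sup <- line_intersection(m_f, b_f, superficial_linear)
  p_deep <- line_intersection(m_f, b_f, deep_linear)
  if (is.null(p_sup) || is.null(p_deep)) {
    return(fascicle_rejection("parallel"))
  }
  if (!is.null(x_bounds)) {
    w <- diff(range(x_bounds))
    domain <- c(x_bounds[1] - extend_widths * w,
                x_bounds[2] + extend_widths * w)
    xs <- c(p_sup[1], p_deep[1])
    if (any(xs < domain[1] | xs > domain[2])) {
      return(fascicle_rejection("out_of_domain"))
    }
  }
  deep_angle <- slope_to_angle_yup(deep_linear[["slope"]])
  pa <- compute_pennation_angle(theta, deep_angle)
  fl <- compute_fascicle_length(p_sup, p_deep, calibration)
  tibble::tibble(
    region_label = region$label,
    slope = m_f, intercept = b_f,
    x_superficial = p_sup[1], y_superficial = p_sup[2],
    x_deep = p_deep[1], y_deep = p_deep[2],
    orientation_deg = theta,
    pennation_deg = pa,
    fascicle_length_cm = fl
  )
}

fascicle_rejection <- function(reason) {
  structure(tibble::tibble(), rejection = reason)
}

# Intersection of y = m x + b with an aponeurosis linear fit; NULL when
# parallel (|slope difference| < 1e-9).
line_intersection <- function(m, b, fit) {
  dm <- fit[["slope"]] - m
  if (abs(dm) < 1e-9) return(NULL)
  x <- (b - fit[["intercept"]]) / dm
  c(x, m * x + b)
}

#' Muscle thickness between the second-order aponeurosis fits
#'
#' Thickness is evaluated at the 20%, 50%, and 80% positions of the imaged
#' aperture (the parent ROI x-extent) as the vertical distance between the
#' quadratic fits of the deep and superficial aponeuroses, converted to cm.
#' The quadratic fits absorb aponeurosis curvature during contraction. A
#' perpendicular mode is available for sensitivity analysis.
#'
#' @param superficial_quadratic,deep_quadratic Quadratic fits
#'   `c(a2 =, a1 =, a0 =)`.
#' @param roi_x_extent Numeric `c(x_min, x_max)` in pixels.
#' @param calibration [calibration_info()] or pixels-per-mm scalar.
#' @param positions_frac Aperture fractions (default 0.2, 0.5, 0.8).
#' @param mode `"vertical"` (default) or `"perpendicular"`.
#' @return A `thickness_measure` list: `positions_frac`, `x_positions_px`,
#'   `thickness_cm`, `mean_thickness_cm`.
#' @export
measure_thickness <- function(superficial_quadratic, deep_quadratic,
                              roi_x_extent, calibration,
                              positions_frac = c(0.2, 0.5, 0.8),
                              mode = c("vertical", "perpendicular")) {
  mode <- match.arg(mode)
  xp <- roi_x_extent[1] + positions_frac * diff(roi_x_extent)
  d_px <- eval_quadratic(deep_quadratic, xp) -
    eval_quadratic(superficial_quadratic, xp)
  if (any(d_px <= 0)) {
    stop("crossed aponeurosis fits: non-positive thickness at x = ",
         paste(signif(xp[d_px <= 0], 5), collapse = ", "), call. = FALSE)
  }
  if (mode == "perpendicular") {
    # project the vertical gap onto the local normal of the mid-surface
    slope_mid <- (2 * superficial_quadratic[["a2"]] * xp +
                    superficial_quadratic[["a1"]] +
                    2 * deep_quadratic[["a2"]] * xp +
                    deep_quadratic[["a1"]]) / 2
    d_px <- d_px / sqrt(1 + slope_mid^2)
  }
  th <- px_to_cm(d_px, calibration)
  structure(
    list(positions_frac = positions_frac, x_positions_px = xp,
         thickness_cm = th, mean_thickness_cm = mean(th), mode = mode),
    class = "thickness_measure"
  )
}

#' Manual-method fascicle length
#'
#' The manual reference formula `FL = MT / sin(PA)`: fascicle length from
#' muscle thickness and pennation angle under the straight-fascicle,
#' parallel-aponeurosis assumption.
#'
#' @param mt_cm Muscle thickness in cm (> 0).
#' @param pa_deg Pennation angle in degrees, in (0, 180).
#' @return Fascicle length in cm.
#' @export
#' @examples
#' manual_fascicle_length(2.0, 30)  # 4
manual_fascicle_length <- function(mt_cm, pa_deg) {
  if (any(pa_deg <= 0 | pa_deg >= 180)) {
    stop("pennation angle must lie strictly between 0 and 180 degrees",
         call. = FALSE)
  }
  if (any(mt_cm <= 0)) stop("muscle thickness must be positive", call. = FALSE)
  mt_cm / sin(pa_deg * pi / 180)
}

#' Analyze one B-mode image
#'
#' Runs the full semi-automated pipeline: fits both aponeuroses (binarize,
#' clean, midline, polynomials), measures thickness between the quadratic
#' fits, adaptively binarizes the parent ROI, traces and filters
#' hyperechoic regions, and extrapolates each accepted fascicle to the
#' linear aponeurosis fits for pennation angle and fascicle length. The
#' result is deterministic given (image, rois, cfg).
#'
#' @param image A [bmode_image()].
#' @param rois List of the three [roi()]s (any order; kinds identify them).
#' @param cfg Configuration from [default_config()].
#' @return A `muscle_architecture` object: `image_id`, `fascicles` tibble,
#'   `thickness`, `summary`, the two `aponeuroses`, rejection counts, and
#'   a config snapshot. `tidy()` returns the fascicle table, `glance()`
#'   the one-row summary.
#' @export
analyze_image <- function(image, rois, cfg = default_config()) {
  rois <- check_roi_set(rois)
  sup <- with_stage("superficial aponeurosis",
                    fit_aponeurosis(image, rois$superficial_aponeurosis, cfg))
  deep <- with_stage("deep aponeurosis",
                     fit_aponeurosis(image, rois$deep_aponeurosis, cfg))
  shared <- c(max(sup$x_extent[1], deep$x_extent[1]),
              min(sup$x_extent[2], deep$x_extent[2]))
  if (any(eval_linear(sup$linear, shared) >= eval_linear(deep$linear, shared))) {
    stop("superficial aponeurosis fit does not lie above the deep fit over ",
         "the shared extent; check ROI kinds", call. = FALSE)
  }
  parent <- rois$parent
  pb <- which(parent$mask, arr.ind = TRUE)
  parent_x_extent <- c(min(pb[, 2]), max(pb[, 2])) - 1  # 0-based
  thickness <- with_stage("thickness",
    measure_thickness(sup$quadratic, deep$quadratic, parent_x_extent,
                      image$calibration,
                      positions_frac = cfg$thickness$positions,
                      mode = cfg$thickness$mode))
  mask <- with_stage("ROI binarization",
    binarize_roi(image, parent,
                 sensitivity = cfg$fascicle$adaptive_sensitivity,
                 window_divisor = cfg$fascicle$window_divisor))
  regions <- with_stage("region tracing",
                        trace_regions(mask, trace_boundaries = FALSE))
  fcfg <- fascicle_filter_config(cfg$fascicle$area_min_px,
                                 cfg$fascicle$area_max_px,
                                 cfg$fascicle$eccentricity_min)
  candidates <- filter_fascicle_candidates(regions, sup$linear, deep$linear,
                                           fcfg)
  rejected <- c(parallel = 0L, out_of_domain = 0L)
  fascicles <- list()
  for (i in seq_len(nrow(candidates))) {
    fm <- extrapolate_and_intersect(candidates[i, ], sup$linear, deep$linear,
                                    image$calibration,
                                    x_bounds = parent_x_extent,
                                    extend_widths = cfg$fascicle$max_extrapolation_widths)
    if (nrow(fm) == 0L) {
      why <- attr(fm, "rejection")
      rejected[why] <- rejected[why] + 1L
    } else if (fm$pennation_deg > 0) {  # co-linear fascicles excluded
      fascicles[[length(fascicles) + 1L]] <- fm
    }
  }
  fascicles <- if (length(fascicles)) dplyr::bind_rows(fascicles) else
    tibble::tibble(region_label = integer(0), slope = numeric(0),
                   intercept = numeric(0), x_superficial = numeric(0),
                   y_superficial = numeric(0), x_deep = numeric(0),
                   y_deep = numeric(0), orientation_deg = numeric(0),
                   pennation_deg = numeric(0),
                   fascicle_length_cm = numeric(0))
  if (nrow(fascicles) == 0L) {
    warning("no fascicles accepted in image '", image$source_id, "'",
            call. = FALSE)
  }
  summ <- list(
    n_fascicles = nrow(fascicles),
    mean_pennation_deg = mean_or_na(fascicles$pennation_deg),
    median_pennation_deg = stats::median(fascicles$pennation_deg),
    sd_pennation_deg = stats::sd(fascicles$pennation_deg),
    mean_fascicle_length_cm = mean_or_na(fascicles$fascicle_length_cm),
    median_fascicle_length_cm = stats::median(fascicles$fascicle_length_cm),
    sd_fascicle_length_cm = stats::sd(fascicles$fascicle_length_cm)
  )
  structure(
    list(image_id = image$source_id,
         fascicles = fascicles,
         thickness = thickness,
         summary = summ,
         aponeuroses = list(superficial = sup, deep = deep),
         n_regions = nrow(regions),
         n_candidates = nrow(candidates),
         rejected = rejected,
         config = cfg),
    class = "muscle_architecture"
  )
}

mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage [", stage, "]: ", conditionMessage(e), call. = FALSE)
  })
}

#' @export
print.muscle_architecture <- function(x, ...) {
  cat(sprintf("<muscle_architecture> %s\n", x$image_id))
  cat(sprintf("  fascicles: %d accepted (of %d candidates, %d regions)\n",
              x$summary$n_fascicles, x$n_candidates, x$n_regions))
  if (x$summary$n_fascicles > 0) {
    cat(sprintf("  pennation angle: %.2f deg (mean), fascicle length: %.2f cm (mean)\n",
                x$summary$mean_pennation_deg,
                x$summary$mean_fascicle_length_cm))
  }
  cat(sprintf("  muscle thickness (20/50/80%%): %s cm, mean %.3f cm\n",
              paste(sprintf("%.3f", x$thickness$thickness_cm), collapse = "/"),
              x$thickness$mean_thickness_cm))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.muscle_architecture <- function(x, ...) {
  dplyr::mutate(x$fascicles, image_id = x$image_id, .before = 1)
}

#' @export
glance.muscle_architecture <- function(x, ...) {
  th <- x$thickness
  tibble::tibble(
    image_id = x$image_id,
    n_fascicles = x$summary$n_fascicles,
    mean_pennation_deg = x$summary$mean_pennation_deg,
    sd_pennation_deg = x$summary$sd_pennation_deg,
    mean_fascicle_length_cm = x$summary$mean_fascicle_length_cm,
    sd_fascicle_length_cm = x$summary$sd_fascicle_length_cm,
    mt20_cm = th$thickness_cm[1],
    mt50_cm = th$thickness_cm[2],
    mt80_cm = th$thickness_cm[3],
    mt_mean_cm = th$mean_thickness_cm
  )
}
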