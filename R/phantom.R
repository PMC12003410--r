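#' Specification of a synthetic B-mode phantom
#'
#' Describes a synthetic longitudinal-view image of a pennate muscle: two
#' bright aponeurosis bands (linear or curved), oblique bright fascicle
#' stripes at a known y-up angle between them, and multiplicative speckle
#' noise, together with the pixel calibration. Defaults emulate the imaging
#' conditions of a vastus lateralis study: a 50 mm aperture at roughly
#' 10.2 px/mm (510 px wide), 5 cm depth, resting muscle thickness around
#' 2.8 cm, and fascicles at 15 degrees.
#'
#' Aponeurosis center lines are given in raster coordinates as
#' `c(slope, intercept)` or `c(a2, a1, a0)`; the fascicle angle is the y-up
#' angle relative to the image horizontal (positive = rising toward the
#' skin as x increases).
#'
#' @param width_px,height_px Image size.
#' @param calibration Pixels per mm.
#' @param superficial_line,deep_line Center lines of the bands (length 2 =
#'   linear, length 3 = quadratic), raster coordinates.
#' @param band_thickness_px Aponeurosis band thickness.
#' @param fascicle_angle_deg y-up stripe angle in (0, 90) relative to the
#'   horizontal.
#' @param fascicle_spacing_px Spacing of stripe anchor points along x.
#' @param stripe_width_px Stripe width (perpendicular).
#' @param background_intensity,stripe_intensity,band_intensity Intensities
#'   in \[0, 1\], ordered background < stripe <= band.
#' @param speckle_family `"uniform"` or `"gaussian"` multiplicative noise.
#' @param speckle_amplitude Noise amplitude (uniform half-range or
#'   gaussian SD of the multiplicative factor); 0 disables speckle.
#' @param speckle_grain_px Spatial correlation length of the speckle in
#'   pixels (box-smoothing window; 1 = independent pixels). Real speckle
#'   has a finite grain set by the resolution cell, so the default is 3.
#' @param n_stripes Number of stripes, or `NULL` to tile the full width;
#'   0 draws bands only.
#' @param seed Integer seed governing all stochastic draws.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(width_px = 510, height_px = 510,
                         calibration = 10.2,
                         superficial_line = c(0, 90),
                         deep_line = c(0, 375.6),
                         band_thickness_px = 10,
                         fascicle_angle_deg = 15,
                         fascicle_spacing_px = 60,
                         stripe_width_px = 4,
                         background_intensity = 0.15,
                         stripe_intensity = 0.55,
                         band_intensity = 0.85,
                         speckle_family = c("uniform", "gaussian"),
                         speckle_amplitude = 0.2,
                         speckle_grain_px = 3,
                         n_stripes = NULL,
                         seed = 1L) {
  speckle_family <- match.arg(speckle_family)
  stopifnot(background_intensity < stripe_intensity,
            stripe_intensity <= band_intensity,
            fascicle_angle_deg > 0, fascicle_angle_deg < 90,
            band_thickness_px > 0, stripe_width_px > 0)
  spec <- structure(
    list(width_px = width_px, height_px = height_px,
         calibration = calibration,
         superficial_line = superficial_line, deep_line = deep_line,
         band_thickness_px = band_thickness_px,
         fascicle_angle_deg = fascicle_angle_deg,
         fascicle_spacing_px = fascicle_spacing_px,
         stripe_width_px = stripe_width_px,
         background_intensity = background_intensity,
         stripe_intensity = stripe_intensity,
         band_intensity = band_intensity,
         speckle_family = speckle_family,
         speckle_amplitude = speckle_amplitude,
         speckle_grain_px = speckle_grain_px,
         n_stripes = n_stripes,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
  x_probe <- seq(0, width_px - 1, length.out = 32)
  gap <- eval_phantom_line(deep_line, x_probe) -
    eval_phantom_line(superficial_line, x_probe)
  if (any(gap <= band_thickness_px)) {
    stop("geometrically impossible phantom: aponeurosis bands touch or cross",
         call. = FALSE)
  }
  spec
}

eval_phantom_line <- function(line, x) {
  if (length(line) == 2L) line[1] * x + line[2]
  else line[1] * x^2 + line[2] * x + line[3]
}

phantom_line_slope <- function(line, x) {
  if (length(line) == 2L) rep(line[1], length(x)) else 2 * line[1] * x + line[2]
}

# x where the (linear) stripe y = m x + c meets an aponeurosis center
# line; closed form for linear lines, quadratic root selection otherwise.
stripe_line_crossing <- function(line, m, c0, x_hint) {
  if (length(line) == 2L) {
    (c0 - line[2]) / (line[1] - m)
  } else {
    roots <- polyroot(c(line[3] - c0, line[2] - m, line[1]))
    re <- Re(roots[abs(Im(roots)) < 1e-8])
    if (!length(re)) return(NA_real_)
    re[which.min(abs(re - x_hint))]
  }
}

#' Generate a synthetic phantom image with analytic ground truth
#'
#' Renders the phantom described by a [phantom_spec()] with anti-aliased
#' (area-coverage) edges, applies seeded multiplicative speckle, and
#' returns the image, the three auto-constructed regions of interest
#' (parent region between the bands, dilated aponeurosis bands), and the
#' analytic truth: the pennation angle relative to the deep line, the
#' per-stripe chord length between the two aponeurosis center lines along
#' the stripe direction (cm), and the vertical center-line separation at
#' the 20/50/80% positions of the parent extent (cm). Deterministic per
#' seed.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` ([bmode_image()]), `rois` (named list of
#'   three [roi()]s), and `truth` (`phantom_truth`: `true_pa_deg`,
#'   `true_fl_cm`, `true_mt_cm`, `fascicle_angle_deg`,
#'   `deep_orientation_deg`, `stripe_anchors_x`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  w <- spec$width_px; h <- spec$height_px
  x <- matrix(rep(0:(w - 1), each = h), h, w)    # 0-based column coords
  y <- matrix(rep(0:(h - 1), times = w), h, w)   # 0-based row coords
  img <- matrix(spec$background_intensity, h, w)

  sup_y <- eval_phantom_line(spec$superficial_line, x[1, ])
  deep_y <- eval_phantom_line(spec$deep_line, x[1, ])
  half_band <- spec$band_thickness_px / 2

  # fascicle stripes between the two center lines
  theta <- spec$fascicle_angle_deg * pi / 180
  m_f <- -tan(theta)                       # raster slope (y-up angle)
  anchors <- phantom_stripe_anchors(spec)
  half_stripe <- spec$stripe_width_px / 2
  norm_f <- sqrt(1 + m_f^2)
  sup_y_full <- eval_phantom_line(spec$superficial_line, x)
  deep_y_full <- eval_phantom_line(spec$deep_line, x)
  between <- y >= sup_y_full & y <= deep_y_full
  for (ax in anchors) {
    c0 <- eval_phantom_line(spec$deep_line, ax) - m_f * ax
    d <- abs(y - (m_f * x + c0)) / norm_f  # perpendicular distance
    cov <- pmin(pmax(half_stripe + 0.5 - d, 0), 1)
    cov[!between] <- 0
    img <- pmax(img, spec$background_intensity +
                  cov * (spec$stripe_intensity - spec$background_intensity))
  }

  # aponeurosis bands (drawn last: they sit over stripe endpoints)
  for (line in list(spec$superficial_line, spec$deep_line)) {
    cy <- eval_phantom_line(line, x)
    d <- abs(y - cy)
    cov <- pmin(pmax(half_band + 0.5 - d, 0), 1)
    img <- pmax(img, spec$background_intensity +
                  cov * (spec$band_intensity - spec$background_intensity))
  }

  if (spec$speckle_amplitude > 0) {
    img <- withr::with_seed(spec$seed, {
      # target SD of the multiplicative factor, matching the unsmoothed
      # family: uniform half-range a has SD a/sqrt(3)
      target_sd <- switch(spec$speckle_family,
        uniform = spec$speckle_amplitude / sqrt(3),
        gaussian = spec$speckle_amplitude)
      raw <- switch(spec$speckle_family,
        uniform = matrix(stats::runif(h * w, -1, 1), h, w),
        gaussian = matrix(stats::rnorm(h * w), h, w))
      g <- max(1L, as.integer(spec$speckle_grain_px))
      if (g %% 2L == 0L) g <- g + 1L
      z <- if (g > 1L) box_mean(raw, g) else raw
      z <- (z - mean(z)) / stats::sd(z)
      img * (1 + target_sd * z)
    })
  }
  img <- pmin(pmax(img, 0), 1)

  image <- bmode_image(img, spec$calibration,
                       source_id = sprintf("phantom_seed%d", spec$seed))

  # auto-constructed ROIs
  margin <- 4
  gap <- 5  # parent starts strictly below the dilated aponeurosis ROIs
  sup_mask <- abs(y - sup_y_full) <= half_band + margin
  deep_mask <- abs(y - deep_y_full) <= half_band + margin
  xm <- 10
  parent_mask <- y > sup_y_full + half_band + gap &
    y < deep_y_full - half_band - gap &
    x >= xm & x <= w - 1 - xm
  rois <- list(
    parent = roi(parent_mask, "parent"),
    superficial_aponeurosis = roi(sup_mask, "superficial_aponeurosis"),
    deep_aponeurosis = roi(deep_mask, "deep_aponeurosis")
  )

  truth <- phantom_truth(spec, anchors, parent_x_extent = c(xm, w - 1 - xm))
  list(image = image, rois = rois, truth = truth)
}

phantom_stripe_anchors <- function(spec) {
  if (!is.null(spec$n_stripes) && spec$n_stripes == 0) return(numeric(0))
  w <- spec$width_px; h <- spec$height_px
  theta <- spec$fascicle_angle_deg * pi / 180
  # stripes rise to the right; extend anchors left of the frame so stripes
  # entering through the bottom/left edges still cross the field of view
  reach <- h / tan(theta)
  anchors <- seq(-ceiling(reach), w - 1 + spec$fascicle_spacing_px,
                 by = spec$fascicle_spacing_px)
  # keep only stripes whose chord between the center lines is visible
  m_f <- -tan(theta)
  visible <- vapply(anchors, function(ax) {
    c0 <- eval_phantom_line(spec$deep_line, ax) - m_f * ax
    xs <- stripe_line_crossing(spec$superficial_line, m_f, c0, ax)
    !is.na(xs) && max(ax, xs) >= 0 && min(ax, xs) <= w - 1
  }, logical(1))
  anchors <- anchors[visible]
  if (!is.null(spec$n_stripes)) {
    mid <- stats::median(seq_along(anchors))
    keep <- order(abs(seq_along(anchors) - mid))[seq_len(min(spec$n_stripes,
                                                             length(anchors)))]
    anchors <- sort(anchors[keep])
  }
  anchors
}

phantom_truth <- function(spec, anchors, parent_x_extent) {
  theta <- spec$fascicle_angle_deg
  m_f <- -tan(theta * pi / 180)
  # deep orientation at mid-extent for curved lines
  x_mid <- mean(parent_x_extent)
  deep_slope <- phantom_line_slope(spec$deep_line, x_mid)
  deep_angle <- slope_to_angle_yup(deep_slope)
  true_pa <- compute_pennation_angle(theta, deep_angle)

  fl <- vapply(anchors, function(ax) {
    c0 <- eval_phantom_line(spec$deep_line, ax) - m_f * ax
    xs <- stripe_line_crossing(spec$superficial_line, m_f, c0, ax)
    xd <- stripe_line_crossing(spec$deep_line, m_f, c0, ax)
    ps <- c(xs, m_f * xs + c0); pd <- c(xd, m_f * xd + c0)
    px_to_cm(sqrt(sum((pd - ps)^2)), spec$calibration)
  }, numeric(1))

  xp <- parent_x_extent[1] + c(0.2, 0.5, 0.8) * diff(parent_x_extent)
  mt <- px_to_cm(eval_phantom_line(spec$deep_line, xp) -
                   eval_phantom_line(spec$superficial_line, xp),
                 spec$calibration)
  structure(
    list(true_pa_deg = true_pa, true_fl_cm = fl, true_mt_cm = mt,
         fascicle_angle_deg = theta, deep_orientation_deg = deep_angle,
         stripe_anchors_x = anchors),
    class = "phantom_truth"
  )
}

#' Write a phantom to disk
#'
#' Writes the rendered image as PNG, the three ROIs as JSON polygon files
#' when polygonal (otherwise PNG masks), and the ground truth as JSON.
#'
#' @param phantom Result of [generate_phantom()].
#' @param dir Output directory.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, "phantom.png")
  png::writePNG(phantom$image$pixels, img_path)
  jsonlite::write_json(list(pixels_per_mm =
                              phantom$image$calibration$pixels_per_mm),
                       paste0(img_path, ".json"), auto_unbox = TRUE)
  paths <- c(image = img_path)
  for (k in names(phantom$rois)) {
    p <- file.path(dir, paste0("roi_", k, ".png"))
    png::writePNG(phantom$rois[[k]]$mask * 1, p)
    paths[paste0("roi_", k)] <- p
  }
  tr <- phantom$truth
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(unclass(tr), truth_path, auto_unbox = TRUE, digits = NA)
  paths["truth"] <- truth_path
  invisible(paths)
}

#' Simulate a rater measurement table with known variance components
#'
#' Generates a long-format table of fascicle length, pennation angle, and
#' muscle thickness measurements under an additive two-way mixed model per
#' measure:
#' `value = grand_mean + intensity_effect + subject + rater +
#' subject:rater + trial_error (+ method_bias for the manual method)`.
#' Subject, rater, and interaction effects are shared across trials; the
#' method bias is a fixed additive offset applied to the manual method
#' (defaults follow reported method differences: -4.0 cm fascicle length,
#' +2.99 deg pennation angle, -0.19 cm thickness, manual minus
#' semi-automated). With all SDs zero every downstream ICC is exactly 1.
#' The theoretical single-measure absolute-agreement ICC across raters is
#' `subject_sd^2 / (subject_sd^2 + rater_sd^2 + interaction_sd^2 +
#' error_sd^2)`.
#'
#' Values are kept within physiologic bounds by truncation; the number of
#' truncated values is recorded in the `truncated` attribute.
#'
#' @param n_subjects Number of subjects.
#' @param intensities Character vector of contraction intensities.
#' @param n_raters,n_trials Design sizes.
#' @param methods Methods to simulate.
#' @param grand_means Named per-measure means (semi-automated scale).
#' @param intensity_effects Named list of per-measure additive shifts, one
#'   value per intensity.
#' @param sds Named list per measure:
#'   `c(subject =, rater =, interaction =, error =)`.
#' @param method_bias Additive offset applied to the manual method, per
#'   measure (manual minus semi-automated).
#' @param seed Integer seed.
#' @return Tibble in `RaterMeasurementTable` long format.
#' @export
generate_measurement_table <- function(
    n_subjects = 15,
    intensities = c("rest", "30%MVIC", "70%MVIC", "MVIC"),
    n_raters = 3, n_trials = 2,
    methods = c("manual", "semi_automated"),
    grand_means = c(FL_cm = 14.9, PA_deg = 11.5, MT_cm = 2.8),
    intensity_effects = list(
      FL_cm = c(0.7, 0.8, -0.5, -1.0),
      PA_deg = c(0.6, -0.5, -0.5, 0.2),
      MT_cm = c(0, 0, 0, 0)),
    sds = list(
      FL_cm = c(subject = 2.0, rater = 0.4, interaction = 0.3, error = 0.5),
      PA_deg = c(subject = 1.8, rater = 0.4, interaction = 0.3, error = 0.5),
      MT_cm = c(subject = 0.45, rater = 0.02, interaction = 0.02,
                error = 0.03)),
    method_bias = c(FL_cm = -4.0, PA_deg = 2.99, MT_cm = -0.19),
    seed = 1L) {
  measures <- names(grand_means)
  bounds <- list(FL_cm = c(0.5, 40), PA_deg = c(0.5, 89.5), MT_cm = c(0.1, 10))
  withr::with_seed(as.integer(seed), {
    truncated <- 0L
    rows <- list()
    for (meas in measures) {
      s <- sds[[meas]]
      eff <- intensity_effects[[meas]]
      subj_eff <- stats::rnorm(n_subjects, 0, s["subject"])
      for (meth in methods) {
        rater_eff <- stats::rnorm(n_raters, 0, s["rater"])
        inter_eff <- matrix(stats::rnorm(n_subjects * n_raters, 0,
                                         s["interaction"]),
                            n_subjects, n_raters)
        for (ii in seq_along(intensities)) {
          for (r in seq_len(n_raters)) {
            for (tr in seq_len(n_trials)) {
              v <- grand_means[meas] + eff[ii] + subj_eff + rater_eff[r] +
                inter_eff[, r] +
                stats::rnorm(n_subjects, 0, s["error"]) +
                if (meth == "manual") method_bias[meas] else 0
              b <- bounds[[meas]]
              truncated <- truncated + sum(v < b[1] | v > b[2])
              v <- pmin(pmax(v, b[1]), b[2])
              rows[[length(rows) + 1L]] <- tibble::tibble(
                subject_id = sprintf("S%02d", seq_len(n_subjects)),
                intensity = intensities[ii],
                rater_id = sprintf("R%d", r),
                trial = tr,
                method = meth,
                measure = meas,
                value = unname(v))
            }
          }
        }
      }
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "truncated") <- truncated
    if (truncated > 0L) {
      message(truncated, " value(s) truncated to physiologic bounds")
    }
    out
  })
}
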