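test_that("pennation angle folds axially and matches simple differences", {
  expect_equal(compute_pennation_angle(20, 0), 20)
  expect_equal(compute_pennation_angle(20, 5), 15)
  expect_equal(compute_pennation_angle(-80, 80), 20)
  # brute force over axial equivalence classes: angle between two lines
  withr::with_seed(17, {
    for (i in 1:200) {
      a <- stats::runif(1, -90, 90); b <- stats::runif(1, -90, 90)
      want <- min(abs(a - b), 180 - abs(a - b))
      expect_equal(compute_pennation_angle(a, b), want, tolerance = 1e-12)
    }
  })
})

test_that("fascicle length is the calibrated Euclidean norm", {
  expect_equal(compute_fascicle_length(c(0, 0), c(300, 400), 10), 5.0)
  expect_equal(compute_fascicle_length(c(0, 0), c(510, 0), 10.2), 5.0)
  expect_error(compute_fascicle_length(c(1, 1), c(1, 1), 10), "coincide")
  withr::with_seed(23, {
    for (i in 1:50) {
      p <- stats::runif(2, 0, 500); q <- stats::runif(2, 0, 500)
      cal <- stats::runif(1, 5, 20)
      expect_equal(compute_fascicle_length(p, q, cal),
                   sqrt(sum((p - q)^2)) / cal / 10, tolerance = 1e-12)
    }
  })
})

test_that("extrapolation solves the closed-form intersections", {
  sup <- c(slope = 0, intercept = 100)
  deep <- c(slope = 0, intercept = 400)
  region <- tibble::tibble(label = 1L, centroid_x = 200, centroid_y = 250,
                           orientation_deg = 30)
  fm <- extrapolate_and_intersect(region, sup, deep, 10)
  expect_equal(fm$y_superficial, 100)
  expect_equal(fm$y_deep, 400)
  expect_equal(fm$x_superficial - fm$x_deep, 300 / tan(30 * pi / 180),
               tolerance = 1e-9)
  expect_equal(fm$pennation_deg, 30)

  # parallel to the deep fit -> rejection
  par_region <- dplyr::mutate(region, orientation_deg = 0)
  rej <- extrapolate_and_intersect(par_region, sup, deep, 10)
  expect_equal(nrow(rej), 0L)
  expect_equal(attr(rej, "rejection"), "parallel")

  # sloped aponeuroses against an independent line-intersection oracle
  sup2 <- c(slope = -tan(5 * pi / 180), intercept = 120)
  deep2 <- c(slope = -tan(5 * pi / 180), intercept = 405)
  reg2 <- tibble::tibble(label = 2L, centroid_x = 250, centroid_y = 260,
                         orientation_deg = 20)
  fm2 <- extrapolate_and_intersect(reg2, sup2, deep2, 10.2)
  m_f <- -tan(20 * pi / 180); b_f <- 260 - m_f * 250
  x_star <- (b_f - 120) / (sup2[["slope"]] - m_f)
  expect_lt(abs(fm2$x_superficial - x_star), 0.5)
  expect_lt(abs(fm2$y_superficial - (m_f * x_star + b_f)), 0.5)
})

test_that("near-parallel candidates are rejected by the extrapolation domain", {
  sup <- c(slope = 0, intercept = 100)
  deep <- c(slope = 0, intercept = 400)
  region <- tibble::tibble(label = 1L, centroid_x = 200, centroid_y = 250,
                           orientation_deg = 0.5)
  rej <- extrapolate_and_intersect(region, sup, deep, 10,
                                   x_bounds = c(0, 500), extend_widths = 4)
  expect_equal(attr(rej, "rejection"), "out_of_domain")
  # without a domain the same candidate is accepted
  fm <- extrapolate_and_intersect(region, sup, deep, 10)
  expect_equal(nrow(fm), 1L)
})

test_that("thickness from quadratic fits handles flat and curved geometry", {
  cal <- calibration_info(10)
  flat_s <- c(a2 = 0, a1 = 0, a0 = 100)
  flat_d <- c(a2 = 0, a1 = 0, a0 = 400)
  th <- measure_thickness(flat_s, flat_d, c(0, 500), cal)
  expect_equal(th$thickness_cm, rep(3, 3))
  expect_equal(th$mean_thickness_cm, 3)
  expect_equal(th$x_positions_px, c(100, 250, 400))

  # curved deep aponeurosis: mid thinner than flanks
  curved_d <- c(a2 = 0.0005, a1 = -0.0005 * 2 * 250, a0 = 400 + 0.0005 * 250^2)
  th2 <- measure_thickness(flat_s, curved_d, c(0, 500), cal)
  expect_lt(th2$thickness_cm[2], th2$thickness_cm[1])
  expect_lt(th2$thickness_cm[2], th2$thickness_cm[3])

  expect_error(measure_thickness(flat_d, flat_s, c(0, 500), cal), "crossed")
})

test_that("manual fascicle length formula FL = MT / sin(PA)", {
  expect_equal(manual_fascicle_length(2.0, 30), 4.0)
  expect_equal(manual_fascicle_length(2.6, 90), 2.6)
  expect_equal(manual_fascicle_length(2.6, 15.1), 2.6 / sin(15.1 * pi / 180))
  expect_lt(abs(manual_fascicle_length(2.6, 15.1) - 9.98), 0.01)
  expect_error(manual_fascicle_length(2.6, 0), "between")
  expect_error(manual_fascicle_length(-1, 20), "positive")
})

test_that("pennation angle is invariant under consistent rotation; FL scales with calibration", {
  withr::with_seed(41, {
    for (i in 1:50) {
      f <- stats::runif(1, -60, 60); d <- stats::runif(1, -30, 30)
      rot <- stats::runif(1, -20, 20)
      expect_equal(compute_pennation_angle(f, d),
                   compute_pennation_angle(f + rot, d + rot),
                   tolerance = 1e-9)
    }
  })
  p1 <- compute_fascicle_length(c(0, 0), c(123, 456), 10.2)
  p2 <- compute_fascicle_length(c(0, 0), c(123, 456), 20.4)
  expect_equal(p1, 2 * p2)
})

test_that("analyze_image recovers the default phantom and is bit-reproducible", {
  ph <- generate_phantom(phantom_spec(seed = 6))
  res <- analyze_image(ph$image, ph$rois)
  expect_gte(res$summary$n_fascicles, 5)
  expect_equal(res$summary$mean_pennation_deg, 15, tolerance = 1 / 15)
  res2 <- analyze_image(ph$image, ph$rois)
  expect_identical(res, res2)
})

test_that("zero-stripe phantom yields an empty fascicle list but valid thickness", {
  ph <- generate_phantom(small_phantom_spec(seed = 3, n_stripes = 0,
                                            speckle_amplitude = 0))
  expect_warning(res <- analyze_image(ph$image, ph$rois), "no fascicles")
  expect_equal(res$summary$n_fascicles, 0L)
  expect_length(ph$truth$true_fl_cm, 0)
  expect_equal(res$thickness$thickness_cm, ph$truth$true_mt_cm,
               tolerance = 0.02)
})

test_that("flat-phantom fascicles satisfy FL * sin(PA) = vertical MT", {
  ph <- generate_phantom(phantom_spec(seed = 8))
  res <- analyze_image(ph$image, ph$rois)
  mt_vert <- px_to_cm(
    eval_linear(res$aponeuroses$deep$linear, res$fascicles$x_deep) -
      eval_linear(res$aponeuroses$superficial$linear, res$fascicles$x_deep),
    ph$image$calibration)
  recon <- res$fascicles$fascicle_length_cm *
    sin(res$fascicles$pennation_deg * pi / 180)
  expect_equal(recon, mt_vert, tolerance = 0.01)
})

test_that("tidy and glance summarize an analysis result", {
  ph <- generate_phantom(small_phantom_spec(seed = 12))
  res <- suppressWarnings(analyze_image(ph$image, ph$rois))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), res$summary$n_fascicles)
  gl <- glance(res)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$mean_pennation_deg, mean(td$pennation_deg))
})
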