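test_that("Otsu binarization separates a bright band from dark background", {
  px <- matrix(0.1, 60, 80)
  px[25:32, ] <- 0.9
  img <- bmode_image(px, 10)
  band_roi <- roi(rbind(matrix(FALSE, 18, 80), matrix(TRUE, 22, 80),
                        matrix(FALSE, 20, 80)),
                  "superficial_aponeurosis")
  mask <- binarize_aponeurosis(img, band_roi)
  expect_identical(which(mask, arr.ind = TRUE)[, 1] |> range(), c(25L, 32L))
  expect_equal(sum(mask), 8 * 80)
})

test_that("uniform-intensity ROI raises an informative error", {
  img <- bmode_image(matrix(0.4, 30, 30), 10)
  r <- roi(matrix(TRUE, 30, 30), "deep_aponeurosis")
  expect_error(binarize_aponeurosis(img, r), "constant|not detected")
  expect_error(binarize_aponeurosis(img, roi(matrix(TRUE, 30, 30), "parent")),
               "aponeurosis kind")
})

test_that("phantom band binarizes to the drawn thickness within 1 px", {
  spec <- small_phantom_spec(seed = 5)
  ph <- generate_phantom(spec)
  mask <- binarize_aponeurosis(ph$image, ph$rois$superficial_aponeurosis)
  mask <- remove_small_regions(mask, 100)
  occ <- colSums(mask)
  occ <- occ[occ > 0]
  # interior columns only (stripe teeth touch the band near its underside)
  expect_lt(abs(stats::median(occ) - spec$band_thickness_px), 1.5)
})

test_that("remove_small_regions matches threshold semantics and the BFS oracle", {
  m <- matrix(FALSE, 100, 100)
  m[10:59, 10:59] <- TRUE            # 2500 px
  m[80:81, 80:84] <- TRUE            # 10 px speck
  out <- remove_small_regions(m, 200)
  expect_equal(sum(out), 2500)

  # largest-component fallback: never empty from non-empty input
  speck <- matrix(FALSE, 20, 20); speck[3:7, 3:12] <- TRUE  # 50 px
  out2 <- remove_small_regions(speck, 200)
  expect_equal(out2, speck)

  # random speck fields against brute-force BFS labeling
  withr::with_seed(42, {
    for (rep in 1:5) {
      m <- matrix(stats::runif(40 * 50) < 0.25, 40, 50)
      min_area <- sample(c(3, 5, 10), 1)
      got <- remove_small_regions(m, min_area)
      lab <- bfs_label(m, 8)
      areas <- tabulate(lab[lab > 0])
      keep <- which(areas >= min_area)
      if (length(keep) == 0) keep <- which.max(areas)
      expect_identical(got, matrix(lab %in% keep, 40, 50))
    }
  })
})

test_that("remove_small_regions is idempotent", {
  withr::with_seed(7, {
    m <- matrix(stats::runif(60 * 60) < 0.3, 60, 60)
    once <- remove_small_regions(m, 20)
    expect_identical(remove_small_regions(once, 20), once)
  })
})

test_that("label_components agrees with the BFS oracle on both connectivities", {
  withr::with_seed(11, {
    for (conn in c(4, 8)) {
      m <- matrix(stats::runif(30 * 35) < 0.35, 30, 35)
      got <- label_components(m, conn)
      want <- bfs_label(m, conn)
      expect_identical(got > 0, want > 0)
      expect_equal(max(got), max(want))
      # same partition, not just same count
      expect_true(all(tapply(want[m], got[m], function(v) length(unique(v))) == 1))
    }
  })
})

test_that("midline is the column-wise (min+max)/2 and mirrors correctly", {
  m <- matrix(FALSE, 30, 10)
  m[11:19, 3] <- TRUE   # rows 10..18 0-based -> mid 14
  m[8, 5] <- TRUE       # single pixel, row 7 0-based
  ml <- extract_midline(m)
  expect_equal(ml$y[ml$x == 2], 14.0)
  expect_equal(ml$y[ml$x == 4], 7.0)
  expect_true(all(diff(ml$x) > 0))

  # mirror property: flipping rows mirrors the midline about the center
  withr::with_seed(3, {
    mm <- random_blob_mask(40, 60, 6)
    ml1 <- extract_midline(mm)
    ml2 <- extract_midline(mm[40:1, ])
    expect_equal(ml2$y, (40 - 1) - ml1$y)
  })
})

test_that("polynomial fits recover exact and noisy generating curves", {
  x <- 0:50
  lin <- fit_polynomials(tibble::tibble(x = x, y = 2 * x + 1))
  expect_equal(unname(lin$linear), c(2, 1), tolerance = 1e-10)
  expect_equal(unname(lin$quadratic[["a2"]]), 0, tolerance = 1e-10)

  quad <- fit_polynomials(tibble::tibble(x = x, y = 0.01 * x^2))
  expect_equal(unname(quad$quadratic), c(0.01, 0, 0), tolerance = 1e-10)

  expect_error(fit_polynomials(tibble::tibble(x = c(1, 1, 2), y = 1:3)),
               "too short")

  # noisy line: slope recovered within 3 standard errors
  withr::with_seed(99, {
    x <- seq(0, 299)
    y <- 0.1 * x + 5 + stats::rnorm(300, 0, 0.5)
    f <- fit_polynomials(tibble::tibble(x = x, y = y))
    se <- 0.5 / sqrt(sum((x - mean(x))^2))
    expect_lt(abs(f$linear[["slope"]] - 0.1), 3 * se)
  })
})

test_that("tilted phantom band yields a midline with the drawn slope", {
  spec <- phantom_spec(width_px = 300, height_px = 300,
                       superficial_line = c(0.1, 40),
                       deep_line = c(0.1, 220),
                       n_stripes = 0, seed = 2)
  ph <- generate_phantom(spec)
  ap <- fit_aponeurosis(ph$image, ph$rois$superficial_aponeurosis)
  expect_equal(unname(ap$linear[["slope"]]), 0.1, tolerance = 0.01)
})

test_that("full aponeurosis pipeline recovers line parameters across seeds", {
  for (s in 1:4) {
    spec <- phantom_spec(width_px = 300, height_px = 300,
                         superficial_line = c(-0.05, 70),
                         deep_line = c(-0.05, 230),
                         n_stripes = 0, seed = s)
    ph <- generate_phantom(spec)
    for (kind in c("superficial_aponeurosis", "deep_aponeurosis")) {
      ap <- fit_aponeurosis(ph$image, ph$rois[[kind]])
      truth <- if (kind == "superficial_aponeurosis") 70 else 230
      expect_equal(unname(ap$linear[["slope"]]), -0.05, tolerance = 0.01)
      expect_lt(abs(unname(ap$linear[["intercept"]]) - truth), 1)
      # least-squares invariant: residuals orthogonal to the design
      res <- ap$midline$y - eval_linear(ap$linear, ap$midline$x)
      expect_lt(abs(sum(res)), 1e-6 * nrow(ap$midline))
      expect_lt(abs(sum(res * ap$midline$x)), 1e-4 * sum(abs(ap$midline$x)))
    }
  }
})
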