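test_that("ICC is exactly 1 for identical columns and penalizes offsets", {
  m <- cbind(c(1, 3, 5, 9, 2), c(1, 3, 5, 9, 2))
  r <- icc(m, "single")
  expect_equal(r$estimate, 1.0)
  expect_equal(as.character(r$label), "excellent")

  # constant column offset, no noise: absolute agreement < 1
  m2 <- cbind(c(1, 3, 5, 9, 2), c(1, 3, 5, 9, 2) + 2)
  r2 <- icc(m2, "single")
  expect_lt(r2$estimate, 1)
  expect_gt(r2$estimate, 0)
})

test_that("ICC point estimates match the aov-based oracle to 1e-10", {
  withr::with_seed(101, {
    for (rep in 1:50) {
      m <- matrix(stats::rnorm(30, 10, 3), 10, 3) +
        outer(stats::rnorm(10, 0, 2), rep(1, 3)) +
        outer(rep(1, 10), stats::rnorm(3, 0, 1))
      expect_equal(icc(m, "single")$estimate, aov_icc_oracle(m, "single"),
                   tolerance = 1e-10)
      expect_equal(icc(m, "average")$estimate, aov_icc_oracle(m, "average"),
                   tolerance = 1e-10)
    }
  })
})

test_that("ICC CI brackets the estimate and input validation works", {
  withr::with_seed(5, {
    m <- matrix(stats::rnorm(45, 20, 4), 15, 3) +
      outer(stats::rnorm(15, 0, 3), rep(1, 3))
    for (mod in c("single", "average")) {
      r <- icc(m, mod)
      expect_lte(r$ci_low, r$estimate)
      expect_gte(r$ci_high, r$estimate)
      expect_lte(r$estimate, 1)
    }
  })
  expect_error(icc(matrix(1:3, 3, 1)), "at least 2")
  expect_error(icc(matrix(5, 4, 3)), "degenerate")
  expect_warning(icc(rbind(cbind(1:5, c(1.3, 2.1, 3.4, 3.9, 5.2)),
                           c(1, NA))),
                 "dropped")
})

test_that("ICC is invariant to affine rescaling of the whole table", {
  withr::with_seed(55, {
    m <- matrix(stats::rnorm(36, 12, 2), 12, 3) +
      outer(stats::rnorm(12, 0, 2), rep(1, 3))
    base <- icc(m, "single")$estimate
    expect_equal(icc(m + 100, "single")$estimate, base, tolerance = 1e-10)
    expect_equal(icc(m * 3.7, "single")$estimate, base, tolerance = 1e-10)
  })
})

test_that("interpretation bands reproduce the published cutpoints", {
  probe <- c(0.10, 0.30, 0.49, 0.499, 0.50, 0.60, 0.75, 0.76, 0.84, 0.90,
             0.901, 0.95, 0.999)
  want <- c("poor", "poor", "poor", "poor", "moderate", "moderate",
            "moderate", "good", "good", "good", "excellent", "excellent",
            "excellent")
  expect_equal(as.character(interpret_icc(probe)), want)
  # monotone non-decreasing across the ordered labels
  grid <- interpret_icc(seq(-0.2, 1, by = 0.005))
  expect_true(all(diff(as.integer(grid)) >= 0))
})

test_that("Pearson with Fisher CI matches cor.test and handles exact fits", {
  x <- c(1, 2, 4, 7, 9.5)
  expect_equal(pearson_with_ci(x, 2 * x + 1)$r, 1.0)
  expect_equal(pearson_with_ci(x, -x)$r, -1.0)
  expect_error(pearson_with_ci(x, rep(1, 5)), "zero variance")
  expect_error(pearson_with_ci(1:3, 1:3), "at least 4")

  withr::with_seed(77, {
    x <- stats::rnorm(20); y <- 0.6 * x + stats::rnorm(20, 0, 0.7)
    got <- pearson_with_ci(x, y)
    ct <- stats::cor.test(x, y)
    expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(c(got$ci_low, got$ci_high), as.numeric(ct$conf.int),
                 tolerance = 1e-9, ignore_attr = TRUE)
  })
})

test_that("Fisher intervals achieve near-nominal coverage", {
  withr::with_seed(2024, {
    rho <- 0.9; n <- 15; reps <- 2000
    cover <- 0; zs <- numeric(reps); rs <- numeric(reps)
    for (i in seq_len(reps)) {
      x <- stats::rnorm(n)
      y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
      ci <- pearson_with_ci(x, y)
      cover <- cover + (ci$ci_low <= rho && rho <= ci$ci_high)
      rs[i] <- ci$r; zs[i] <- atanh(ci$r)
    }
    expect_lt(abs(cover / reps - 0.95), 0.02)
    expect_lt(abs(mean(rs) - tanh(mean(zs))), 0.02)
  })
})

test_that("Bland-Altman trivial cases and closed-form normal recovery", {
  x <- c(1, 2, 3, 4.5)
  r0 <- bland_altman(x, x)
  expect_equal(r0$bias, 0)
  expect_equal(c(r0$loa_low, r0$loa_high), c(0, 0))

  r1 <- bland_altman(x + 1, x)
  expect_equal(r1$bias, 1.0)
  expect_equal(r1$sd_diff, 0)
  expect_equal(c(r1$loa_low, r1$loa_high), c(1, 1))

  expect_error(bland_altman(1:3, 1:4), "length mismatch")

  withr::with_seed(404, {
    d <- stats::rnorm(10000, -4, 2.85)
    ba <- bland_altman(d, rep(0, 10000))
    expect_lt(abs(ba$bias - (-4)), 0.1)
    expect_lt(abs(ba$loa_low - (-4 - 1.96 * 2.85)), 0.15)
    expect_lt(abs(ba$loa_high - (-4 + 1.96 * 2.85)), 0.15)
    # the blandr-style CI constructions
    expect_equal(diff(ba$ci_bias) / 2,
                 stats::qt(0.975, 9999) * ba$sd_diff / sqrt(10000))
    expect_equal(diff(ba$ci_loa_low) / 2,
                 stats::qt(0.975, 9999) * ba$sd_diff * sqrt(3 / 10000))
  })
})

test_that("Bland-Altman bias is antisymmetric", {
  withr::with_seed(9, {
    a <- stats::rnorm(30, 5); b <- stats::rnorm(30, 4)
    expect_equal(bland_altman(a, b)$bias, -bland_altman(b, a)$bias)
  })
})

test_that("reliability report covers the full design and mirrors its layout", {
  tab <- generate_measurement_table(seed = 42)
  rep <- reliability_report(tab)
  # 3 measures x 4 intensities x 2 methods x 2 contrasts
  expect_equal(nrow(rep$icc), 3 * 4 * 2 * 2)
  expect_equal(sort(unique(rep$icc$contrast)),
               c("inter_rater", "intra_rater"))
  expect_equal(nrow(rep$pearson), 3 * 4 * 2)
  expect_equal(nrow(rep$bland_altman), 3)
  expect_true(all(rep$icc$estimate <= 1))
  # inter-rater rows use the average-measure ICC(2,k) model
  expect_true(all(rep$icc$model[rep$icc$contrast == "inter_rater"] ==
                    "two_way_random_avg_abs"))
})

test_that("degenerate designs are skipped with warnings, perfect repeats give 1", {
  tab <- generate_measurement_table(seed = 7)
  one_rater <- dplyr::filter(tab, rater_id == "R1")
  w <- testthat::capture_warnings(rep1 <- reliability_report(one_rater))
  expect_true(all(grepl("fewer than 2 raters", w)))
  expect_equal(length(w), 3 * 4 * 2)  # one per skipped contrast
  expect_equal(nrow(rep1$icc[rep1$icc$contrast == "inter_rater", ]), 0L)

  # identical trials for all subjects -> intra-rater ICC 1
  noiseless <- generate_measurement_table(
    sds = list(FL_cm = c(subject = 2, rater = 0, interaction = 0, error = 0),
               PA_deg = c(subject = 2, rater = 0, interaction = 0, error = 0),
               MT_cm = c(subject = 0.4, rater = 0, interaction = 0,
                         error = 0)),
    seed = 11)
  repn <- reliability_report(noiseless)
  intra <- repn$icc[repn$icc$contrast == "intra_rater", ]
  expect_true(all(abs(intra$estimate - 1) < 1e-12))
})

test_that("duplicate keys and missing columns are rejected", {
  tab <- generate_measurement_table(seed = 3)
  expect_error(reliability_report(rbind(tab, tab[1, ])), "duplicate")
  expect_error(reliability_report(tab[, -7]), "lacks column")
})
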