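#' Intraclass correlation coefficient (absolute agreement)
#'
#' Two-way absolute-agreement ICC from the ANOVA mean squares of a
#' subjects-by-measurements table, in the McGraw-Wong parameterization.
#' `"single"` is the single-rater form used for intra-rater reliability
#' (the two-way mixed, single rater, absolute agreement ICC shares its
#' point estimate with the two-way random form ICC(A,1)); `"average"` is
#' the multiple-rater form ICC(2,k) used for inter-rater reliability.
#' Confidence intervals use the standard F-based construction for
#' absolute-agreement ICCs; average-measure bounds are the single-measure
#' bounds stepped up with the Spearman-Brown relation.
#'
#' Rows containing missing values are dropped with a warning (the ANOVA
#' decomposition needs complete cells). The estimate can be negative and
#' is reported as computed; the interpretation label is applied to
#' `max(estimate, 0)`.
#'
#' @param x Numeric matrix or data frame, subjects in rows, measurements
#'   (raters or trials) in columns.
#' @param model `"single"` (two-way mixed/random, single measurement,
#'   absolute agreement) or `"average"` (ICC(2,k)).
#' @param conf_level Confidence level (default 0.95).
#' @return An `icc_result`: `estimate`, `ci_low`, `ci_high`, `model`,
#'   `n_subjects`, `k_measurements`, `label`, and the mean squares.
#' @export
#' @examples
#' m <- cbind(c(1, 2, 3, 4), c(1.1, 2.0, 3.2, 3.9))
#' icc(m)$estimate
icc <- function(x, model = c("single", "average"), conf_level = 0.95) {
  model <- match.arg(model)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  complete <- stats::complete.cases(x)
  if (!all(complete)) {
    warning(sum(!complete), " row(s) with missing cells dropped", call. = FALSE)
    x <- x[complete, , drop = FALSE]
  }
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) {
    stop("ICC needs at least 2 subjects and 2 measurements", call. = FALSE)
  }
  grand <- mean(x)
  if (sum((x - grand)^2) < .Machine$double.eps * n * k) {
    stop("degenerate table: zero total variance", call. = FALSE)
  }
  ms <- icc_mean_squares(x)
  msr <- ms["msr"]; msc <- ms["msc"]; mse <- ms["mse"]
  est1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  alpha <- 1 - conf_level
  if (mse < 1e-14 * max(msr, 1) && msc < 1e-14 * max(msr, 1)) {
    # no measurement variance at all: the interval is degenerate
    ci1 <- c(est1, est1)
  } else {
    a <- (k * est1) / (n * (1 - est1))
    b <- 1 + (k * est1 * (n - 1)) / (n * (1 - est1))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    low <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    high <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci1 <- c(low, high)
  }
  if (model == "single") {
    est <- est1; ci <- ci1
    model_name <- "two_way_mixed_single_abs"
  } else {
    est <- (msr - mse) / (msr + (msc - mse) / n)
    sb <- function(r) k * r / (1 + (k - 1) * r)
    ci <- sb(ci1)
    model_name <- "two_way_random_avg_abs"
  }
  structure(
    list(estimate = unname(est),
         ci_low = unname(min(ci, est)), ci_high = unname(max(ci, est)),
         conf_level = conf_level,
         model = model_name,
         n_subjects = n, k_measurements = k,
         label = interpret_icc(max(unname(est), 0)),
         mean_squares = c(msr = unname(msr), msc = unname(msc),
                          mse = unname(mse))),
    class = "icc_result"
  )
}

# Two-way ANOVA mean squares: rows = subjects, columns = measurements.
icc_mean_squares <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  ssr <- k * sum((rowMeans(x) - grand)^2)
  ssc <- n * sum((colMeans(x) - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  c(msr = ssr / (n - 1), msc = ssc / (k - 1),
    mse = sse / ((n - 1) * (k - 1)))
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC [%s] = %.3f (%g%% CI %.3f-%.3f), n = %d, k = %d: %s\n",
              x$model, x$estimate, 100 * x$conf_level, x$ci_low, x$ci_high,
              x$n_subjects, x$k_measurements, x$label))
  invisible(x)
}

#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, ci_low = x$ci_low,
                 ci_high = x$ci_high, model = x$model, label = x$label)
}

#' @export
glance.icc_result <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, ci_low = x$ci_low,
                 ci_high = x$ci_high, conf_level = x$conf_level,
                 model = x$model, n_subjects = x$n_subjects,
                 k_measurements = x$k_measurements, label = x$label)
}

#' Interpret an ICC estimate
#'
#' Reliability bands: below 0.50 poor, 0.50 to 0.75 moderate, above 0.75
#' up to 0.90 good, above 0.90 excellent. The published wording overlaps
#' at the cutpoints; this implementation closes the bands as
#' `< 0.50`, `[0.50, 0.75]`, `(0.75, 0.90]`, `> 0.90` so every estimate
#' maps to exactly one label.
#'
#' @param estimate Numeric vector of ICC estimates.
#' @return Character vector of labels, ordered factor levels
#'   poor < moderate < good < excellent.
#' @export
#' @examples
#' interpret_icc(c(0.3, 0.6, 0.84, 0.95))
interpret_icc <- function(estimate) {
  out <- ifelse(estimate < 0.50, "poor",
         ifelse(estimate <= 0.75, "moderate",
         ifelse(estimate <= 0.90, "good", "excellent")))
  factor(out, levels = c("poor", "moderate", "good", "excellent"),
         ordered = TRUE)
}

#' Pearson correlation with Fisher confidence interval
#'
#' Sample Pearson correlation with a confidence interval from the Fisher
#' z-transform (`SE = 1 / sqrt(n - 3)`).
#'
#' @param x,y Numeric vectors of equal length, n >= 4, nonconstant.
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with `r`, `ci_low`, `ci_high`, `n`.
#' @export
pearson_with_ci <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance input", call. = FALSE)
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    ci <- c(r, r)
  } else {
    z <- atanh(r)
    hw <- stats::qnorm(1 - (1 - conf_level) / 2) / sqrt(n - 3)
    ci <- tanh(c(z - hw, z + hw))
  }
  tibble::tibble(r = r, ci_low = ci[1], ci_high = ci[2], n = n)
}

#' Bland-Altman method-comparison statistics
#'
#' Pairwise differences `method1 - method2`: bias (mean difference),
#' sample SD of the differences, limits of agreement at
#' `bias +/- loa_multiplier * sd`, and confidence intervals for the bias
#' (`t * sd / sqrt(n)`) and each limit (`t * sd * sqrt(3 / n)`).
#'
#' @param method1,method2 Numeric vectors of equal length.
#' @param loa_multiplier Limits-of-agreement multiplier (default 1.96).
#' @param conf_level Confidence level for the intervals.
#' @return A `bland_altman` object with fields `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `ci_bias`, `ci_loa_low`, `ci_loa_high`, `n`,
#'   and the per-pair `means`/`differences` used for plotting.
#' @export
bland_altman <- function(method1, method2, loa_multiplier = 1.96,
                         conf_level = 0.95) {
  if (length(method1) != length(method2)) stop("length mismatch", call. = FALSE)
  d <- method1 - method2
  n <- length(d)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  bias <- mean(d)
  sdd <- stats::sd(d)
  loa <- bias + c(-1, 1) * loa_multiplier * sdd
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  ci_bias <- bias + c(-1, 1) * tq * sdd / sqrt(n)
  hw_loa <- tq * sdd * sqrt(3 / n)
  structure(
    list(bias = bias, sd_diff = sdd,
         loa_low = loa[1], loa_high = loa[2],
         ci_bias = ci_bias,
         ci_loa_low = loa[1] + c(-1, 1) * hw_loa,
         ci_loa_high = loa[2] + c(-1, 1) * hw_loa,
         loa_multiplier = loa_multiplier, conf_level = conf_level, n = n,
         means = (method1 + method2) / 2, differences = d),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f (CI %.3f to %.3f), LoA %.3f to %.3f\n",
              x$n, x$bias, x$ci_bias[1], x$ci_bias[2], x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(
    bias = x$bias, sd_diff = x$sd_diff,
    loa_low = x$loa_low, loa_high = x$loa_high,
    ci_bias_low = x$ci_bias[1], ci_bias_high = x$ci_bias[2],
    ci_loa_low_low = x$ci_loa_low[1], ci_loa_low_high = x$ci_loa_low[2],
    ci_loa_high_low = x$ci_loa_high[1], ci_loa_high_high = x$ci_loa_high[2],
    n = x$n
  )
}

#' @export
glance.bland_altman <- function(x, ...) tidy.bland_altman(x)

measure_levels <- c("FL_cm", "PA_deg", "MT_cm")

validate_measurement_table <- function(table) {
  required <- c("subject_id", "intensity", "rater_id", "trial", "method",
                "measure", "value")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols)) {
    stop("measurement table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  key <- table[, c("subject_id", "intensity", "rater_id", "trial", "method",
                   "measure")]
  if (anyDuplicated(key)) {
    stop("duplicate (subject, intensity, rater, trial, method, measure) keys",
         call. = FALSE)
  }
  if (!all(is.finite(table$value))) stop("non-finite values", call. = FALSE)
  invisible(table)
}

#' Full reliability report for a rater measurement table
#'
#' Reproduces the reliability workflow on a long-format table of per-image
#' measurements keyed by subject, contraction intensity, rater, trial, and
#' method. Per measure x intensity x method it computes: the intra-rater
#' ICC (two-way mixed, single rater, absolute agreement, trial 1 vs trial
#' 2 of the repeated rater), the inter-rater ICC(2,k) across raters at
#' trial 1, and the Pearson correlation across trials. Per measure,
#' pooled over intensities and subjects, it computes Bland-Altman
#' statistics comparing the two methods (using each subject-intensity
#' cell's across-rater mean at trial 1). Contrasts whose design cells are
#' missing are skipped with a warning.
#'
#' @param table Data frame with columns `subject_id`, `intensity`,
#'   `rater_id`, `trial`, `method`, `measure`, `value`.
#' @param conf_level Confidence level.
#' @return A `reliability_report` list with tibbles `icc` (one row per
#'   contrast), `pearson`, and `bland_altman`.
#' @export
reliability_report <- function(table, conf_level = 0.95) {
  table <- tibble::as_tibble(table)
  validate_measurement_table(table)
  cells <- dplyr::distinct(table, .data$measure, .data$intensity, .data$method)
  icc_rows <- list(); pearson_rows <- list()
  for (i in seq_len(nrow(cells))) {
    cc <- cells[i, ]
    sub <- dplyr::filter(table, .data$measure == cc$measure,
                         .data$intensity == cc$intensity,
                         .data$method == cc$method)
    # intra-rater: the rater(s) with both trials, trial 1 vs trial 2
    trials <- sort(unique(sub$trial))
    repeated <- sub |>
      dplyr::count(.data$rater_id, .data$trial) |>
      dplyr::count(.data$rater_id) |>
      dplyr::filter(.data$n >= 2)
    if (nrow(repeated) >= 1L && length(trials) >= 2L) {
      rr <- repeated$rater_id[1]
      wide <- sub |>
        dplyr::filter(.data$rater_id == rr,
                      .data$trial %in% trials[1:2]) |>
        tidyr::pivot_wider(id_cols = "subject_id", names_from = "trial",
                           values_from = "value") |>
        dplyr::select(-"subject_id")
      res <- try(icc(wide, model = "single", conf_level = conf_level),
                 silent = TRUE)
      if (!inherits(res, "try-error")) {
        icc_rows[[length(icc_rows) + 1L]] <- dplyr::bind_cols(
          cc, contrast = "intra_rater", rater_id = as.character(rr),
          glance(res))
      }
      pr <- try(pearson_with_ci(wide[[1]], wide[[2]], conf_level), silent = TRUE)
      if (!inherits(pr, "try-error")) {
        pearson_rows[[length(pearson_rows) + 1L]] <-
          dplyr::bind_cols(cc, rater_id = as.character(rr), pr)
      }
    } else {
      warning("intra-rater contrast skipped for ", cc$measure, " / ",
              cc$intensity, " / ", cc$method, ": no repeated rater",
              call. = FALSE)
    }
    # inter-rater: all raters at the first trial
    raters <- sort(unique(sub$rater_id))
    if (length(raters) >= 2L) {
      wide <- sub |>
        dplyr::filter(.data$trial == trials[1]) |>
        tidyr::pivot_wider(id_cols = "subject_id", names_from = "rater_id",
                           values_from = "value") |>
        dplyr::select(-"subject_id")
      res <- try(icc(wide, model = "average", conf_level = conf_level),
                 silent = TRUE)
      if (!inherits(res, "try-error")) {
        icc_rows[[length(icc_rows) + 1L]] <- dplyr::bind_cols(
          cc, contrast = "inter_rater", rater_id = NA_character_,
          glance(res))
      }
    } else {
      warning("inter-rater contrast skipped for ", cc$measure, " / ",
              cc$intensity, " / ", cc$method, ": fewer than 2 raters",
              call. = FALSE)
    }
  }
  # Bland-Altman per measure, methods compared on matched cells
  ba_rows <- list()
  methods <- sort(unique(table$method))
  if (length(methods) == 2L) {
    paired <- table |>
      dplyr::filter(.data$trial == min(.data$trial)) |>
      dplyr::group_by(.data$measure, .data$intensity, .data$subject_id,
                      .data$method) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "method", values_from = "value") |>
      tidyr::drop_na()
    for (m in unique(paired$measure)) {
      pm <- dplyr::filter(paired, .data$measure == m)
      # manual minus semi-automated where those levels are present
      lev <- if (all(c("manual", "semi_automated") %in% methods)) {
        c("manual", "semi_automated")
      } else methods
      ba <- bland_altman(pm[[lev[1]]], pm[[lev[2]]], conf_level = conf_level)
      ba_rows[[length(ba_rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(measure = m, method1 = lev[1], method2 = lev[2]),
        tidy(ba))
    }
  } else {
    warning("Bland-Altman skipped: need exactly 2 methods", call. = FALSE)
  }
  structure(
    list(icc = dplyr::bind_rows(icc_rows),
         pearson = dplyr::bind_rows(pearson_rows),
         bland_altman = dplyr::bind_rows(ba_rows)),
    class = "reliability_report"
  )
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("<reliability_report>\n")
  cat("  ICC contrasts:", nrow(x$icc), "\n")
  cat("  Pearson contrasts:", nrow(x$pearson), "\n")
  cat("  Bland-Altman comparisons:", nrow(x$bland_altman), "\n")
  invisible(x)
}

#' Write a reliability report to CSV (plus JSON mirror)
#'
#' @param report A [reliability_report()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_reliability_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$icc, file.path(dir, "icc.csv"))
  readr::write_csv(report$pearson, file.path(dir, "pearson.csv"))
  readr::write_csv(report$bland_altman, file.path(dir, "bland_altman.csv"))
  jsonlite::write_json(
    lapply(unclass(report), as.data.frame),
    file.path(dir, "reliability.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
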