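# Shared fixtures and independent oracles used across the suite.

# Small, fast phantom used where full size is unnecessary.
small_phantom_spec <- function(seed = 1L, ...) {
  phantom_spec(width_px = 300, height_px = 300,
               superficial_line = c(0, 60), deep_line = c(0, 220),
               seed = seed, ...)
}

# Independent connected-component labeling oracle: plain breadth-first
# search over the pixel grid, no shared code with label_components().
bfs_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  nb <- if (connectivity == 8) {
    expand.grid(dr = -1:1, dc = -1:1)
  } else {
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  for (j in seq_len(nc)) for (i in seq_len(nr)) {  # column-major like raster
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j)); lab[i, j] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (q in seq_len(nrow(nb))) {
          r <- p[1] + nb$dr[q]; c <- p[2] + nb$dc[q]
          if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
              mask[r, c] && lab[r, c] == 0L) {
            lab[r, c] <- cur
            queue[[length(queue) + 1L]] <- c(r, c)
          }
        }
      }
    }
  }
  lab
}

# Independent ICC oracle: mean squares from stats::aov on the long layout,
# plugged into the absolute-agreement formulas written out directly.
aov_icc_oracle <- function(m, model = "single") {
  n <- nrow(m); k <- ncol(m)
  long <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  tab <- summary(stats::aov(y ~ subject + rater, data = long))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  if (model == "single") {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  } else {
    (msr - mse) / (msr + (msc - mse) / n)
  }
}

# Draw a random blob mask: rectangles and rasterized ellipses.
random_blob_mask <- function(nr, nc, n_shapes) {
  m <- matrix(FALSE, nr, nc)
  for (i in seq_len(n_shapes)) {
    if (stats::runif(1) < 0.5) {
      r0 <- sample(nr - 4, 1); c0 <- sample(nc - 4, 1)
      h <- sample(2:12, 1); w <- sample(2:25, 1)
      m[r0:min(nr, r0 + h), c0:min(nc, c0 + w)] <- TRUE
    } else {
      cy <- stats::runif(1, 5, nr - 5); cx <- stats::runif(1, 5, nc - 5)
      a <- stats::runif(1, 2, 18); b <- stats::runif(1, 1, 5)
      th <- stats::runif(1, -pi / 2, pi / 2)
      ix <- which(matrix(TRUE, nr, nc))
      yy <- (ix - 1) %% nr + 1 - cy; xx <- (ix - 1) %/% nr + 1 - cx
      u <- xx * cos(th) + yy * sin(th); v <- -xx * sin(th) + yy * cos(th)
      m[ix[(u / a)^2 + (v / b)^2 <= 1]] <- TRUE
    }
  }
  m
}

# Rasterize an ideal stripe through (cx, cy) at y-up angle theta_deg with
# the given perpendicular half width, restricted to rows [y0, y1].
rasterize_stripe <- function(nr, nc, cx, cy, theta_deg, half_width,
                             y0 = 0, y1 = nr - 1) {
  m_f <- -tan(theta_deg * pi / 180)
  x <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  y <- matrix(rep(0:(nr - 1), times = nc), nr, nc)
  d <- abs(y - (cy + m_f * (x - cx))) / sqrt(1 + m_f^2)
  d <= half_width & y >= y0 & y <= y1
}
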