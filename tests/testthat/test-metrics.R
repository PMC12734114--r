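test_that("stationary gaze yields one long fixation at its centroid", {
  scr <- test_screen()
  df <- make_gaze_df((0:59) / 30, 700, 420)
  out <- ivt_classify(df, scr)
  expect_true(all(out$labels == "fixation"))
  expect_identical(nrow(out$events), 1L)
  expect_equal(out$events$end_s - out$events$start_s, 59 / 30)
  expect_equal(c(out$events$centroid_x, out$events$centroid_y), c(700, 420))
  expect_identical(fixation_count(out$events)$count, 1L)
})

test_that("a single jump splits two stationary clusters into two fixations", {
  scr <- test_screen()
  ts <- (0:59) / 30
  x <- c(rep(400, 30), rep(1000, 30))
  df <- make_gaze_df(ts, x, 540)
  out <- ivt_classify(df, scr)
  expect_identical(nrow(out$events), 2L)
  expect_identical(out$labels[31], "saccade")
  expect_identical(sum(out$labels == "saccade"), 1L)
  expect_equal(out$events$centroid_x, c(400, 1000))
})

test_that("continuous fast sweeps produce no fixations", {
  scr <- test_screen()
  # 1200 px/s = 300 mm/s at 500 mm ~ 33 deg/s, above the 30 deg/s threshold
  df <- make_gaze_df((0:59) / 30, seq(0, 59) * 40, 540)
  out <- ivt_classify(df, scr, v_threshold = 30)
  expect_identical(nrow(out$events), 0L)
  expect_true(all(out$labels[-1] == "saccade"))
})

test_that("classification matches the brute-force oracle on random walks", {
  scr <- test_screen()
  set.seed(99)
  for (rep in 1:20) {
    n <- 120
    ts <- (0:(n - 1)) / 30
    x <- 960 + cumsum(stats::rnorm(n, 0, 4))
    y <- 540 + cumsum(stats::rnorm(n, 0, 4))
    jumps <- sample(10:(n - 10), 3)
    for (j in jumps) x[j:n] <- x[j:n] + sample(c(-400, 400), 1)
    df <- make_gaze_df(ts, x, y)
    got <- ivt_classify(df, scr)
    want <- ivt_oracle(df, scr)
    expect_identical(got$labels, want$labels)
    if (is.null(want$events)) {
      expect_identical(nrow(got$events), 0L)
    } else {
      expect_equal(got$events$start_s, want$events$start_s)
      expect_equal(got$events$end_s, want$events$end_s)
      expect_equal(got$events$n_samples, want$events$n_samples)
    }
  }
})

test_that("IVT respects invalid samples, gaps, and invariances", {
  scr <- test_screen()
  set.seed(7)
  n <- 90
  ts <- (0:(n - 1)) / 30
  ts[46:n] <- ts[46:n] + 0.5          # a long gap breaks the run
  x <- 960 + cumsum(stats::rnorm(n, 0, 3))
  y <- 540 + cumsum(stats::rnorm(n, 0, 3))
  valid <- rep(TRUE, n); valid[20:22] <- FALSE
  df <- make_gaze_df(ts, x, y, valid)
  out <- ivt_classify(df, scr)
  expect_true(all(is.na(out$labels[20:22])))
  oracle <- ivt_oracle(df, scr)
  expect_identical(out$labels, oracle$labels)
  # invariance under time shift and rigid translation
  df2 <- df; df2$timestamp_s <- df2$timestamp_s + 1000
  df3 <- df; df3$gaze_x_px <- df3$gaze_x_px + 55; df3$gaze_y_px <- df3$gaze_y_px - 70
  expect_identical(ivt_classify(df2, scr)$labels, out$labels)
  expect_identical(ivt_classify(df3, scr)$labels, out$labels)
  # raising the threshold never shrinks the fixation sample count
  counts <- vapply(c(10, 20, 30, 50, 100), function(v)
    sum(ivt_classify(df, scr, v_threshold = v)$labels == "fixation", na.rm = TRUE),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("heatmaps conserve mass and peak where the gaze dwells", {
  scr <- test_screen()
  df <- make_gaze_df((0:29) / 30, 700, 420)
  h <- build_heatmap(df, scr, sigma_px = 20, downsample = 4)
  expect_equal(sum(h$values), 1, tolerance = 1e-9)
  expect_true(all(h$values >= 0))
  peak <- which(h$values == max(h$values), arr.ind = TRUE)
  expect_equal(unname((peak[1, "col"] - 0.5) * 4), 700, tolerance = 4)
  expect_equal(unname((peak[1, "row"] - 0.5) * 4), 420, tolerance = 4)
  expect_error(build_heatmap(make_gaze_df(0, 1, 1, valid = FALSE), scr),
               "no valid")
})

test_that("two equal clusters carry equal heatmap mass", {
  scr <- test_screen()
  df <- make_gaze_df((0:99) / 30, c(rep(400, 50), rep(1400, 50)),
                     c(rep(400, 50), rep(700, 50)))
  h <- build_heatmap(df, scr, sigma_px = 25, downsample = 4)
  cx <- (seq_len(ncol(h$values)) - 0.5) * 4
  left <- sum(h$values[, cx < 900]); right <- sum(h$values[, cx >= 900])
  expect_equal(left / right, 1, tolerance = 0.01)
  # two distinct local maxima near the cluster centers
  lhalf <- h$values[, cx < 900]; rhalf <- h$values[, cx >= 900]
  pl <- which(lhalf == max(lhalf), arr.ind = TRUE)[1, ]
  pr <- which(rhalf == max(rhalf), arr.ind = TRUE)[1, ]
  expect_equal(unname((pl["col"] - 0.5) * 4), 400, tolerance = 4)
  expect_equal(unname((pr["col"] + sum(cx < 900) - 0.5) * 4), 1400, tolerance = 4)
})

test_that("a concatenated session is the mixture of its parts", {
  scr <- test_screen()
  a <- make_gaze_df((0:39) / 30, 600, 500)
  b <- make_gaze_df((40:99) / 30, 1300, 640)
  ha <- build_heatmap(a, scr, sigma_px = 30, downsample = 8, normalize = FALSE)
  hb <- build_heatmap(b, scr, sigma_px = 30, downsample = 8, normalize = FALSE)
  hab <- build_heatmap(rbind(a, b), scr, sigma_px = 30, downsample = 8,
                       normalize = FALSE)
  expect_equal(hab$values, ha$values + hb$values, tolerance = 1e-12)
})

test_that("accuracy reports match their closed-form definitions", {
  scr <- test_screen()
  ts <- (0:99) / 30
  truth <- data.frame(timestamp_s = ts,
                      target_x_px = rep(c(480, 1440), each = 50),
                      target_y_px = rep(c(270, 810), each = 50),
                      target_id = rep(1:2, each = 50))
  # perfect prediction: everything zero
  perfect <- make_gaze_df(ts, truth$target_x_px, truth$target_y_px)
  rep0 <- accuracy_report(perfect, truth, scr)
  expect_equal(rep0$overall$mean_error_deg, 0)
  expect_equal(rep0$overall$rmse_x_px, 0)
  # constant +3 px x offset
  off <- make_gaze_df(ts, truth$target_x_px + 3, truth$target_y_px)
  rep1 <- accuracy_report(off, truth, scr)
  expect_equal(rep1$overall$rmse_x_px, 3, tolerance = 1e-12)
  expect_equal(rep1$overall$rmse_y_px, 0)
  # random residuals vs the direct root-mean-square formula
  set.seed(3)
  rx <- stats::rnorm(100, 0, 12); ry <- stats::rnorm(100, 0, 9)
  noisy <- make_gaze_df(ts, truth$target_x_px + rx, truth$target_y_px + ry)
  rep2 <- accuracy_report(noisy, truth, scr)
  expect_equal(rep2$overall$rmse_x_px, sqrt(mean(rx^2)), tolerance = 1e-12)
  expect_equal(rep2$overall$rmse_y_px, sqrt(mean(ry^2)), tolerance = 1e-12)
  # region assignment: targets sit in quadrants 1 and 4
  expect_identical(sort(rep2$per_region$region), c("1", "4"))
  expect_identical(rep2$per_target$target_id, c("1", "2"))
  expect_error(accuracy_report(make_gaze_df(1000, 1, 1), truth, scr),
               "no overlap")
})
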