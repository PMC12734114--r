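make_gaze_df <- function(ts, x, y, valid = TRUE) {
  data.frame(timestamp_s = ts, gaze_x_px = x, gaze_y_px = y,
             valid = rep_len(valid, length(ts)))
}

# independent brute-force velocity-threshold oracle (plain loops, no reuse of
# package internals beyond the metric definition)
ivt_oracle <- function(df, scr, vthr = 30, minfix = 0.06, gap = 3) {
  ok <- which(df$valid)
  ts <- df$timestamp_s[ok]; x <- df$gaze_x_px[ok]; y <- df$gaze_y_px[ok]
  n <- length(ok)
  nominal <- stats::median(diff(ts))
  lab <- rep(NA_character_, nrow(df))
  runs <- list(); cur <- 1
  for (i in seq_len(n - 1)) {
    if (ok[i + 1] - ok[i] > 1 || ts[i + 1] - ts[i] > gap * nominal) {
      runs <- c(runs, list(cur:i)); cur <- i + 1
    }
  }
  runs <- c(runs, list(cur:n))
  events <- NULL
  for (r in runs) {
    if (length(r) < 2) next
    v <- numeric(length(r))
    for (k in 2:length(r)) {
      i <- r[k - 1]; j <- r[k]
      sep <- sqrt(((x[j] - x[i]) * scr$width_mm / scr$res_x)^2 +
                  ((y[j] - y[i]) * scr$height_mm / scr$res_y)^2)
      v[k] <- atan(sep / scr$viewing_distance_mm) * 180 / pi / (ts[j] - ts[i])
    }
    v[1] <- v[2]
    l <- ifelse(v > vthr, "saccade", "fixation")
    lab[ok[r]] <- l
    k <- 1
    while (k <= length(r)) {
      if (l[k] == "fixation") {
        m <- k
        while (m < length(r) && l[m + 1] == "fixation") m <- m + 1
        if (ts[r[m]] - ts[r[k]] >= minfix)
          events <- rbind(events, data.frame(start_s = ts[r[k]], end_s = ts[r[m]],
                                             n_samples = m - k + 1))
        k <- m + 1
      } else k <- k + 1
    }
  }
  list(labels = lab, events = events)
}
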