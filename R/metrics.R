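#' Velocity-threshold (I-VT) fixation/saccade classification
#'
#' Classifies each valid gaze sample by its angular velocity: the visual-angle
#' displacement between consecutive samples divided by their time difference.
#' Samples with velocity strictly above `v_threshold` are saccades, the rest
#' fixations (the first sample of a run inherits the label of its successor).
#' Runs are broken at invalid samples and at timestamp gaps larger than
#' `max_gap_factor` nominal frame intervals; no velocity is computed across a
#' break. Contiguous fixation runs shorter than `min_fix_s` are discarded from
#' the event list. Defaults follow common velocity-threshold practice:
#' 30 deg/s threshold, 60 ms minimum fixation, no gap fill, no merging.
#'
#' @param samples Gaze log data frame (needs `timestamp_s`, `gaze_x_px`,
#'   `gaze_y_px`, `valid`).
#' @param screen A [screen_geometry()].
#' @param v_threshold Saccade velocity threshold in deg/s (default 30).
#' @param min_fix_s Minimum fixation duration in seconds (default 0.06).
#' @param max_gap_factor Timestamp gap, in nominal frame intervals, that
#'   breaks a run (default 3).
#' @return `list(labels, velocity, events)`: per-sample labels (`"fixation"`,
#'   `"saccade"` or `NA` for invalid), per-sample angular velocity (deg/s),
#'   and a data frame of fixation events (`start_s`, `end_s`, `centroid_x`,
#'   `centroid_y`, `n_samples`).
#' @export
ivt_classify <- function(samples, screen, v_threshold = 30, min_fix_s = 0.06,
                         max_gap_factor = 3) {
  n <- nrow(samples)
  labels <- rep(NA_character_, n)
  velocity <- rep(NA_real_, n)
  events <- data.frame(start_s = numeric(0), end_s = numeric(0),
                       centroid_x = numeric(0), centroid_y = numeric(0),
                       n_samples = integer(0))
  ok <- which(samples$valid)
  if (length(ok) < 2)
    return(list(labels = labels, velocity = velocity, events = events))

  ts <- samples$timestamp_s[ok]
  gx <- samples$gaze_x_px[ok]
  gy <- samples$gaze_y_px[ok]
  dts <- diff(ts)
  nominal <- stats::median(dts)
  # a run breaks where consecutive *valid* samples are not adjacent rows or
  # their timestamps gap too widely
  breaks <- diff(ok) > 1 | dts > max_gap_factor * nominal
  run_id <- cumsum(c(0, breaks))

  for (r in unique(run_id)) {
    idx <- which(run_id == r)
    if (length(idx) < 2) next
    i <- ok[idx]
    ang <- visual_angle_error(cbind(gx[idx[-length(idx)]], gy[idx[-length(idx)]]),
                              cbind(gx[idx[-1]], gy[idx[-1]]), screen)
    v <- ang / diff(ts[idx])
    velocity[i[-1]] <- v
    velocity[i[1]] <- v[1]
    lab <- ifelse(c(v[1], v) > v_threshold, "saccade", "fixation")
    labels[i] <- lab

    # fixation events within this run
    fix <- lab == "fixation"
    seg <- cumsum(c(0, abs(diff(fix))))
    for (s in unique(seg[fix])) {
      mem <- i[seg == s & fix]
      dur <- samples$timestamp_s[mem[length(mem)]] - samples$timestamp_s[mem[1]]
      if (dur < min_fix_s) next
      events <- rbind(events, data.frame(
        start_s = samples$timestamp_s[mem[1]],
        end_s = samples$timestamp_s[mem[length(mem)]],
        centroid_x = mean(samples$gaze_x_px[mem]),
        centroid_y = mean(samples$gaze_y_px[mem]),
        n_samples = length(mem)))
    }
  }
  rownames(events) <- NULL
  list(labels = labels, velocity = velocity, events = events)
}

#' Fixation count and mean duration
#'
#' @param events Fixation event data frame from [ivt_classify()].
#' @return `list(count, mean_duration_s)`.
#' @export
fixation_count <- function(events) {
  list(count = nrow(events),
       mean_duration_s = if (nrow(events) == 0) NA_real_ else
         mean(events$end_s - events$start_s))
}

#' Build a gaze heatmap
#'
#' Sum of isotropic Gaussian kernels centred at the valid gaze samples,
#' truncated at three standard deviations and (by default) normalised to unit
#' mass. The grid covers the screen at `1/downsample` resolution; cell (i, j)
#' is centred at `((j - 0.5) * downsample, (i - 0.5) * downsample)` px.
#'
#' @param samples Gaze log data frame.
#' @param screen A [screen_geometry()].
#' @param sigma_px Kernel standard deviation in px (default 2% of screen
#'   width).
#' @param downsample Grid cell size in px (default 1 = full resolution).
#' @param normalize Scale the grid to sum to one (default `TRUE`).
#' @return An object of class `heatmap_grid`: `values` (res_y/ds x res_x/ds
#'   matrix), `downsample`, `normalized`.
#' @export
build_heatmap <- function(samples, screen, sigma_px = 0.02 * screen$res_x,
                          downsample = 1, normalize = TRUE) {
  stopifnot(sigma_px > 0)
  ok <- samples$valid & is.finite(samples$gaze_x_px) & is.finite(samples$gaze_y_px)
  if (!any(ok)) stop("no valid gaze samples to build a heatmap from")
  gx <- samples$gaze_x_px[ok]
  gy <- samples$gaze_y_px[ok]
  nx <- ceiling(screen$res_x / downsample)
  ny <- ceiling(screen$res_y / downsample)
  cx <- (seq_len(nx) - 0.5) * downsample
  cy <- (seq_len(ny) - 0.5) * downsample
  vals <- matrix(0, ny, nx)
  r <- 3 * sigma_px
  for (k in seq_along(gx)) {
    jx <- which(cx >= gx[k] - r & cx <= gx[k] + r)
    jy <- which(cy >= gy[k] - r & cy <= gy[k] + r)
    if (length(jx) == 0 || length(jy) == 0) next
    kx <- exp(-(cx[jx] - gx[k])^2 / (2 * sigma_px^2))
    ky <- exp(-(cy[jy] - gy[k])^2 / (2 * sigma_px^2))
    vals[jy, jx] <- vals[jy, jx] + outer(ky, kx)
  }
  if (normalize) {
    total <- sum(vals)
    if (total > 0) vals <- vals / total
  }
  structure(list(values = vals, downsample = downsample,
                 normalized = normalize, sigma_px = sigma_px),
            class = "heatmap_grid")
}

#' @export
print.heatmap_grid <- function(x, ...) {
  cat(sprintf("<heatmap_grid> %d x %d cells (%g px/cell), mass %.6f\n",
              nrow(x$values), ncol(x$values), x$downsample, sum(x$values)))
  invisible(x)
}

#' Export a heatmap as PNG and as a plain-text matrix
#'
#' The PNG uses the conventional attention colour ramp (blue through green and
#' yellow to red).
#'
#' @param heatmap A `heatmap_grid`.
#' @param png_path Optional PNG output path.
#' @param matrix_path Optional text-matrix output path.
#' @return Invisibly, the paths written.
#' @export
export_heatmap <- function(heatmap, png_path = NULL, matrix_path = NULL) {
  if (!is.null(matrix_path))
    utils::write.table(format(heatmap$values, digits = 9, trim = TRUE,
                              scientific = TRUE),
                       matrix_path, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  if (!is.null(png_path)) {
    ramp <- grDevices::colorRamp(c("blue", "green", "yellow", "red"))
    v <- heatmap$values / max(heatmap$values)
    rgb <- ramp(as.numeric(v)) / 255
    img <- array(0, dim = c(nrow(v), ncol(v), 3))
    for (ch in 1:3) img[, , ch] <- matrix(rgb[, ch], nrow(v), ncol(v))
    png::writePNG(img, png_path)
  }
  invisible(c(png_path, matrix_path))
}

screen_region <- function(x, y, screen) {
  # quadrants split at the screen midlines: 1 TL, 2 TR, 3 BL, 4 BR
  1L + (x >= screen$res_x / 2) + 2L * (y >= screen$res_y / 2)
}

#' Accuracy report against ground-truth targets
#'
#' Joins gaze samples with the true target position at each timestamp and
#' reports mean visual-angle errors (Euclidean and per axis) overall, per
#' target (when the truth log carries a `target_id`) and per screen quadrant
#' of the true target, plus per-axis RMSE in pixels.
#'
#' @param samples Gaze log data frame.
#' @param truth Data frame with `timestamp_s`, `target_x_px`, `target_y_px`
#'   and optionally `target_id`.
#' @param screen A [screen_geometry()].
#' @return An object of class `accuracy_report`: `overall` (mean_error_deg,
#'   mean_error_x_deg, mean_error_y_deg, rmse_x_px, rmse_y_px, n),
#'   `per_target`, `per_region` data frames.
#' @export
accuracy_report <- function(samples, truth, screen) {
  s <- samples[samples$valid, ]
  # timestamps may have passed through text logs; join at microsecond grain
  s$.t <- round(s$timestamp_s, 6)
  truth$.t <- round(truth$timestamp_s, 6)
  truth$timestamp_s <- NULL
  m <- merge(s, truth, by = ".t")
  if (nrow(m) == 0)
    stop("no overlap between gaze samples and ground truth")
  pred <- cbind(m$gaze_x_px, m$gaze_y_px)
  tru <- cbind(m$target_x_px, m$target_y_px)
  err <- visual_angle_error(pred, tru, screen)
  err_x <- visual_angle_error(pred, tru, screen, axis = "x")
  err_y <- visual_angle_error(pred, tru, screen, axis = "y")
  m$region <- screen_region(m$target_x_px, m$target_y_px, screen)

  overall <- list(mean_error_deg = mean(err),
                  mean_error_x_deg = mean(err_x),
                  mean_error_y_deg = mean(err_y),
                  rmse_x_px = sqrt(mean((m$gaze_x_px - m$target_x_px)^2)),
                  rmse_y_px = sqrt(mean((m$gaze_y_px - m$target_y_px)^2)),
                  n = nrow(m))

  agg <- function(group) {
    sp <- split(seq_len(nrow(m)), group)
    do.call(rbind, lapply(names(sp), function(g) {
      i <- sp[[g]]
      data.frame(group = g,
                 mean_error_deg = mean(err[i]),
                 mean_error_x_deg = mean(err_x[i]),
                 mean_error_y_deg = mean(err_y[i]),
                 n = length(i))
    }))
  }
  per_target <- if ("target_id" %in% names(m)) agg(m$target_id) else NULL
  per_region <- agg(m$region)
  names(per_region)[1] <- "region"
  if (!is.null(per_target)) names(per_target)[1] <- "target_id"

  structure(list(overall = overall, per_target = per_target,
                 per_region = per_region),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  o <- x$overall
  cat(sprintf(paste0("<accuracy_report> mean error %.3f deg (x %.3f, y %.3f), ",
                     "RMSE (%.1f, %.1f) px over %d samples\n"),
              o$mean_error_deg, o$mean_error_x_deg, o$mean_error_y_deg,
              o$rmse_x_px, o$rmse_y_px, o$n))
  invisible(x)
}

#' Write an accuracy report and fixation events to disk
#'
#' @param report An `accuracy_report`.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @param events Fixation events data frame from [ivt_classify()].
#' @export
write_events <- function(events, path) {
  out <- events
  for (col in c("start_s", "end_s", "centroid_x", "centroid_y"))
    out[[col]] <- fmt9(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
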