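#' Tracker configuration
#'
#' Thresholds and switches for the per-frame tracking loop.
#'
#' * `head_threshold`: yaw/pitch dead-band in degrees beyond which the head is
#'   declared moving (default 2).
#' * `settle_delta`, `settle_frames`: the head has "stopped moving" when the
#'   inter-frame pose change stays below `settle_delta` degrees for
#'   `settle_frames` consecutive frames (defaults 0.5 and 3); at that moment
#'   the reference point freezes at the current head-pointing.
#' * `update_benchmarks`: recompute the pupil-center benchmarks from
#'   eye-corner displacement during head motion (default `TRUE`; turning it
#'   off is the ablation of the compensation mechanism).
#' * `pitch_sign`: sign applied to the calibration pitch when storing the
#'   head-pointing benchmark angle, so the printed head-pointing formula (a
#'   "+" between the two pitch tangents) reproduces the calibration reference
#'   point exactly; default -1.
#' * `clamp`: clamp off-screen gaze/head-pointing to screen bounds (default
#'   `TRUE`; clamped samples are flagged, never dropped).
#' * `smooth_window`: optional moving-average width in samples for the gaze
#'   output, 0 = off (default).
#'
#' @param head_threshold,settle_delta,settle_frames,update_benchmarks,pitch_sign,clamp,smooth_window
#'   See description.
#' @return A list of class `tracker_config`.
#' @export
tracker_config <- function(head_threshold = 2, settle_delta = 0.5,
                           settle_frames = 3, update_benchmarks = TRUE,
                           pitch_sign = -1, clamp = TRUE, smooth_window = 0) {
  stopifnot(head_threshold > 0, settle_delta > 0, settle_frames >= 1,
            pitch_sign %in% c(-1, 1))
  structure(list(head_threshold = head_threshold,
                 settle_delta = settle_delta,
                 settle_frames = settle_frames,
                 update_benchmarks = update_benchmarks,
                 pitch_sign = pitch_sign,
                 clamp = clamp,
                 smooth_window = smooth_window),
            class = "tracker_config")
}

#' Initialise tracker state from a calibration result
#'
#' @param calibration A `calibration_result` from [run_calibration()].
#' @param config A [tracker_config()].
#' @return A list of class `tracker_state`: current benchmarks (reference
#'   point, updated pupil benchmarks), head state, reference pose, and the
#'   frozen calibration quantities.
#' @export
tracker_state <- function(calibration, config = tracker_config()) {
  b <- calibration$benchmarks
  eq_pose0 <- head_pose(pitch = config$pitch_sign * b$head_pose0$pitch,
                        yaw = b$head_pose0$yaw,
                        roll = b$head_pose0$roll)
  structure(list(
    reference_point = b$reference_point,
    pose_ref = b$head_pose0,       # pose tied to the current reference point
    pupil_left = b$pupil_left,     # current benchmarks Lc*, Rc*
    pupil_right = b$pupil_right,
    cal_pupil_left = b$pupil_left, # calibration benchmarks Lc, Rc
    cal_pupil_right = b$pupil_right,
    cal_corners = b$corners,
    head_pose0 = b$head_pose0,
    eq_pose0 = eq_pose0,           # benchmark angles as used by Eqs (3)-(4)
    scale = calibration$scale,
    face_model = calibration$config$face_model,
    head_state = "fixed",
    last_pose = b$head_pose0,
    still_frames = 0L,
    config = config), class = "tracker_state")
}

#' @export
print.tracker_state <- function(x, ...) {
  cat(sprintf("<tracker_state> head %s, reference (%.1f, %.1f)\n",
              x$head_state, x$reference_point[1], x$reference_point[2]))
  invisible(x)
}

#' Head-state detection
#'
#' The head is "moving" when the yaw or pitch deviation from the pose tied to
#' the current reference-point benchmark strictly exceeds the threshold; the
#' threshold acts as a dead-band, so a deviation exactly at the threshold is
#' still "fixed".
#'
#' @param pose Current [head_pose()].
#' @param state A [tracker_state()].
#' @param threshold Degrees (default from the state's config).
#' @return `"fixed"` or `"moving"`.
#' @export
detect_head_state <- function(pose, state, threshold = state$config$head_threshold) {
  if (!pose$valid) return(state$head_state)
  dev <- max(abs(pose$yaw - state$pose_ref$yaw),
             abs(pose$pitch - state$pose_ref$pitch))
  if (dev > threshold) "moving" else "fixed"
}

#' Head-pointing coordinate on screen
#'
#' Where the head's facing direction intersects the screen, from the current
#' yaw/pitch and the benchmark angles:
#' `dx = d (tan(yaw) - tan(yaw0))`, `dy = d (tan(pitch) + tan(pitch0))` in mm,
#' and `H = (Ox + dx / pitch_mm_x, Oy - dy / pitch_mm_y)` in screen px with O
#' the screen center. `pose0` holds the benchmark angles exactly as they enter
#' these formulas (the tracker stores the calibration pitch pre-multiplied by
#' `pitch_sign`, which makes the printed "+" return H = O at the calibration
#' pose). Out-of-screen H is clamped to the screen bounds and flagged via the
#' `"on_screen"` attribute.
#'
#' @param pose Current [head_pose()].
#' @param pose0 Benchmark angles (yaw0, pitch0) as a [head_pose()].
#' @param screen A [screen_geometry()].
#' @param clamp Clamp to `[0, res - 1]` (default `TRUE`).
#' @return Length-2 screen point in px, attribute `on_screen`.
#' @export
compute_head_pointing <- function(pose, pose0, screen, clamp = TRUE) {
  d <- screen$viewing_distance_mm
  dx <- d * (tan(deg2rad(pose$yaw)) - tan(deg2rad(pose0$yaw)))
  dy <- d * (tan(deg2rad(pose$pitch)) + tan(deg2rad(pose0$pitch)))
  ppx <- screen$width_mm / screen$res_x
  ppy <- screen$height_mm / screen$res_y
  h <- c(screen$res_x / 2 + dx / ppx, screen$res_y / 2 - dy / ppy)
  on_screen <- h[1] >= 0 && h[1] <= screen$res_x - 1 &&
    h[2] >= 0 && h[2] <= screen$res_y - 1
  if (clamp && !on_screen)
    h <- pmin(pmax(h, 0), c(screen$res_x - 1, screen$res_y - 1))
  attr(h, "on_screen") <- on_screen
  h
}

#' Update the pupil-center benchmarks from eye-corner displacement
#'
#' After the head moves, the pupil benchmark for each eye is shifted by the
#' mean of the signed displacement vectors of that eye's inner and outer
#' corners since calibration:
#' `Lc* = Lc + (LI + LO) / 2`, `Rc* = Rc + (RI + RO) / 2`.
#'
#' @param features Current [extract_eye_features()] output.
#' @param corners_cal Calibration corner set (list with `inner_left`,
#'   `outer_left`, `inner_right`, `outer_right`).
#' @param pupil_left_cal,pupil_right_cal Calibration pupil benchmarks Lc, Rc.
#' @return `list(left, right)` updated benchmarks in image px.
#' @export
update_pupil_benchmark <- function(features, corners_cal,
                                   pupil_left_cal, pupil_right_cal) {
  li <- features$inner_corner_left - corners_cal$inner_left
  lo <- features$outer_corner_left - corners_cal$outer_left
  ri <- features$inner_corner_right - corners_cal$inner_right
  ro <- features$outer_corner_right - corners_cal$outer_right
  list(left = pupil_left_cal + (li + lo) / 2,
       right = pupil_right_cal + (ri + ro) / 2)
}

#' Predict the gaze point from the current pupil centers
#'
#' Deviations from the pupil benchmarks, `Lb = L - Lc*` and `Rb = R - Rc*`,
#' are scaled componentwise by the per-eye coefficients and added to the
#' reference point: `LG = H + Lb * Ls`, `RG = H + Rb * Rs`; the reported gaze
#' is the average of LG and RG.
#'
#' @param features Current [extract_eye_features()] output.
#' @param state A [tracker_state()].
#' @param reference Reference point H (default the state's).
#' @return `list(gaze, gaze_left, gaze_right, dev_left, dev_right, on_screen)`.
#' @export
predict_gaze <- function(features, state, reference = state$reference_point) {
  lb <- features$pupil_left - state$pupil_left
  rb <- features$pupil_right - state$pupil_right
  lg <- reference + lb * state$scale$left
  rg <- reference + rb * state$scale$right
  gaze <- (lg + rg) / 2
  list(gaze = gaze, gaze_left = lg, gaze_right = rg,
       dev_left = lb, dev_right = rb)
}

invalid_sample <- function(timestamp, state) {
  data.frame(timestamp_s = timestamp, gaze_x_px = NA_real_, gaze_y_px = NA_real_,
             gaze_left_x = NA_real_, gaze_left_y = NA_real_,
             gaze_right_x = NA_real_, gaze_right_y = NA_real_,
             head_state = state$head_state,
             ref_x = state$reference_point[1], ref_y = state$reference_point[2],
             valid = FALSE)
}

#' Advance the tracker by one frame
#'
#' Extracts features and head pose, detects the head state, and predicts the
#' gaze sample. While the head is moving, the head-pointing coordinate and the
#' pupil benchmarks are recomputed every frame so gaze output never pauses;
#' when the inter-frame pose change stays below the settle threshold for the
#' configured number of frames the reference point freezes at the current
#' head-pointing and the state returns to "fixed". Feature or pose failures
#' yield an invalid sample and leave the state untouched.
#'
#' @param frame A [landmark_frame()].
#' @param state A [tracker_state()].
#' @param intrinsics A [camera_intrinsics()].
#' @param screen A [screen_geometry()].
#' @return `list(sample, state)`: a one-row gaze data frame and the updated
#'   state.
#' @export
track_step <- function(frame, state, intrinsics, screen) {
  feats <- tryCatch(extract_eye_features(frame), error = function(e) NULL)
  if (is.null(feats))
    return(list(sample = invalid_sample(frame$timestamp, state), state = state))
  pose <- estimate_head_pose(feats$pnp_points, state$face_model, intrinsics)
  if (!pose$valid)
    return(list(sample = invalid_sample(frame$timestamp, state), state = state))

  cfg <- state$config
  new_state <- detect_head_state(pose, state)
  reference <- state$reference_point

  if (new_state == "moving") {
    h <- compute_head_pointing(pose, state$eq_pose0, screen, clamp = cfg$clamp)
    if (cfg$update_benchmarks) {
      upd <- update_pupil_benchmark(feats, state$cal_corners,
                                    state$cal_pupil_left, state$cal_pupil_right)
      state$pupil_left <- upd$left
      state$pupil_right <- upd$right
    }
    reference <- as.numeric(h)
    delta <- max(abs(pose$yaw - state$last_pose$yaw),
                 abs(pose$pitch - state$last_pose$pitch))
    state$still_frames <- if (delta < cfg$settle_delta)
      state$still_frames + 1L else 0L
    if (state$still_frames >= cfg$settle_frames) {
      # motion has ceased: freeze the reference point at the current
      # head-pointing and re-anchor the head-state dead-band here
      state$reference_point <- reference
      state$pose_ref <- pose
      new_state <- "fixed"
      state$still_frames <- 0L
    }
  } else {
    state$still_frames <- 0L
  }
  state$head_state <- new_state
  state$last_pose <- pose

  g <- predict_gaze(feats, state, reference = reference)
  gaze <- g$gaze
  on_screen <- gaze[1] >= 0 && gaze[1] <= screen$res_x - 1 &&
    gaze[2] >= 0 && gaze[2] <= screen$res_y - 1
  if (cfg$clamp && !on_screen)
    gaze <- pmin(pmax(gaze, 0), c(screen$res_x - 1, screen$res_y - 1))

  sample <- data.frame(
    timestamp_s = frame$timestamp,
    gaze_x_px = gaze[1], gaze_y_px = gaze[2],
    gaze_left_x = g$gaze_left[1], gaze_left_y = g$gaze_left[2],
    gaze_right_x = g$gaze_right[1], gaze_right_y = g$gaze_right[2],
    head_state = new_state,
    ref_x = reference[1], ref_y = reference[2],
    valid = TRUE)
  sample$dev_left_x <- g$dev_left[1]; sample$dev_left_y <- g$dev_left[2]
  sample$dev_right_x <- g$dev_right[1]; sample$dev_right_y <- g$dev_right[2]
  sample$on_screen <- on_screen
  list(sample = sample, state = state)
}

#' Track a whole landmark stream
#'
#' Runs [track_step()] over every frame and optionally applies the
#' moving-average output filter.
#'
#' @param frames List of [landmark_frame()]s.
#' @param calibration A `calibration_result`.
#' @param intrinsics A [camera_intrinsics()].
#' @param screen A [screen_geometry()].
#' @param config A [tracker_config()].
#' @return A gaze log data frame (one row per frame).
#' @export
track_stream <- function(frames, calibration, intrinsics, screen,
                         config = tracker_config()) {
  state <- tracker_state(calibration, config)
  rows <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    st <- track_step(frames[[i]], state, intrinsics, screen)
    rows[[i]] <- st$sample
    state <- st$state
  }
  log <- do.call(rbind, rows)
  rownames(log) <- NULL
  if (config$smooth_window > 1) {
    k <- config$smooth_window
    sm <- function(v) stats::filter(v, rep(1 / k, k), sides = 1)
    ok <- log$valid
    for (col in c("gaze_x_px", "gaze_y_px")) {
      smoothed <- as.numeric(sm(log[[col]]))
      log[[col]] <- ifelse(is.na(smoothed) | !ok, log[[col]], smoothed)
    }
  }
  log
}

#' Write / read a gaze log (CSV + JSON sidecar)
#'
#' CSV columns: `timestamp_s, gaze_x_px, gaze_y_px, gaze_left_x, gaze_left_y,
#' gaze_right_x, gaze_right_y, head_state, ref_x, ref_y, valid`, written at 9
#' significant digits for a bit-exact round trip. The sidecar records the
#' screen geometry, tracker configuration and a hash of the calibration.
#'
#' @param log Gaze log data frame from [track_stream()].
#' @param path CSV output path.
#' @param screen A [screen_geometry()].
#' @param config A [tracker_config()].
#' @param calibration Optional `calibration_result` to hash into the sidecar.
#' @return `path`, invisibly.
#' @export
write_gaze_log <- function(log, path, screen = NULL, config = NULL,
                           calibration = NULL) {
  cols <- c("timestamp_s", "gaze_x_px", "gaze_y_px", "gaze_left_x",
            "gaze_left_y", "gaze_right_x", "gaze_right_y", "head_state",
            "ref_x", "ref_y", "valid")
  out <- log[cols]
  for (col in setdiff(cols, c("head_state", "valid")))
    out[[col]] <- fmt9(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  side <- list(n_samples = nrow(log))
  if (!is.null(screen)) side$screen <- unclass(screen)
  if (!is.null(config)) side$config <- unclass(config)
  if (!is.null(calibration)) {
    key <- paste(fmt9(c(calibration$benchmarks$pupil_left,
                        calibration$benchmarks$pupil_right,
                        calibration$scale$left, calibration$scale$right)),
                 collapse = ",")
    side$calibration_hash <- sprintf("%08x", sum(utf8ToInt(key) *
                                                   seq_along(utf8ToInt(key))) %% 0xFFFFFFFF)
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_gaze_log
#' @export
read_gaze_log <- function(path) {
  df <- utils::read.csv(path)
  df$valid <- as.logical(df$valid)
  df
}
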