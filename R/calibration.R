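#' Five-point calibration dot layout
#'
#' Dot 1 at the screen center, then top, left, bottom, right edge dots inset
#' by `margin` pixels from the respective screen edge. The upper/lower dots
#' determine the y-axis scale coefficients and the left/right dots the x-axis
#' coefficients.
#'
#' @param screen A [screen_geometry()].
#' @param margin Edge inset in px (default 30).
#' @return Data frame with columns `index`, `x`, `y`.
#' @export
calibration_dots <- function(screen, margin = 30) {
  cx <- screen$res_x / 2
  cy <- screen$res_y / 2
  data.frame(index = 1:5,
             x = c(cx, cx, margin, cx, screen$res_x - margin),
             y = c(cy, margin, cy, screen$res_y - margin, cy))
}

calibration_error <- function(msg) {
  stop(errorCondition(msg, class = c("gazetrack_calibration_failed", "error")))
}

#' Aggregate per-dot features over the final dwell window
#'
#' The user fixates each calibration dot for about `dwell` seconds; the
#' arithmetic mean of every feature coordinate and pose angle over the samples
#' in the last `window` seconds is the per-dot measurement.
#'
#' @param samples List of `list(timestamp, features, pose)` entries in time
#'   order (features from [extract_eye_features()], pose a [head_pose()]).
#' @param dwell Nominal dwell time in seconds (default 2).
#' @param window Averaging window at the end of the dwell, in seconds
#'   (default 0.5).
#' @return `list(features, pose, n)` with componentwise means.
#' @export
aggregate_dot_features <- function(samples, dwell = 2, window = 0.5) {
  if (length(samples) == 0) calibration_error("no samples at calibration dot")
  ts <- vapply(samples, function(s) s$timestamp, numeric(1))
  if (max(ts) - min(ts) < window)
    calibration_error(sprintf(
      "samples span %.3f s, less than the %.3f s averaging window",
      max(ts) - min(ts), window))
  keep <- samples[ts >= max(ts) - window]
  if (length(keep) == 0) calibration_error("empty averaging window")

  mean_pts <- function(get) {
    m <- do.call(rbind, lapply(keep, get))
    colMeans(m)
  }
  feats <- structure(list(
    pupil_left = mean_pts(function(s) s$features$pupil_left),
    pupil_right = mean_pts(function(s) s$features$pupil_right),
    inner_corner_left = mean_pts(function(s) s$features$inner_corner_left),
    outer_corner_left = mean_pts(function(s) s$features$outer_corner_left),
    inner_corner_right = mean_pts(function(s) s$features$inner_corner_right),
    outer_corner_right = mean_pts(function(s) s$features$outer_corner_right),
    pnp_points = Reduce("+", lapply(keep, function(s) s$features$pnp_points)) /
      length(keep)), class = "eye_features")
  pose <- head_pose(
    pitch = mean(vapply(keep, function(s) s$pose$pitch, numeric(1))),
    yaw = mean(vapply(keep, function(s) s$pose$yaw, numeric(1))),
    roll = mean(vapply(keep, function(s) s$pose$roll, numeric(1))))
  list(features = feats, pose = pose, n = length(keep))
}

#' Per-eye scale coefficients from the four edge dots
#'
#' The x coefficient is the screen separation of the right and left dots over
#' the corresponding pupil-center separation; the y coefficient is the
#' bottom/top analogue:
#' `Ls = ((C5x - C3x)/(L5x - L3x), (C4y - C2y)/(L4y - L2y))`, and the same for
#' the right eye.
#'
#' @param dots The [calibration_dots()] data frame (rows 2..5 used).
#' @param pupils_left,pupils_right 4x2 matrices of mean pupil centers at dots
#'   2 (top), 3 (left), 4 (bottom), 5 (right), in image px.
#' @param sanity Admissible magnitude range for each coefficient
#'   (default `c(5, 500)` screen-px per image-px).
#' @return `list(left = c(sx, sy), right = c(sx, sy))`, class
#'   `scale_coefficients`.
#' @export
compute_scale_coefficients <- function(dots, pupils_left, pupils_right,
                                       sanity = c(5, 500)) {
  d <- dots[match(2:5, dots$index), ]
  one_eye <- function(p) {
    dx <- p[4, 1] - p[2, 1]   # right dot minus left dot pupil x
    dy <- p[3, 2] - p[1, 2]   # bottom dot minus top dot pupil y
    if (dx == 0 || dy == 0)
      calibration_error("zero pupil displacement between opposite edge dots")
    c(sx = (d$x[4] - d$x[2]) / dx, sy = (d$y[3] - d$y[1]) / dy)
  }
  sc <- structure(list(left = one_eye(rbind(pupils_left)),
                       right = one_eye(rbind(pupils_right))),
                  class = "scale_coefficients")
  mags <- abs(c(sc$left, sc$right))
  if (any(!is.finite(mags)) || any(mags < sanity[1]) || any(mags > sanity[2]))
    calibration_error(sprintf(
      "scale coefficient magnitude outside sanity range [%g, %g]",
      sanity[1], sanity[2]))
  sc
}

#' Head-stability check over the five calibration dots
#'
#' The head must stay still during calibration: the yaw/pitch deviation of
#' every dot's pose from the dot-1 pose must not exceed `threshold` degrees
#' (roll is ignored, matching what the tracker uses downstream). A deviation
#' exactly at the threshold still passes.
#'
#' @param poses List of five [head_pose()]s, dot 1 first.
#' @param threshold Degrees (default 2, the head-state threshold).
#' @return `TRUE` (stable) or `FALSE`.
#' @export
validate_head_stability <- function(poses, threshold = 2) {
  ref <- poses[[1]]
  dev <- vapply(poses, function(p)
    max(abs(p$yaw - ref$yaw), abs(p$pitch - ref$pitch)), numeric(1))
  max(dev) <= threshold
}

#' Run the five-point calibration on a landmark stream
#'
#' Frames are assigned to dots by timestamp (`dwell` seconds per dot in dot
#' order), per-dot features are aggregated over the final `window` seconds,
#' head stability is validated, the per-eye scale coefficients are computed
#' from the edge dots, and the benchmarks (reference point = screen center,
#' pupil centers, eye corners, head pose) are taken from dot 1.
#'
#' @param frames List of [landmark_frame()]s covering all five dots in order.
#' @param screen A [screen_geometry()].
#' @param intrinsics A [camera_intrinsics()].
#' @param face_model 6x3 generic face model (see [default_face_model()]).
#' @param dots Dot layout (default [calibration_dots()] at 30 px margin).
#' @param dwell,window Seconds per dot and averaging window (defaults 2, 0.5).
#' @param stability_threshold Degrees (default 2).
#' @param pupil_method Passed to [extract_eye_features()].
#' @return An object of class `calibration_result`: `benchmarks` (reference
#'   point, pupil centers Lc/Rc, corner set, head pose), `scale`
#'   (`scale_coefficients`), `per_dot` aggregates, `stability_ok`, `config`.
#'   Signals a condition of class `gazetrack_calibration_failed` when the user
#'   must recalibrate.
#' @export
run_calibration <- function(frames, screen, intrinsics, face_model,
                            dots = calibration_dots(screen),
                            dwell = 2, window = 0.5,
                            stability_threshold = 2,
                            pupil_method = "iris_center") {
  ts <- vapply(frames, function(f) f$timestamp, numeric(1))
  t0 <- min(ts)
  per_dot <- vector("list", 5)
  for (i in 1:5) {
    in_dot <- ts - t0 >= (i - 1) * dwell & ts - t0 < i * dwell
    if (!any(in_dot))
      calibration_error(sprintf("no samples at calibration dot %d", i))
    samples <- lapply(frames[in_dot], function(f) {
      feats <- extract_eye_features(f, pupil_method = pupil_method)
      pose <- estimate_head_pose(feats$pnp_points, face_model, intrinsics)
      if (!pose$valid)
        calibration_error(sprintf("head pose failed during calibration dot %d", i))
      list(timestamp = f$timestamp, features = feats, pose = pose)
    })
    per_dot[[i]] <- aggregate_dot_features(samples, dwell = dwell, window = window)
  }

  if (!validate_head_stability(lapply(per_dot, `[[`, "pose"),
                               threshold = stability_threshold))
    calibration_error(
      "head moved during calibration beyond the stability threshold; recalibrate")

  scale <- compute_scale_coefficients(
    dots,
    pupils_left = t(vapply(per_dot[2:5], function(d) d$features$pupil_left, numeric(2))),
    pupils_right = t(vapply(per_dot[2:5], function(d) d$features$pupil_right, numeric(2))))

  f1 <- per_dot[[1]]$features
  benchmarks <- list(
    reference_point = c(dots$x[dots$index == 1], dots$y[dots$index == 1]),
    pupil_left = f1$pupil_left,
    pupil_right = f1$pupil_right,
    corners = list(inner_left = f1$inner_corner_left,
                   outer_left = f1$outer_corner_left,
                   inner_right = f1$inner_corner_right,
                   outer_right = f1$outer_corner_right),
    head_pose0 = per_dot[[1]]$pose)

  structure(list(benchmarks = benchmarks, scale = scale, per_dot = per_dot,
                 stability_ok = TRUE,
                 config = list(dwell = dwell, window = window,
                               stability_threshold = stability_threshold,
                               pupil_method = pupil_method,
                               dots = dots,
                               face_model = face_model)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(paste0("<calibration_result> Ls = (%.2f, %.2f), Rs = (%.2f, %.2f),",
                     " stability %s\n"),
              x$scale$left[1], x$scale$left[2],
              x$scale$right[1], x$scale$right[2],
              if (x$stability_ok) "ok" else "FAILED"))
  invisible(x)
}

#' Serialize / restore a calibration result as JSON
#'
#' Saves every benchmark, the scale coefficients, per-dot aggregates and the
#' configuration echo so that tracking sessions can be replayed from a saved
#' calibration.
#'
#' @param cal A `calibration_result`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_calibration()` returns the restored object.
#' @export
write_calibration <- function(cal, path) {
  ser <- list(
    benchmarks = list(
      reference_point = cal$benchmarks$reference_point,
      pupil_left = cal$benchmarks$pupil_left,
      pupil_right = cal$benchmarks$pupil_right,
      corners = cal$benchmarks$corners,
      head_pose0 = unclass(cal$benchmarks$head_pose0)),
    scale = unclass(cal$scale),
    per_dot = lapply(cal$per_dot, function(d)
      list(features = unclass(d$features), pose = unclass(d$pose), n = d$n)),
    stability_ok = cal$stability_ok,
    config = list(dwell = cal$config$dwell, window = cal$config$window,
                  stability_threshold = cal$config$stability_threshold,
                  pupil_method = cal$config$pupil_method,
                  dots = cal$config$dots,
                  face_model = as.numeric(cal$config$face_model)))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  num2 <- function(x) as.numeric(unlist(x))
  hp <- s$benchmarks$head_pose0
  restore_pose <- function(p)
    head_pose(pitch = p$pitch, yaw = p$yaw, roll = p$roll)
  restore_feats <- function(f) {
    out <- lapply(f[setdiff(names(f), "pnp_points")], num2)
    out$pnp_points <- if (is.matrix(f$pnp_points)) f$pnp_points else
      do.call(rbind, lapply(f$pnp_points, num2))
    class(out) <- "eye_features"
    out
  }
  structure(list(
    benchmarks = list(
      reference_point = num2(s$benchmarks$reference_point),
      pupil_left = num2(s$benchmarks$pupil_left),
      pupil_right = num2(s$benchmarks$pupil_right),
      corners = lapply(s$benchmarks$corners, num2),
      head_pose0 = restore_pose(hp)),
    scale = structure(list(left = num2(s$scale$left),
                           right = num2(s$scale$right)),
                      class = "scale_coefficients"),
    per_dot = lapply(s$per_dot, function(d)
      list(features = restore_feats(d$features),
           pose = restore_pose(d$pose),
           n = d$n)),
    stability_ok = isTRUE(s$stability_ok),
    config = list(dwell = s$config$dwell, window = s$config$window,
                  stability_threshold = s$config$stability_threshold,
                  pupil_method = s$config$pupil_method,
                  dots = data.frame(index = num2(s$config$dots$index),
                                    x = num2(s$config$dots$x),
                                    y = num2(s$config$dots$y)),
                  face_model = matrix(num2(s$config$face_model), ncol = 3))),
    class = "calibration_result")
}
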