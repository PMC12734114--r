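#' Generic six-point face model
#'
#' 3D coordinates (mm) of the six facial points used for head-pose
#' estimation, in the head frame: x right, y down, z depth (into the head,
#' away from the camera when the face looks at the screen), nose tip at the
#' origin. Row order: nose tip, chin, left mouth corner, right mouth corner,
#' left outer eye corner, right outer eye corner ("left"/"right" are image
#' sides). Dimensions follow typical adult anthropometry.
#'
#' @return 6x3 numeric matrix.
#' @export
default_face_model <- function() {
  m <- rbind(
    nose_tip = c(0, 0, 0),
    chin = c(0, 65, 15),
    mouth_left = c(-28, 35, 12),
    mouth_right = c(28, 35, 12),
    eye_outer_left = c(-47.5, -35, 18),
    eye_outer_right = c(47.5, -35, 18))
  colnames(m) <- c("x", "y", "z")
  m
}

#' Synthetic rig configuration
#'
#' A rigid head with two rotating eyeballs, observed by a pinhole webcam
#' mounted at the top-center of the screen and tilted down toward the eyes.
#' World frame = screen frame in mm (origin at the screen's top-left corner,
#' x right, y down, z out of the screen toward the user). The head's nose tip
#' sits at `head_position` (defaults: screen center x, eye line at screen
#' center height, viewing distance in z); head rotations pivot about a neck
#' point below/behind the face origin so rotation also translates the eyes.
#'
#' @param screen A [screen_geometry()].
#' @param intrinsics A [camera_intrinsics()]; default a 640x480 webcam with
#'   600 px focal length and zero distortion.
#' @param head_position Nose-tip world position at the neutral pose (mm).
#' @param camera_position Camera center in world mm (default top-center of
#'   the screen).
#' @param camera_tilt_deg Downward camera tilt; `NULL` (default) aims the
#'   camera at the eye midpoint.
#' @param eyeball_radius Rotation-center-to-pupil distance in mm (default 12).
#' @param iris_radius Iris ring radius in mm (default 5.5).
#' @param interocular Distance between eyeball centers in mm (default 65).
#' @param neck_pivot Head-frame pivot of head rotations (default 80 mm below,
#'   40 mm behind the face origin).
#' @param noise_sigma Isotropic Gaussian landmark jitter in px (default 0).
#' @param seed RNG seed for the jitter (default 1).
#' @return An object of class `rig_config`.
#' @export
rig_config <- function(screen = screen_geometry(),
                       intrinsics = camera_intrinsics(600, 600, 320, 240, 640, 480),
                       head_position = NULL,
                       camera_position = NULL,
                       camera_tilt_deg = NULL,
                       eyeball_radius = 12,
                       iris_radius = 5.5,
                       interocular = 65,
                       neck_pivot = c(0, 80, 40),
                       noise_sigma = 0,
                       seed = 1L) {
  stopifnot(noise_sigma >= 0, eyeball_radius > 0)
  d <- screen$viewing_distance_mm
  if (is.null(head_position))
    head_position <- c(screen$width_mm / 2, screen$height_mm / 2 + 35, d)
  if (is.null(camera_position))
    camera_position <- c(screen$width_mm / 2, 0, 0)
  eye_y <- head_position[2] - 35
  eye_z <- head_position[3] + 30
  if (is.null(camera_tilt_deg))
    camera_tilt_deg <- rad2deg(atan2(eye_y - camera_position[2],
                                     eye_z - camera_position[3]))
  if (head_position[3] <= 0) stop("head must sit in front of the screen")
  face <- default_face_model()
  eyes <- rbind(left = c(-interocular / 2, -35, 30),
                right = c(interocular / 2, -35, 30))
  inner <- rbind(left = c(-interocular / 2 + 15, -35, 18),
                 right = c(interocular / 2 - 15, -35, 18))
  structure(list(screen = screen, intrinsics = intrinsics,
                 head_position = head_position,
                 camera_position = camera_position,
                 camera_tilt_deg = camera_tilt_deg,
                 eyeball_radius = eyeball_radius,
                 iris_radius = iris_radius,
                 face_model = face,
                 eye_centers = eyes,
                 inner_corners = inner,
                 neck_pivot = neck_pivot,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "rig_config")
}

#' @export
print.rig_config <- function(x, ...) {
  cat(sprintf("<rig_config> head at (%.0f, %.0f, %.0f) mm, noise %.2f px, seed %d\n",
              x$head_position[1], x$head_position[2], x$head_position[3],
              x$noise_sigma, x$seed))
  invisible(x)
}

rig_camera_rotation <- function(rig) rot_x(deg2rad(rig$camera_tilt_deg))

head_to_world <- function(points, pose, rig) {
  R <- pose_rotation(pose$yaw, pose$pitch, pose$roll)
  p <- sweep(matrix(points, ncol = 3), 2, rig$neck_pivot)
  p <- p %*% t(R)
  sweep(p, 2, rig$neck_pivot + rig$head_position, "+")
}

rig_project <- function(points_world, rig) {
  pc <- sweep(matrix(points_world, ncol = 3), 2, rig$camera_position)
  pc <- pc %*% t(rig_camera_rotation(rig))
  project_points(pc, diag(3), c(0, 0, 0), rig$intrinsics)
}

#' Render one synthetic landmark frame
#'
#' Rotates the rigid head to the scenario's pose, aims each eyeball so its
#' optical axis passes through the 3D target position on the screen plane
#' (pupil = eyeball center + radius x gaze direction), projects all landmark
#' points through the pinhole camera, and adds seeded Gaussian jitter when the
#' rig's `noise_sigma > 0` (drawn from the current RNG state; use
#' [render_stream()] for seeded streams).
#'
#' @param scenario A scenario from [make_fixation_scenario()],
#'   [make_pursuit_scenario()] or [make_calibration_scenario()].
#' @param t Time in seconds within `[0, duration]`.
#' @param rig A [rig_config()].
#' @return `list(frame, target, pose_world, pose_camera)`: the
#'   [landmark_frame()], the true target in screen px, the commanded
#'   world-frame pose and the ground-truth pose in the camera frame (what a
#'   pose estimator should recover).
#' @export
render_frame <- function(scenario, t, rig) {
  if (t < 0 || t > scenario$duration) stop("t outside scenario duration")
  target_px <- scenario$target_fn(t)
  pose <- scenario$pose_fn(t)
  target_mm <- c(px_to_mm(target_px, rig$screen), 0)

  lm <- GAZE_LANDMARKS
  face_w <- head_to_world(rig$face_model, pose, rig)
  inner_w <- head_to_world(rig$inner_corners, pose, rig)
  eyes_w <- head_to_world(rig$eye_centers, pose, rig)

  pupil_w <- ring_w <- NULL
  ring_ids <- integer(0)
  for (e in 1:2) {
    g <- target_mm - eyes_w[e, ]
    g <- g / sqrt(sum(g^2))
    pupil <- eyes_w[e, ] + rig$eyeball_radius * g
    # iris ring: 4 points on a circle perpendicular to the gaze direction
    u <- pracma_cross(g, c(0, 1, 0)); u <- u / sqrt(sum(u^2))
    v <- pracma_cross(g, u)
    ring <- rbind(pupil + rig$iris_radius * u, pupil + rig$iris_radius * v,
                  pupil - rig$iris_radius * u, pupil - rig$iris_radius * v)
    pupil_w <- rbind(pupil_w, pupil)
    ring_w <- rbind(ring_w, ring)
  }
  ids <- c(lm$nose_tip, lm$chin, lm$mouth_left, lm$mouth_right,
           lm$left_eye_outer, lm$right_eye_outer,
           lm$left_eye_inner, lm$right_eye_inner,
           lm$left_iris_center, lm$left_iris_ring,
           lm$right_iris_center, lm$right_iris_ring)
  pts_world <- rbind(face_w, inner_w,
                     pupil_w[1, , drop = FALSE], ring_w[1:4, ],
                     pupil_w[2, , drop = FALSE], ring_w[5:8, ])
  proj <- rig_project(pts_world, rig)
  if (rig$noise_sigma > 0)
    proj <- proj + matrix(stats::rnorm(length(proj), 0, rig$noise_sigma),
                          ncol = 2)

  frame <- landmark_frame(
    timestamp = t,
    points = data.frame(id = ids, x = proj[, 1], y = proj[, 2]),
    image_width = rig$intrinsics$image_width,
    image_height = rig$intrinsics$image_height,
    source = "synthetic")

  R_total <- rig_camera_rotation(rig) %*%
    pose_rotation(pose$yaw, pose$pitch, pose$roll)
  list(frame = frame, target = target_px, pose_world = pose,
       pose_camera = pose_from_rotation(R_total))
}

#' Render a whole scenario into a landmark stream plus ground truth
#'
#' Samples the scenario at its rate, seeding the RNG once from the rig seed so
#' identical seeds give bitwise-identical streams.
#'
#' @param scenario A scenario object.
#' @param rig A [rig_config()].
#' @param t0 Offset added to all emitted timestamps (seconds, default 0) so
#'   that streams can be concatenated into one monotone log.
#' @return `list(frames, truth)`: the landmark frames and a truth data frame
#'   (`timestamp_s`, `target_x_px`, `target_y_px`, `yaw_deg`, `pitch_deg`,
#'   `roll_deg` in the camera frame, and `target_id` when the scenario has a
#'   dot schedule).
#' @export
render_stream <- function(scenario, rig, t0 = 0) {
  n <- round(scenario$duration * scenario$rate)
  ts <- (seq_len(n) - 1) / scenario$rate
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(rig$seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  frames <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    rf <- render_frame(scenario, ts[i], rig)
    rf$frame$timestamp <- ts[i] + t0
    frames[[i]] <- rf$frame
    row <- data.frame(timestamp_s = ts[i] + t0,
                      target_x_px = rf$target[1], target_y_px = rf$target[2],
                      yaw_deg = rf$pose_camera$yaw,
                      pitch_deg = rf$pose_camera$pitch,
                      roll_deg = rf$pose_camera$roll)
    if (!is.null(scenario$target_id_fn))
      row$target_id <- scenario$target_id_fn(ts[i])
    truth[[i]] <- row
  }
  list(frames = frames, truth = do.call(rbind, truth))
}

head_angles_toward <- function(point_px, screen) {
  p <- px_to_mm(point_px, screen)
  d <- screen$viewing_distance_mm
  c(yaw = rad2deg(atan((p[1] - screen$width_mm / 2) / d)),
    pitch = rad2deg(atan((screen$height_mm / 2 - p[2]) / d)))
}

make_pose_schedule <- function(targets_px, onsets, dwell, screen, head_mode,
                               head_fraction, yaw_limit, pitch_limit,
                               transition_s = 0.5) {
  if (head_mode == "fixed")
    return(function(t) head_pose(0, 0, 0))
  angles <- t(apply(targets_px, 1, head_angles_toward, screen = screen))
  angles <- cbind(
    yaw = pmin(pmax(head_fraction * angles[, "yaw"], -yaw_limit), yaw_limit),
    pitch = pmin(pmax(head_fraction * angles[, "pitch"], -pitch_limit), pitch_limit))
  function(t) {
    k <- findInterval(t, onsets)
    if (k < 1) k <- 1
    cur <- angles[k, ]
    prev <- if (k == 1) c(yaw = 0, pitch = 0) else angles[k - 1, ]
    dt <- t - onsets[k]
    w <- if (dt >= transition_s) 1 else dt / transition_s
    a <- prev + w * (cur - prev)
    head_pose(pitch = a["pitch"], yaw = a["yaw"], roll = 0)
  }
}

#' Fixation-grid scenario (the 16-dot task)
#'
#' Dots appear row-major, left to right then top to bottom, each dwelling
#' `dwell` seconds, on a uniform `n_cols` x `n_rows` grid (dot centers at the
#' cell midpoints). With `head_mode = "toward_target"` the head rotates a
#' configurable fraction of the way toward each dot (linearly over a short
#' transition, then holds), clipped to the yaw/pitch limits; with `"fixed"`
#' the head stays at the neutral pose.
#'
#' @param screen A [screen_geometry()].
#' @param n_cols,n_rows Grid size (default 4x4).
#' @param dwell Seconds per dot (default 3).
#' @param rate Sampling rate in Hz (default 30).
#' @param head_mode `"fixed"` or `"toward_target"`.
#' @param head_fraction Fraction of the full target angle the head turns
#'   (default 0.5).
#' @param yaw_limit,pitch_limit Head-rotation clip in degrees (defaults 18
#'   and 10).
#' @return A scenario object (list with `duration`, `rate`, `target_fn`,
#'   `pose_fn`, `target_id_fn`, `kind`, `meta`).
#' @export
make_fixation_scenario <- function(screen, n_cols = 4, n_rows = 4, dwell = 3,
                                   rate = 30,
                                   head_mode = c("fixed", "toward_target"),
                                   head_fraction = 0.5,
                                   yaw_limit = 18, pitch_limit = 10) {
  head_mode <- match.arg(head_mode)
  xs <- screen$res_x * (seq_len(n_cols) - 0.5) / n_cols
  ys <- screen$res_y * (seq_len(n_rows) - 0.5) / n_rows
  grid <- expand.grid(x = xs, y = ys)[, c("x", "y")]  # row-major: x fastest
  n <- nrow(grid)
  onsets <- (seq_len(n) - 1) * dwell
  duration <- n * dwell
  dot_at <- function(t) as.integer(min(max(findInterval(t, onsets), 1), n))
  pose_fn <- make_pose_schedule(as.matrix(grid), onsets, dwell, screen,
                                head_mode, head_fraction, yaw_limit, pitch_limit)
  list(duration = duration, rate = rate,
       target_fn = function(t) as.numeric(grid[dot_at(t), ]),
       pose_fn = pose_fn,
       target_id_fn = function(t) dot_at(t),
       kind = "fixation",
       meta = list(grid = grid, dwell = dwell, head_mode = head_mode,
                   head_fraction = head_fraction,
                   yaw_limit = yaw_limit, pitch_limit = pitch_limit))
}

#' Calibration scenario (five dots, fixed head)
#'
#' @param screen A [screen_geometry()].
#' @param dots Dot layout from [calibration_dots()].
#' @param dwell Seconds per dot (default 2).
#' @param rate Sampling rate in Hz (default 30).
#' @return A scenario object.
#' @export
make_calibration_scenario <- function(screen, dots = calibration_dots(screen),
                                      dwell = 2, rate = 30) {
  onsets <- (dots$index - 1) * dwell
  dot_at <- function(t) min(max(findInterval(t, onsets), 1), nrow(dots))
  list(duration = nrow(dots) * dwell, rate = rate,
       target_fn = function(t) c(dots$x[dot_at(t)], dots$y[dot_at(t)]),
       pose_fn = function(t) head_pose(0, 0, 0),
       target_id_fn = function(t) dot_at(t),
       kind = "calibration",
       meta = list(dots = dots, dwell = dwell))
}

#' Smooth-pursuit scenarios
#'
#' Rectangular: the target traverses a centred rectangle clockwise at
#' `speed_px_s` starting from the upper-left vertex. Circular: clockwise sweep
#' at `omega_deg_s` on a circle of `radius_px` around the screen center,
#' starting at the top of the circle. Duration is one full lap (for the
#' circle, exactly `360 / omega_deg_s` seconds).
#'
#' @param kind `"rect"` or `"circle"`.
#' @param screen A [screen_geometry()].
#' @param speed_px_s Rectangular speed (default 120 px/s).
#' @param rect_size `c(width, height)` of the rectangle in px (default
#'   1200x700, centred).
#' @param omega_deg_s Circular angular speed (default 15 deg/s).
#' @param radius_px Circle radius (default 350 px).
#' @param rate Sampling rate in Hz (default 30).
#' @param head_mode `"fixed"` or `"toward_target"` (continuous tracking).
#' @param head_fraction,yaw_limit,pitch_limit As in
#'   [make_fixation_scenario()].
#' @return A scenario object.
#' @export
make_pursuit_scenario <- function(kind = c("rect", "circle"), screen,
                                  speed_px_s = 120, rect_size = c(1200, 700),
                                  omega_deg_s = 15, radius_px = 350,
                                  rate = 30,
                                  head_mode = c("fixed", "toward_target"),
                                  head_fraction = 0.5,
                                  yaw_limit = 18, pitch_limit = 10) {
  kind <- match.arg(kind)
  head_mode <- match.arg(head_mode)
  cx <- screen$res_x / 2; cy <- screen$res_y / 2
  if (kind == "rect") {
    w <- rect_size[1]; h <- rect_size[2]
    if (w > screen$res_x || h > screen$res_y)
      stop("rectangle exceeds screen bounds")
    perim <- 2 * (w + h)
    duration <- perim / speed_px_s
    x0 <- cx - w / 2; y0 <- cy - h / 2
    target_fn <- function(t) {
      s <- (speed_px_s * t) %% perim
      if (s < w) c(x0 + s, y0)
      else if (s < w + h) c(x0 + w, y0 + (s - w))
      else if (s < 2 * w + h) c(x0 + w - (s - w - h), y0 + h)
      else c(x0, y0 + h - (s - 2 * w - h))
    }
  } else {
    if (radius_px > min(cx, cy)) stop("circle exceeds screen bounds")
    duration <- 360 / omega_deg_s
    target_fn <- function(t) {
      phi <- deg2rad(omega_deg_s * t)
      c(cx + radius_px * sin(phi), cy - radius_px * cos(phi))
    }
  }
  pose_fn <- if (head_mode == "fixed") function(t) head_pose(0, 0, 0) else
    function(t) {
      a <- head_angles_toward(target_fn(t), screen)
      head_pose(pitch = min(max(head_fraction * a["pitch"], -pitch_limit), pitch_limit),
                yaw = min(max(head_fraction * a["yaw"], -yaw_limit), yaw_limit),
                roll = 0)
    }
  list(duration = duration, rate = rate, target_fn = target_fn,
       pose_fn = pose_fn, target_id_fn = NULL,
       kind = paste0("pursuit_", kind),
       meta = list(kind = kind, speed_px_s = speed_px_s,
                   rect_size = rect_size, omega_deg_s = omega_deg_s,
                   radius_px = radius_px, head_mode = head_mode))
}

#' Run the full pipeline on the synthetic rig
#'
#' Renders a five-dot calibration stream with the head at the neutral pose,
#' calibrates, renders the scenario stream, tracks it, and scores the
#' predicted gaze against the rig's ground truth.
#'
#' @param scenario A scenario object.
#' @param rig A [rig_config()].
#' @param config A [tracker_config()].
#' @param cal_dwell Calibration dwell per dot in seconds (default 2).
#' @param cal_margin Calibration edge-dot margin in px (default 30).
#' @return `list(calibration, gaze, truth, report)`.
#' @export
run_closed_loop <- function(scenario, rig, config = tracker_config(),
                            cal_dwell = 2, cal_margin = 30) {
  dots <- calibration_dots(rig$screen, margin = cal_margin)
  cal_scn <- make_calibration_scenario(rig$screen, dots, dwell = cal_dwell,
                                       rate = scenario$rate)
  cal_stream <- render_stream(cal_scn, rig)
  calibration <- run_calibration(cal_stream$frames, rig$screen, rig$intrinsics,
                                 face_model = rig$face_model, dots = dots,
                                 dwell = cal_dwell)
  stream <- render_stream(scenario, rig)
  gaze <- track_stream(stream$frames, calibration, rig$intrinsics, rig$screen,
                       config = config)
  report <- accuracy_report(gaze, stream$truth, rig$screen)
  list(calibration = calibration, gaze = gaze, truth = stream$truth,
       report = report)
}
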