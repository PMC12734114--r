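# shared fixture builders: everything is generated in code at test time

test_screen <- function() screen_geometry(1920, 1080, 480, 270, 500)
test_intrinsics <- function() camera_intrinsics(600, 600, 320, 240, 640, 480)
test_rig <- function(...) rig_config(test_screen(), ...)

# a minimal landmark frame holding the 14 consumed ids at given coordinates
make_test_frame <- function(timestamp = 0, pupil_left = c(100, 50),
                            pupil_right = c(160, 50), drop_ids = integer(0)) {
  lm <- GAZE_LANDMARKS
  ids <- c(lm$nose_tip, lm$chin, lm$mouth_left, lm$mouth_right,
           lm$left_eye_outer, lm$right_eye_outer,
           lm$left_eye_inner, lm$right_eye_inner,
           lm$left_iris_center, lm$right_iris_center)
  xy <- rbind(c(130, 80), c(130, 150), c(110, 115), c(150, 115),
              c(85, 50), c(175, 50), c(115, 50), c(145, 50),
              pupil_left, pupil_right)
  keep <- !(ids %in% drop_ids)
  landmark_frame(timestamp,
                 data.frame(id = ids[keep], x = xy[keep, 1], y = xy[keep, 2]),
                 image_width = 640, image_height = 480)
}

# eye_features object with explicit fields, for algebraic tests
make_test_features <- function(pupil_left = c(100, 50), pupil_right = c(160, 50),
                               shift = c(0, 0)) {
  structure(list(
    pupil_left = pupil_left + shift,
    pupil_right = pupil_right + shift,
    inner_corner_left = c(115, 50) + shift,
    outer_corner_left = c(85, 50) + shift,
    inner_corner_right = c(145, 50) + shift,
    outer_corner_right = c(175, 50) + shift,
    pnp_points = matrix(c(130, 130, 110, 150, 85, 175,
                          80, 150, 115, 115, 50, 50), ncol = 2) +
      matrix(shift, 6, 2, byrow = TRUE)),
    class = "eye_features")
}

# time-ordered calibration samples with optional per-sample feature generator
make_dot_samples <- function(times, feat_fn, pose = head_pose(0, 0, 0)) {
  lapply(times, function(t)
    list(timestamp = t, features = feat_fn(t), pose = pose))
}

# synthetic checkerboard corner views projected with known intrinsics
make_board_views <- function(intr, n_views = 12, board = c(6, 8, 25),
                             seed = 7) {
  set.seed(seed)
  obj <- expand.grid(corner_col = 0:(board[2] - 1),
                     corner_row = 0:(board[1] - 1))
  lapply(seq_len(n_views), function(v) {
    R <- pose_rotation(stats::runif(1, -25, 25), stats::runif(1, -20, 20),
                       stats::runif(1, -10, 10))
    tr <- c(stats::runif(1, -60, 60), stats::runif(1, -40, 40),
            stats::runif(1, 400, 800))
    p <- project_points(cbind(obj$corner_col * board[3],
                              obj$corner_row * board[3], 0), R, tr, intr)
    data.frame(corner_row = obj$corner_row, corner_col = obj$corner_col,
               x_px = p[, 1], y_px = p[, 2])
  })
}

# a scenario that fixates one static target with a supplied pose schedule
make_static_scenario <- function(target, duration, rate = 30,
                                 pose_fn = function(t) head_pose(0, 0, 0)) {
  list(duration = duration, rate = rate,
       target_fn = function(t) target,
       pose_fn = pose_fn,
       target_id_fn = NULL, kind = "static", meta = list())
}

# small, fast closed-loop fixture (4-dot grid at reduced rate)
small_fixation_loop <- function(head_mode = "fixed", rate = 15, dwell = 2, ...) {
  scr <- test_screen()
  rig <- test_rig()
  scn <- make_fixation_scenario(scr, n_cols = 2, n_rows = 2, dwell = dwell,
                                rate = rate, head_mode = head_mode)
  run_closed_loop(scn, rig, ...)
}
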