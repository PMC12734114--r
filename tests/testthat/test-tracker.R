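fake_state <- function(pose_ref = head_pose(0, 0, 0)) {
  list(pose_ref = pose_ref, head_state = "fixed", config = tracker_config())
}

test_that("head-state detection is a strict dead-band on yaw and pitch", {
  st <- fake_state()
  expect_identical(detect_head_state(head_pose(0.3, 0.5, 0), st), "fixed")
  expect_identical(detect_head_state(head_pose(0, 2.5, 0), st), "moving")
  # exactly at the threshold: still fixed (strict >)
  expect_identical(detect_head_state(head_pose(2, 0, 0), st), "fixed")
  # invalid pose leaves the state unchanged
  st$head_state <- "moving"
  expect_identical(detect_head_state(head_pose(valid = FALSE), st), "moving")
})

test_that("head-pointing follows the tangent geometry", {
  scr <- test_screen()
  # zero-offset case: yaw at benchmark, pitch at minus the stored benchmark
  h <- compute_head_pointing(head_pose(pitch = -3, yaw = 5),
                             head_pose(pitch = 3, yaw = 5), scr)
  expect_equal(as.numeric(h), c(960, 540), tolerance = 1e-12)
  expect_true(attr(h, "on_screen"))
  # tangent oracle: 500 tan(10 deg) = 88.163 mm -> +352.65 px
  h <- compute_head_pointing(head_pose(0, 10), head_pose(0, 0), scr)
  expect_equal(as.numeric(h), c(960 + 500 * tan(10 * pi / 180) / 0.25, 540),
               tolerance = 1e-9)
  expect_equal(h[1], 1312.654, tolerance = 1e-3)
  # 45 degrees points 2000 px right of center: clamped and flagged
  h <- compute_head_pointing(head_pose(0, 45), head_pose(0, 0), scr)
  expect_equal(as.numeric(h), c(1919, 540))
  expect_false(attr(h, "on_screen"))
})

test_that("pupil benchmarks shift by the mean corner displacement", {
  cal <- make_test_features()
  corners <- list(inner_left = cal$inner_corner_left,
                  outer_left = cal$outer_corner_left,
                  inner_right = cal$inner_corner_right,
                  outer_right = cal$outer_corner_right)
  # LI = (10, 0), LO = (12, 0) -> Lc* = Lc + (11, 0)
  now <- cal
  now$inner_corner_left <- cal$inner_corner_left + c(10, 0)
  now$outer_corner_left <- cal$outer_corner_left + c(12, 0)
  upd <- update_pupil_benchmark(now, corners, c(100, 50), c(160, 50))
  expect_equal(upd$left, c(111, 50))
  expect_equal(upd$right, c(160, 50))
  # zero displacement is the identity
  upd <- update_pupil_benchmark(cal, corners, c(100, 50), c(160, 50))
  expect_equal(upd$left, c(100, 50))
})

test_that("gaze prediction maps pupil deviations through the coefficients", {
  st <- list(pupil_left = c(100, 50), pupil_right = c(160, 50),
             scale = list(left = c(90, 80), right = c(90, 80)),
             reference_point = c(960, 540))
  # zero deviation: gaze at the reference point
  g <- predict_gaze(make_test_features(), st)
  expect_equal(g$gaze, c(960, 540))
  # Lb = (2, 0) at sx = 90 on both eyes: x advances 180 px
  g <- predict_gaze(make_test_features(shift = c(2, 0)), st)
  expect_equal(g$gaze_left, c(1140, 540))
  expect_equal(g$gaze, c(1140, 540))
  expect_equal(g$dev_left, c(2, 0))
})

test_that("a static head reduces the tracker to plain pupil-offset mapping", {
  scr <- test_screen()
  rig <- test_rig()
  loop <- small_fixation_loop(head_mode = "fixed")
  expect_true(all(loop$gaze$head_state == "fixed"))
  expect_true(all(loop$gaze$ref_x == 960 & loop$gaze$ref_y == 540))
  # algebraic identity with direct benchmark mapping on a sample frame
  cal <- loop$calibration
  scn <- make_fixation_scenario(scr, n_cols = 2, n_rows = 2, dwell = 2,
                                rate = 15, head_mode = "fixed")
  fr <- render_frame(scn, 3.0, rig)$frame
  f <- extract_eye_features(fr)
  lg <- c(960, 540) + (f$pupil_left - cal$benchmarks$pupil_left) * cal$scale$left
  rg <- c(960, 540) + (f$pupil_right - cal$benchmarks$pupil_right) * cal$scale$right
  row <- loop$gaze[abs(loop$gaze$timestamp_s - 3.0) < 1e-9, ]
  expect_equal(c(row$gaze_x_px, row$gaze_y_px), unname((lg + rg) / 2),
               tolerance = 1e-9)
})

test_that("a head turn drives fixed -> moving -> fixed and refreezes the reference", {
  scr <- test_screen()
  rig <- test_rig()
  dots <- calibration_dots(scr)
  cal_scn <- make_calibration_scenario(scr, dots, dwell = 2, rate = 15)
  cal <- run_calibration(render_stream(cal_scn, rig)$frames, scr,
                         rig$intrinsics, rig$face_model, dots = dots, dwell = 2)
  # gaze holds the screen center; the head turns 8 degrees over 0.5 s
  scn <- make_static_scenario(c(960, 540), duration = 4, rate = 30,
                              pose_fn = function(t) {
                                yaw <- if (t < 1) 0 else min((t - 1) / 0.5, 1) * 8
                                head_pose(0, yaw, 0)
                              })
  stream <- render_stream(scn, rig)
  gaze <- track_stream(stream$frames, cal, rig$intrinsics, scr)
  states <- rle(gaze$head_state)$values
  expect_identical(states, c("fixed", "moving", "fixed"))
  # after settling the reference point matches the head-pointing recomputed
  # from that frame's estimated pose
  settle <- which(gaze$head_state == "fixed" &
                    c("", gaze$head_state[-nrow(gaze)]) == "moving")[1]
  f <- extract_eye_features(stream$frames[[settle]])
  pose <- estimate_head_pose(f$pnp_points, rig$face_model, rig$intrinsics)
  eq0 <- head_pose(pitch = -cal$benchmarks$head_pose0$pitch,
                   yaw = cal$benchmarks$head_pose0$yaw)
  h <- compute_head_pointing(pose, eq0, scr)
  expect_equal(c(gaze$ref_x[settle], gaze$ref_y[settle]), as.numeric(h),
               tolerance = 1e-6)
  # and the reference stays put afterwards
  expect_true(all(gaze$ref_x[settle:nrow(gaze)] == gaze$ref_x[settle]))
})

test_that("feature failures yield invalid samples and leave state untouched", {
  loop <- small_fixation_loop(head_mode = "fixed")
  state <- tracker_state(loop$calibration)
  bad <- make_test_frame(drop_ids = GAZE_LANDMARKS$right_iris_center)
  out <- track_step(bad, state, test_intrinsics(), test_screen())
  expect_false(out$sample$valid)
  expect_identical(out$state, state)
})

test_that("predicted gaze is invariant to a common landmark translation", {
  # translating pupils and corners together shifts the updated benchmark by
  # the same vector, so the deviation (and hence the gaze) cancels exactly
  cal <- make_test_features()
  corners <- list(inner_left = cal$inner_corner_left,
                  outer_left = cal$outer_corner_left,
                  inner_right = cal$inner_corner_right,
                  outer_right = cal$outer_corner_right)
  st <- list(scale = list(left = c(90, 80), right = c(85, 75)),
             reference_point = c(700, 400))
  for (shift in list(c(12.5, -3), c(-40, 22))) {
    now <- make_test_features(pupil_left = c(103, 48), shift = shift)
    upd <- update_pupil_benchmark(now, corners, c(100, 50), c(160, 50))
    st$pupil_left <- upd$left; st$pupil_right <- upd$right
    g <- predict_gaze(now, st)
    ref <- make_test_features(pupil_left = c(103, 48))
    upd0 <- update_pupil_benchmark(ref, corners, c(100, 50), c(160, 50))
    st0 <- st; st0$pupil_left <- upd0$left; st0$pupil_right <- upd0$right
    expect_equal(g$gaze, predict_gaze(ref, st0)$gaze, tolerance = 1e-12)
  }
})

test_that("tracking identical streams is bitwise deterministic", {
  scr <- test_screen()
  rig <- test_rig(noise_sigma = 0.3, seed = 5)
  dots <- calibration_dots(scr)
  cal_scn <- make_calibration_scenario(scr, dots, dwell = 2, rate = 15)
  cal <- run_calibration(render_stream(cal_scn, rig)$frames, scr,
                         rig$intrinsics, rig$face_model, dots = dots, dwell = 2)
  scn <- make_static_scenario(c(1400, 300), duration = 1, rate = 30)
  frames <- render_stream(scn, rig)$frames
  g1 <- track_stream(frames, cal, rig$intrinsics, scr)
  g2 <- track_stream(frames, cal, rig$intrinsics, scr)
  expect_identical(g1, g2)
})

test_that("gaze logs round-trip through CSV with their sidecar", {
  loop <- small_fixation_loop(head_mode = "fixed")
  path <- withr::local_tempfile(fileext = ".csv")
  write_gaze_log(loop$gaze, path, screen = test_screen(),
                 config = tracker_config(), calibration = loop$calibration)
  back <- read_gaze_log(path)
  expect_equal(nrow(back), nrow(loop$gaze))
  expect_equal(back$gaze_x_px, loop$gaze$gaze_x_px, tolerance = 1e-7)
  expect_type(back$valid, "logical")
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_true(!is.null(side$calibration_hash))
})
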