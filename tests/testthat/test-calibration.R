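test_that("per-dot aggregation averages the final window", {
  # constant features are idempotent under averaging
  ts <- seq(0, 2, by = 1 / 30)
  const <- make_dot_samples(ts, function(t) make_test_features())
  agg <- aggregate_dot_features(const)
  expect_equal(agg$features$pupil_left, c(100, 50))
  expect_equal(agg$pose$yaw, 0)

  # linear ramp: mean over exactly the last-0.5 s samples (brute force)
  ramp <- make_dot_samples(ts, function(t)
    make_test_features(pupil_left = c(100 + 5 * t, 50)))
  agg <- aggregate_dot_features(ramp, dwell = 2, window = 0.5)
  sel <- ts >= max(ts) - 0.5
  expect_equal(agg$features$pupil_left[1], mean(100 + 5 * ts[sel]),
               tolerance = 1e-12)
  expect_identical(agg$n, sum(sel))

  # too short a span cannot fill the window
  short <- make_dot_samples(c(0, 0.1, 0.2), function(t) make_test_features())
  expect_error(aggregate_dot_features(short),
               class = "gazetrack_calibration_failed")
})

test_that("scale coefficients follow the edge-dot displacement ratios", {
  scr <- test_screen()
  dots <- calibration_dots(scr, margin = 60)
  # C5x - C3x = 1800, L5x - L3x = 20  ->  sx = 90
  pl <- rbind(c(120, 40), c(110, 55), c(120, 60), c(130, 55))
  pr <- pl + 60
  sc <- compute_scale_coefficients(dots, pl, pr)
  expect_equal(unname(sc$left[1]), 1800 / 20)
  expect_equal(unname(sc$left[2]), (1020 - 60) / 20)
  # equal per-eye deltas give equal coefficients
  expect_equal(sc$right, sc$left)
  # zero x-displacement between the left and right dots is degenerate
  bad <- rbind(c(120, 40), c(110, 55), c(120, 60), c(110, 55))  # L5x == L3x
  expect_error(compute_scale_coefficients(dots, bad, pr),
               class = "gazetrack_calibration_failed")
})

test_that("scale coefficients depend only on pupil differences", {
  scr <- test_screen()
  dots <- calibration_dots(scr)
  pl <- rbind(c(120, 40), c(110, 55), c(120, 60), c(130, 55))
  pr <- pl + 40
  base <- compute_scale_coefficients(dots, pl, pr)
  shifted <- compute_scale_coefficients(dots, pl + 17.3, pr + 17.3)
  expect_equal(shifted, base)
})

test_that("head-stability validation compares yaw/pitch against dot 1", {
  same <- replicate(5, head_pose(0, 0, 0), simplify = FALSE)
  expect_true(validate_head_stability(same))
  drift <- same; drift[[4]] <- head_pose(0, 3, 0)
  expect_false(validate_head_stability(drift))
  # a deviation exactly at the threshold still passes
  edge <- same; edge[[3]] <- head_pose(2, 0, 0)
  expect_true(validate_head_stability(edge, threshold = 2))
  # roll is ignored
  rolled <- same; rolled[[2]] <- head_pose(0, 0, 10)
  expect_true(validate_head_stability(rolled))
})

test_that("rig calibration recovers the rig's own benchmarks", {
  scr <- test_screen()
  rig <- test_rig()
  dots <- calibration_dots(scr)
  scn <- make_calibration_scenario(scr, dots, dwell = 2, rate = 15)
  frames <- render_stream(scn, rig)$frames
  cal <- run_calibration(frames, scr, rig$intrinsics, rig$face_model,
                         dots = dots, dwell = 2)
  expect_true(cal$stability_ok)
  expect_equal(cal$benchmarks$reference_point, c(960, 540))
  # pupil benchmark equals the rig's projected pupil while gazing dot 1
  truth <- extract_eye_features(render_frame(scn, 1.9, rig)$frame)
  expect_equal(cal$benchmarks$pupil_left, truth$pupil_left, tolerance = 1e-6)
  expect_equal(cal$benchmarks$pupil_right, truth$pupil_right, tolerance = 1e-6)
  # neutral rig head pose seen through the tilted camera: zero yaw
  expect_lt(abs(cal$benchmarks$head_pose0$yaw), 1e-4)
  # deterministic given the same stream
  cal2 <- run_calibration(frames, scr, rig$intrinsics, rig$face_model,
                          dots = dots, dwell = 2)
  expect_equal(cal$scale, cal2$scale)
})

test_that("head motion or missing dots abort the calibration", {
  scr <- test_screen()
  rig <- test_rig()
  dots <- calibration_dots(scr)
  scn <- make_calibration_scenario(scr, dots, dwell = 2, rate = 15)
  # 3-degree yaw during dot 3 breaks the stability rule
  scn_moved <- scn
  scn_moved$pose_fn <- function(t)
    if (t >= 4 && t < 6) head_pose(0, 3, 0) else head_pose(0, 0, 0)
  frames <- render_stream(scn_moved, rig)$frames
  expect_error(run_calibration(frames, scr, rig$intrinsics, rig$face_model,
                               dots = dots, dwell = 2),
               class = "gazetrack_calibration_failed")
  # stream ending after 4 dots
  frames <- render_stream(scn, rig)$frames
  ts <- vapply(frames, function(f) f$timestamp, numeric(1))
  expect_error(run_calibration(frames[ts < 8], scr, rig$intrinsics,
                               rig$face_model, dots = dots, dwell = 2),
               class = "gazetrack_calibration_failed")
})

test_that("doubling the rig's pupil excursion roughly halves the coefficients", {
  scr <- test_screen()
  dots <- calibration_dots(scr)
  scn <- make_calibration_scenario(scr, dots, dwell = 2, rate = 15)
  cal1 <- run_calibration(render_stream(scn, test_rig())$frames, scr,
                          test_intrinsics(), default_face_model(),
                          dots = dots, dwell = 2)
  cal2 <- run_calibration(render_stream(scn, test_rig(eyeball_radius = 24))$frames,
                          scr, test_intrinsics(), default_face_model(),
                          dots = dots, dwell = 2)
  ratio <- c(cal2$scale$left / cal1$scale$left,
             cal2$scale$right / cal1$scale$right)
  expect_equal(unname(ratio), rep(0.5, 4), tolerance = 0.05)
})

test_that("calibration results survive the JSON round trip", {
  scr <- test_screen()
  rig <- test_rig()
  dots <- calibration_dots(scr)
  scn <- make_calibration_scenario(scr, dots, dwell = 2, rate = 15)
  frames <- render_stream(scn, rig)$frames
  cal <- run_calibration(frames, scr, rig$intrinsics, rig$face_model,
                         dots = dots, dwell = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_equal(back$benchmarks$pupil_left, cal$benchmarks$pupil_left)
  expect_equal(back$scale$left, unname(cal$scale$left))
  expect_equal(back$config$face_model, unname(cal$config$face_model))
  # a restored calibration drives the tracker to identical output
  task <- make_static_scenario(c(1200, 700), duration = 0.5, rate = 30)
  stream <- render_stream(task, rig)$frames
  g1 <- track_stream(stream, cal, rig$intrinsics, scr)
  g2 <- track_stream(stream, back, rig$intrinsics, scr)
  expect_equal(g2$gaze_x_px, g1$gaze_x_px, tolerance = 1e-9)
})
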