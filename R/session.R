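#' Session configuration
#'
#' One place for everything a tracking session needs. Defaults mirror the
#' evaluation setup the package is built around: a 1920x1080 screen viewed
#' from 500 mm, 30 Hz sampling, 2 degree head-state threshold, 3 s fixation
#' dwell, 120 px/s rectangular and 15 deg/s circular pursuit with a 350 px
#' radius. Values can be loaded from a YAML file and overridden per call.
#'
#' @param path Optional YAML file; its top-level keys override the defaults.
#' @param ... Further overrides (named, same keys).
#' @return A list of class `session_config` with elements `screen`
#'   (a [screen_geometry()]), `rig` options, `tracker` (a [tracker_config()]),
#'   `ivt`, `calibration`, `scenario` and `seed`.
#' @export
session_config <- function(path = NULL, ...) {
  defaults <- list(
    screen = list(res_x = 1920, res_y = 1080, width_mm = 480, height_mm = 270,
                  viewing_distance_mm = 500),
    rig = list(noise_sigma = 0, seed = 1),
    tracker = list(head_threshold = 2, settle_delta = 0.5, settle_frames = 3,
                   update_benchmarks = TRUE, pitch_sign = -1, clamp = TRUE,
                   smooth_window = 0),
    ivt = list(v_threshold = 30, min_fix_s = 0.06, max_gap_factor = 3),
    calibration = list(dwell = 2, window = 0.5, margin = 30,
                       stability_threshold = 2),
    scenario = list(rate = 30, dwell = 3, head_mode = "fixed",
                    head_fraction = 0.5, yaw_limit = 18, pitch_limit = 10,
                    speed_px_s = 120, omega_deg_s = 15, radius_px = 350),
    heatmap = list(sigma_frac = 0.02, downsample = 4),
    seed = 1L)
  cfg <- defaults
  merge_in <- function(cfg, upd) {
    for (k in names(upd)) {
      cfg[[k]] <- if (is.list(upd[[k]]) && is.list(cfg[[k]]))
        utils::modifyList(cfg[[k]], upd[[k]]) else upd[[k]]
    }
    cfg
  }
  if (!is.null(path)) cfg <- merge_in(cfg, yaml::read_yaml(path))
  dots <- list(...)
  if (length(dots)) cfg <- merge_in(cfg, dots)
  structure(cfg, class = "session_config")
}

config_screen <- function(cfg) do.call(screen_geometry, cfg$screen)
config_tracker <- function(cfg) do.call(tracker_config, cfg$tracker)

build_scenario <- function(cfg, task, screen) {
  sc <- cfg$scenario
  switch(task,
    fixation = make_fixation_scenario(
      screen, dwell = sc$dwell, rate = sc$rate, head_mode = sc$head_mode,
      head_fraction = sc$head_fraction, yaw_limit = sc$yaw_limit,
      pitch_limit = sc$pitch_limit),
    pursuit_rect = make_pursuit_scenario(
      "rect", screen, speed_px_s = sc$speed_px_s, rate = sc$rate,
      head_mode = sc$head_mode, head_fraction = sc$head_fraction,
      yaw_limit = sc$yaw_limit, pitch_limit = sc$pitch_limit),
    pursuit_circle = make_pursuit_scenario(
      "circle", screen, omega_deg_s = sc$omega_deg_s,
      radius_px = sc$radius_px, rate = sc$rate, head_mode = sc$head_mode,
      head_fraction = sc$head_fraction, yaw_limit = sc$yaw_limit,
      pitch_limit = sc$pitch_limit),
    stop("unknown task: ", task))
}

#' Run a complete task end to end
#'
#' Calibrate, track, and analyse one of the built-in tasks, writing every
#' artifact (gaze log + sidecar, fixation events, heatmap matrix and PNG,
#' accuracy report JSON) into `out_dir`. With the `synthetic` backend the
#' input stream comes from the rig; with `replay` it is read from
#' `landmarks` (scenario ground truth must then be supplied as `truth`).
#'
#' @param config A [session_config()].
#' @param task `"fixation"`, `"pursuit_rect"` or `"pursuit_circle"`.
#' @param backend `"synthetic"` or `"replay"`.
#' @param out_dir Output directory (created if missing).
#' @param landmarks,truth Replay inputs: landmark log CSV path and truth data
#'   frame (or CSV path), ignored for the synthetic backend.
#' @param verbose Narrate progress (default `FALSE`).
#' @return Invisibly, `list(report, gaze, events, heatmap, paths)`. A
#'   calibration failure signals `gazetrack_calibration_failed` (the user
#'   must recalibrate).
#' @export
run_task <- function(config, task = c("fixation", "pursuit_rect", "pursuit_circle"),
                     backend = c("synthetic", "replay"),
                     out_dir = tempfile("gazetrack_"),
                     landmarks = NULL, truth = NULL, verbose = FALSE) {
  task <- match.arg(task)
  backend <- match.arg(backend)
  screen <- config_screen(config)
  tcfg <- config_tracker(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  scenario <- build_scenario(config, task, screen)
  rig <- rig_config(screen, noise_sigma = config$rig$noise_sigma,
                    seed = config$rig$seed)

  if (backend == "synthetic") {
    say("calibrating on the synthetic rig (5 dots)")
    loop <- run_closed_loop(scenario, rig, config = tcfg,
                            cal_dwell = config$calibration$dwell,
                            cal_margin = config$calibration$margin)
    calibration <- loop$calibration
    gaze <- loop$gaze
    truth_df <- loop$truth
    report <- loop$report
  } else {
    if (is.null(landmarks)) stop("replay backend needs a landmark log path")
    frames <- landmark_stream(list(type = "replay", path = landmarks))
    n_cal <- round(5 * config$calibration$dwell * scenario$rate)
    say("calibrating from the first %d replayed frames", n_cal)
    calibration <- run_calibration(
      frames[seq_len(min(n_cal, length(frames)))], screen, rig$intrinsics,
      face_model = rig$face_model,
      dots = calibration_dots(screen, margin = config$calibration$margin),
      dwell = config$calibration$dwell)
    track_frames <- frames[-seq_len(min(n_cal, length(frames)))]
    gaze <- track_stream(track_frames, calibration, rig$intrinsics, screen,
                         config = tcfg)
    truth_df <- if (is.character(truth)) utils::read.csv(truth) else truth
    report <- if (!is.null(truth_df))
      accuracy_report(gaze, truth_df, screen) else NULL
  }
  say("tracked %d frames (%d valid)", nrow(gaze), sum(gaze$valid))

  ivt <- ivt_classify(gaze, screen, v_threshold = config$ivt$v_threshold,
                      min_fix_s = config$ivt$min_fix_s,
                      max_gap_factor = config$ivt$max_gap_factor)
  heat <- build_heatmap(gaze, screen,
                        sigma_px = config$heatmap$sigma_frac * screen$res_x,
                        downsample = config$heatmap$downsample)

  paths <- list(
    gaze = file.path(out_dir, "gaze.csv"),
    calibration = file.path(out_dir, "calibration.json"),
    events = file.path(out_dir, "events.csv"),
    heatmap_matrix = file.path(out_dir, "heatmap.txt"),
    heatmap_png = file.path(out_dir, "heatmap.png"),
    report = file.path(out_dir, "report.json"))
  write_gaze_log(gaze, paths$gaze, screen = screen, config = tcfg,
                 calibration = calibration)
  write_calibration(calibration, paths$calibration)
  write_events(ivt$events, paths$events)
  export_heatmap(heat, png_path = paths$heatmap_png,
                 matrix_path = paths$heatmap_matrix)
  if (!is.null(report)) write_report(report, paths$report)
  say("artifacts written to %s", out_dir)

  invisible(list(report = report, gaze = gaze, truth = truth_df,
                 events = ivt$events, heatmap = heat,
                 calibration = calibration, paths = paths))
}
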