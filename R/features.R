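#' Landmark index map
#'
#' The face-mesh landmark indices consumed by the tracker, using the index
#' space of the common 468-point face mesh with 10 refined iris points
#' (468-477). "left"/"right" refer to image sides for an upright face seen by
#' the camera. The pupil center is the iris-center landmark of each eye; the
#' four-point iris ring (indices 469-472 / 474-477) is only used when the
#' `ring_centroid` pupil method is selected.
#'
#' @format A named list of integer landmark ids.
#' @export
GAZE_LANDMARKS <- list(
  nose_tip = 1L,
  chin = 152L,
  left_eye_outer = 33L,
  left_eye_inner = 133L,
  right_eye_inner = 362L,
  right_eye_outer = 263L,
  mouth_left = 61L,
  mouth_right = 291L,
  left_iris_center = 468L,
  left_iris_ring = c(469L, 470L, 471L, 472L),
  right_iris_center = 473L,
  right_iris_ring = c(474L, 475L, 476L, 477L)
)

#' Construct a landmark frame
#'
#' One timestamped set of 2D facial/iris landmarks in image pixel coordinates,
#' kept sub-pixel (never rounded).
#'
#' @param timestamp Time in seconds.
#' @param points Data frame with columns `id`, `x`, `y` (image px).
#' @param image_width,image_height Image size in px.
#' @param source One of `"live"`, `"replay"`, `"synthetic"`.
#' @return An object of class `landmark_frame`.
#' @export
landmark_frame <- function(timestamp, points, image_width, image_height,
                           source = "synthetic") {
  stopifnot(is.data.frame(points), all(c("id", "x", "y") %in% names(points)))
  if (!all(is.finite(points$x)) || !all(is.finite(points$y)))
    stop("landmark coordinates must be finite")
  structure(list(timestamp = timestamp,
                 points = points[c("id", "x", "y")],
                 image_width = image_width, image_height = image_height,
                 source = source),
            class = "landmark_frame")
}

#' @export
print.landmark_frame <- function(x, ...) {
  cat(sprintf("<landmark_frame> t = %.4f s, %d points, %d x %d px (%s)\n",
              x$timestamp, nrow(x$points), x$image_width, x$image_height,
              x$source))
  invisible(x)
}

lookup_points <- function(frame, ids) {
  idx <- match(ids, frame$points$id)
  if (anyNA(idx)) {
    missing <- ids[is.na(idx)]
    stop("frame is missing landmark index ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cbind(frame$points$x[idx], frame$points$y[idx])
}

#' Extract per-frame eye features
#'
#' Pure indexing into the landmark frame: pupil centers (iris-center landmark,
#' or the centroid of the 4-point iris ring when `pupil_method =
#' "ring_centroid"`), the four eye corners, and the six points used for
#' head-pose estimation (nose tip, chin, mouth corners, outer eye corners).
#'
#' @param frame A [landmark_frame()].
#' @param pupil_method `"iris_center"` (default) or `"ring_centroid"`.
#' @return An object of class `eye_features` with fields `pupil_left`,
#'   `pupil_right`, `inner_corner_left`, `outer_corner_left`,
#'   `inner_corner_right`, `outer_corner_right` (length-2 px vectors) and
#'   `pnp_points` (6x2 matrix).
#' @export
extract_eye_features <- function(frame, pupil_method = c("iris_center", "ring_centroid")) {
  pupil_method <- match.arg(pupil_method)
  lm <- GAZE_LANDMARKS
  if (pupil_method == "iris_center") {
    pl <- lookup_points(frame, lm$left_iris_center)[1, ]
    pr <- lookup_points(frame, lm$right_iris_center)[1, ]
  } else {
    pl <- colMeans(lookup_points(frame, lm$left_iris_ring))
    pr <- colMeans(lookup_points(frame, lm$right_iris_ring))
  }
  corners <- lookup_points(frame, c(lm$left_eye_inner, lm$left_eye_outer,
                                    lm$right_eye_inner, lm$right_eye_outer))
  pnp <- lookup_points(frame, c(lm$nose_tip, lm$chin, lm$mouth_left,
                                lm$mouth_right, lm$left_eye_outer,
                                lm$right_eye_outer))
  structure(list(pupil_left = pl, pupil_right = pr,
                 inner_corner_left = corners[1, ],
                 outer_corner_left = corners[2, ],
                 inner_corner_right = corners[3, ],
                 outer_corner_right = corners[4, ],
                 pnp_points = pnp),
            class = "eye_features")
}

## ---- landmark log IO ------------------------------------------------------

fmt9 <- function(x) sprintf("%.9g", x)

#' Write a landmark stream to a CSV log with a JSON sidecar
#'
#' CSV columns: `timestamp_s, landmark_id, x_px, y_px`, written at 9
#' significant digits so that [read_landmark_log()] round-trips bit-exactly.
#' The sidecar `<path>.json` records image size, source and (optionally) the
#' rig seed.
#'
#' @param frames List of [landmark_frame()]s.
#' @param path CSV output path.
#' @param seed Optional integer recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_landmark_log <- function(frames, path, seed = NULL) {
  stopifnot(length(frames) > 0)
  rows <- lapply(frames, function(f)
    data.frame(timestamp_s = fmt9(f$timestamp),
               landmark_id = f$points$id,
               x_px = fmt9(f$points$x),
               y_px = fmt9(f$points$y)))
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(image_width = frames[[1]]$image_width,
               image_height = frames[[1]]$image_height,
               source = frames[[1]]$source,
               n_frames = length(frames))
  if (!is.null(seed)) side$seed <- seed
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a landmark log written by [write_landmark_log()]
#'
#' @param path CSV path (sidecar `<path>.json` must exist).
#' @return List of [landmark_frame()]s with strictly increasing timestamps.
#' @export
read_landmark_log <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ts <- unique(df$timestamp_s)
  if (any(diff(ts) <= 0))
    stop("landmark log timestamps are not strictly increasing at row ",
         which(diff(ts) <= 0)[1] + 1)
  sp <- split(df, factor(df$timestamp_s, levels = unique(df$timestamp_s)))
  lapply(sp, function(g)
    landmark_frame(timestamp = g$timestamp_s[1],
                   points = data.frame(id = g$landmark_id, x = g$x_px, y = g$y_px),
                   image_width = side$image_width,
                   image_height = side$image_height,
                   source = "replay"))
}

#' Open a landmark stream from a backend specification
#'
#' Pluggable frame source. The core library supports the `replay` backend
#' (a recorded CSV log) and the `synthetic` backend (the built-in rig); a live
#' landmark detector can be plugged in by passing a `frames` element directly.
#'
#' @param backend A list with element `type` (`"replay"`, `"synthetic"` or
#'   `"frames"`) plus `path` (replay), `scenario` and `rig` (synthetic), or
#'   `frames` (a pre-built list).
#' @return A list of [landmark_frame()]s with strictly increasing timestamps.
#' @export
landmark_stream <- function(backend) {
  frames <- switch(backend$type,
    replay = read_landmark_log(backend$path),
    synthetic = render_stream(backend$scenario, backend$rig)$frames,
    frames = backend$frames,
    stop("unknown landmark backend: ", backend$type))
  ts <- vapply(frames, function(f) f$timestamp, numeric(1))
  if (any(diff(ts) <= 0))
    stop("landmark stream timestamps are not strictly increasing")
  frames
}
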