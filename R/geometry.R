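#' Camera intrinsics
#'
#' Pinhole camera parameters in pixel units, with the standard 5-coefficient
#' radial/tangential distortion model (k1, k2, p1, p2, k3). These are the
#' quantities a checkerboard calibration recovers; [calibrate_camera()] returns
#' this object.
#'
#' @param focal_x,focal_y Focal lengths in pixels (> 0).
#' @param principal_x,principal_y Principal point in pixels, inside the image.
#' @param image_width,image_height Image size in pixels.
#' @param distortion Numeric length-5 vector (k1, k2, p1, p2, k3); default zero.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(focal_x, focal_y, principal_x, principal_y,
                              image_width, image_height,
                              distortion = rep(0, 5)) {
  stopifnot(focal_x > 0, focal_y > 0,
            image_width > 0, image_height > 0,
            length(distortion) == 5, all(is.finite(distortion)))
  if (principal_x < 0 || principal_x > image_width ||
      principal_y < 0 || principal_y > image_height)
    stop("principal point must lie within image bounds")
  structure(list(focal_x = focal_x, focal_y = focal_y,
                 principal_x = principal_x, principal_y = principal_y,
                 image_width = image_width, image_height = image_height,
                 distortion = as.numeric(distortion)),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("<camera_intrinsics> f = (%.2f, %.2f) px, c = (%.2f, %.2f) px, %d x %d\n",
              x$focal_x, x$focal_y, x$principal_x, x$principal_y,
              x$image_width, x$image_height))
  invisible(x)
}

#' Screen geometry
#'
#' Pixel resolution, physical size and viewing distance of the display. The
#' screen uses a top-left origin with x right and y down; all physical
#' quantities are in millimetres. The default viewing distance of 500 mm is
#' the usual desktop seating distance.
#'
#' @param res_x,res_y Resolution in pixels.
#' @param width_mm,height_mm Physical size in mm.
#' @param viewing_distance_mm User-to-screen distance d in mm (default 500).
#' @return An object of class `screen_geometry`.
#' @export
screen_geometry <- function(res_x = 1920, res_y = 1080,
                            width_mm = 480, height_mm = 270,
                            viewing_distance_mm = 500) {
  stopifnot(res_x > 0, res_y > 0, width_mm > 0, height_mm > 0,
            viewing_distance_mm > 0)
  pitch <- width_mm / res_x
  if (pitch < 0.05 || pitch > 1.0)
    stop("pixel pitch ", signif(pitch, 3), " mm/px outside sane range [0.05, 1]")
  structure(list(res_x = res_x, res_y = res_y,
                 width_mm = width_mm, height_mm = height_mm,
                 viewing_distance_mm = viewing_distance_mm),
            class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %d x %d px, %.0f x %.0f mm, d = %.0f mm\n",
              x$res_x, x$res_y, x$width_mm, x$height_mm, x$viewing_distance_mm))
  invisible(x)
}

#' Head pose angles
#'
#' Pitch/yaw/roll in degrees. Sign convention: yaw positive turns the face
#' toward the viewer's right on screen; pitch positive tilts the face upward;
#' roll rotates about the optical axis.
#'
#' @param pitch,yaw,roll Angles in degrees, each within (-90, 90) when valid.
#' @param valid Logical; `FALSE` marks a failed pose estimate.
#' @return An object of class `head_pose`.
#' @export
head_pose <- function(pitch = 0, yaw = 0, roll = 0, valid = TRUE) {
  if (valid && any(abs(c(pitch, yaw, roll)) >= 90))
    stop("valid head pose angles must lie in (-90, 90) degrees")
  structure(list(pitch = unname(pitch), yaw = unname(yaw),
                 roll = unname(roll), valid = valid),
            class = "head_pose")
}

#' @export
print.head_pose <- function(x, ...) {
  cat(sprintf("<head_pose> pitch %.2f, yaw %.2f, roll %.2f [%s]\n",
              x$pitch, x$yaw, x$roll, if (x$valid) "valid" else "invalid"))
  invisible(x)
}

## ---- rotations ------------------------------------------------------------
## Camera/world axes: x right, y down, z forward (away from the camera).
## Head rotation = Ry(-yaw) %*% Rx(-pitch) %*% Rz(roll) so that positive yaw
## swings the face normal (-z) toward +x (viewer's right) and positive pitch
## swings it toward -y (up).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}
rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}
rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

#' Rotation matrix from head-pose angles
#'
#' @param yaw,pitch,roll Angles in degrees (package sign convention).
#' @return 3x3 rotation matrix.
#' @export
pose_rotation <- function(yaw, pitch, roll = 0) {
  rot_y(-deg2rad(yaw)) %*% rot_x(-deg2rad(pitch)) %*% rot_z(deg2rad(roll))
}

#' Decompose a rotation matrix into head-pose angles
#'
#' Inverse of [pose_rotation()]; well defined for |pitch| < 90 degrees.
#'
#' @param R 3x3 rotation matrix.
#' @return A [head_pose()].
#' @export
pose_from_rotation <- function(R) {
  pitch <- asin(max(-1, min(1, R[2, 3])))
  yaw <- atan2(-R[1, 3], R[3, 3])
  roll <- atan2(R[2, 1], R[2, 2])
  head_pose(pitch = rad2deg(pitch), yaw = rad2deg(yaw), roll = rad2deg(roll))
}

## ---- projection -----------------------------------------------------------

#' Project 3D points through a pinhole camera
#'
#' Applies `p_cam = R p + t`, perspective division, the 5-coefficient
#' distortion model, and the intrinsic matrix. This is the forward model shared
#' by the synthetic rig and by the pose/intrinsics solvers.
#'
#' @param points Nx3 matrix of 3D points (mm).
#' @param rotation 3x3 rotation matrix (object-to-camera).
#' @param translation Length-3 translation (mm, camera frame).
#' @param intrinsics A [camera_intrinsics()].
#' @return Nx2 matrix of image points in pixels.
#' @export
project_points <- function(points, rotation, translation, intrinsics) {
  points <- matrix(points, ncol = 3)
  pc <- points %*% t(rotation)
  pc <- sweep(pc, 2, translation, "+")
  if (any(pc[, 3] <= 0)) stop("point behind the camera plane")
  xn <- pc[, 1] / pc[, 3]
  yn <- pc[, 2] / pc[, 3]
  d <- intrinsics$distortion
  r2 <- xn^2 + yn^2
  radial <- 1 + d[1] * r2 + d[2] * r2^2 + d[5] * r2^3
  xd <- xn * radial + 2 * d[3] * xn * yn + d[4] * (r2 + 2 * xn^2)
  yd <- yn * radial + d[3] * (r2 + 2 * yn^2) + 2 * d[4] * xn * yn
  cbind(intrinsics$focal_x * xd + intrinsics$principal_x,
        intrinsics$focal_y * yd + intrinsics$principal_y)
}

## ---- head pose estimation (PnP) -------------------------------------------

collinear2d <- function(pts, tol = 1e-8) {
  p <- sweep(pts, 2, colMeans(pts))
  s <- svd(p)$d
  s[1] > 0 && (s[2] / s[1]) < tol
}

pnp_residuals <- function(par, model_points, image_points, intrinsics) {
  R <- pose_rotation(par[1], par[2], par[3])
  proj <- tryCatch(
    project_points(model_points, R, par[4:6], intrinsics),
    error = function(e) NULL)
  if (is.null(proj)) return(rep(1e6, 2 * nrow(model_points)))
  as.numeric(proj - image_points)
}

#' Estimate head pose from six facial landmarks (perspective-n-point)
#'
#' Recovers the rigid pose of a generic 3D face model (nose tip, chin, mouth
#' corners, outer eye corners) from its 2D image projections by minimising the
#' reprojection error with Levenberg-Marquardt, and decomposes the rotation into
#' pitch/yaw/roll under the package sign convention. The reprojection RMS is
#' attached as attribute `"residual_px"` and the camera-frame translation as
#' `"translation"`.
#'
#' @param image_points 6x2 matrix of image points (px), same row order as
#'   `model_points`.
#' @param model_points 6x3 matrix of model points (mm), nose tip at the origin.
#' @param intrinsics A [camera_intrinsics()].
#' @param max_residual_px Reprojection RMS above which the pose is flagged
#'   invalid (default 5 px).
#' @return A [head_pose()]; `valid = FALSE` for degenerate configurations.
#' @export
estimate_head_pose <- function(image_points, model_points, intrinsics,
                               max_residual_px = 5) {
  image_points <- matrix(image_points, ncol = 2)
  model_points <- matrix(model_points, ncol = 3)
  if (nrow(image_points) != 6 || nrow(model_points) != 6)
    stop("exactly six 2D-3D correspondences are required")
  if (collinear2d(image_points, tol = 1e-6))
    return(head_pose(valid = FALSE))

  # depth init from the ratio of model to image spread, lateral from centroid
  dm <- mean(dist(model_points[, 1:2]))
  di <- mean(dist(image_points))
  tz0 <- intrinsics$focal_x * dm / di
  tx0 <- (mean(image_points[, 1]) - intrinsics$principal_x) * tz0 / intrinsics$focal_x
  ty0 <- (mean(image_points[, 2]) - intrinsics$principal_y) * tz0 / intrinsics$focal_y

  best <- NULL
  for (yaw0 in c(0, -15, 15)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(yaw0, 0, 0, tx0, ty0, tz0),
        fn = pnp_residuals,
        model_points = model_points, image_points = image_points,
        intrinsics = intrinsics,
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rms <- sqrt(mean(fit$fvec^2))
    if (is.null(best) || rms < best$rms) best <- list(fit = fit, rms = rms)
    if (best$rms < 1e-6) break
  }
  if (is.null(best) || !is.finite(best$rms) || best$rms > max_residual_px)
    return(head_pose(valid = FALSE))
  par <- best$fit$par
  pose <- head_pose(pitch = par[2], yaw = par[1], roll = par[3])
  attr(pose, "residual_px") <- best$rms
  attr(pose, "translation") <- par[4:6]
  pose
}

## ---- checkerboard camera calibration --------------------------------------

homography_dlt <- function(obj_xy, img_xy) {
  # normalized DLT for a plane-to-image homography
  norm_pts <- function(p) {
    mu <- colMeans(p)
    sc <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, mu)^2)))
    Tm <- matrix(c(sc, 0, 0, 0, sc, 0, -sc * mu[1], -sc * mu[2], 1), 3, 3)
    list(p = cbind(p, 1) %*% t(Tm), T = Tm)
  }
  a <- norm_pts(obj_xy); b <- norm_pts(img_xy)
  n <- nrow(obj_xy)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- a$p[i, ]; u <- b$p[i, 1]; v <- b$p[i, 2]
    A[2 * i - 1, ] <- c(-X, 0, 0, 0, u * X)
    A[2 * i, ] <- c(0, 0, 0, -X, v * X)
  }
  h <- svd(A)$v[, 9]
  H <- solve(b$T) %*% matrix(h, 3, 3, byrow = TRUE) %*% a$T
  H / H[3, 3]
}

calib_residuals <- function(par, obj_pts, img_list, n_views) {
  fx <- par[1]; fy <- par[2]; cx <- par[3]; cy <- par[4]
  dist <- c(par[5], par[6], 0, 0, 0)
  intr <- list(focal_x = fx, focal_y = fy, principal_x = cx, principal_y = cy,
               distortion = dist)
  class(intr) <- "camera_intrinsics"
  res <- vector("list", n_views)
  for (v in seq_len(n_views)) {
    p <- par[6 + (v - 1) * 6 + 1:6]
    R <- pose_rotation(p[1], p[2], p[3])
    proj <- tryCatch(project_points(obj_pts, R, p[4:6], intr),
                     error = function(e) NULL)
    if (is.null(proj)) return(rep(1e6, 2 * nrow(obj_pts) * n_views))
    res[[v]] <- as.numeric(proj - img_list[[v]])
  }
  unlist(res)
}

#' Calibrate a camera from checkerboard corner coordinates
#'
#' Closed-form intrinsics from the homography constraints of a planar target
#' (each view contributes two linear constraints on the image of the absolute
#' conic), followed by a full Levenberg-Marquardt bundle refinement of
#' intrinsics, radial distortion (k1, k2) and per-view extrinsics.
#'
#' @param corner_views Either a list of data frames with columns
#'   `corner_row`, `corner_col`, `x_px`, `y_px` (one per view), or a single
#'   data frame with an additional `view_id` column (the CSV log format).
#' @param board Numeric `c(rows, cols, square_mm)`: inner-corner grid size and
#'   square edge length.
#' @param image_width,image_height Image size in pixels.
#' @return A [camera_intrinsics()] with attribute `"rms_px"` (reprojection RMS).
#' @export
calibrate_camera <- function(corner_views, board, image_width, image_height) {
  if (is.data.frame(corner_views))
    corner_views <- split(corner_views[c("corner_row", "corner_col", "x_px", "y_px")],
                          corner_views$view_id)
  n_views <- length(corner_views)
  if (n_views < 3)
    stop("camera calibration needs at least 3 checkerboard views")
  rows <- board[1]; cols <- board[2]; sq <- board[3]
  n_corners <- rows * cols

  obj_xy <- NULL
  img_list <- vector("list", n_views)
  for (v in seq_len(n_views)) {
    cv <- corner_views[[v]]
    if (nrow(cv) != n_corners)
      stop("view ", v, " has ", nrow(cv), " corners, expected ", n_corners)
    cv <- cv[order(cv$corner_row, cv$corner_col), ]
    if (is.null(obj_xy))
      obj_xy <- cbind(cv$corner_col * sq, cv$corner_row * sq)
    img_list[[v]] <- cbind(cv$x_px, cv$y_px)
  }

  Hs <- lapply(img_list, function(im) homography_dlt(obj_xy, im))

  # Zhang's constraints: for each H, v12 . b = 0 and (v11 - v22) . b = 0
  vij <- function(H, i, j) {
    c(H[1, i] * H[1, j],
      H[1, i] * H[2, j] + H[2, i] * H[1, j],
      H[2, i] * H[2, j],
      H[3, i] * H[1, j] + H[1, i] * H[3, j],
      H[3, i] * H[2, j] + H[2, i] * H[3, j],
      H[3, i] * H[3, j])
  }
  V <- do.call(rbind, lapply(Hs, function(H)
    rbind(vij(H, 1, 2), vij(H, 1, 1) - vij(H, 2, 2))))
  sv <- svd(V)
  if (sv$d[5] / sv$d[1] < 1e-10)
    stop("ill-conditioned calibration: views are degenerate or duplicated")
  b <- sv$v[, 6]
  B11 <- b[1]; B12 <- b[2]; B22 <- b[3]; B13 <- b[4]; B23 <- b[5]; B33 <- b[6]
  v0 <- (B12 * B13 - B11 * B23) / (B11 * B22 - B12^2)
  lam <- B33 - (B13^2 + v0 * (B12 * B13 - B11 * B23)) / B11
  fx2 <- lam / B11
  fy2 <- lam * B11 / (B11 * B22 - B12^2)
  if (!is.finite(fx2) || !is.finite(fy2) || fx2 <= 0 || fy2 <= 0)
    stop("ill-conditioned calibration: closed-form intrinsics are degenerate")
  fx <- sqrt(fx2); fy <- sqrt(fy2)
  skew <- -B12 * fx^2 * fy / lam
  u0 <- skew * v0 / fy - B13 * fx^2 / lam

  # per-view extrinsics from H = K [r1 r2 t]
  K <- matrix(c(fx, 0, 0, 0, fy, 0, u0, v0, 1), 3, 3)
  Kinv <- solve(K)
  par0 <- c(fx, fy, u0, v0, 0, 0)
  for (H in Hs) {
    h1 <- Kinv %*% H[, 1]; h2 <- Kinv %*% H[, 2]; h3 <- Kinv %*% H[, 3]
    s <- 1 / sqrt(sum(h1^2))
    if (h3[3] * s < 0) s <- -s
    r1 <- s * h1; r2 <- s * h2; r3 <- pracma_cross(r1, r2)
    R <- cbind(r1, r2, r3)
    # nearest rotation matrix
    sv2 <- svd(R)
    R <- sv2$u %*% t(sv2$v)
    if (det(R) < 0) R <- sv2$u %*% diag(c(1, 1, -1)) %*% t(sv2$v)
    ang <- pose_from_rotation(R)
    par0 <- c(par0, ang$yaw, ang$pitch, ang$roll, s * h3)
  }

  fit <- minpack.lm::nls.lm(
    par = par0, fn = calib_residuals,
    obj_pts = cbind(obj_xy, 0), img_list = img_list, n_views = n_views,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  rms <- sqrt(mean(fit$fvec^2))
  p <- fit$par
  out <- camera_intrinsics(focal_x = p[1], focal_y = p[2],
                           principal_x = p[3], principal_y = p[4],
                           image_width = image_width,
                           image_height = image_height,
                           distortion = c(p[5], p[6], 0, 0, 0))
  attr(out, "rms_px") <- rms
  out
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Read checkerboard corner logs
#'
#' CSV with header `view_id, corner_row, corner_col, x_px, y_px`.
#'
#' @param path File path.
#' @return A data frame suitable for [calibrate_camera()].
#' @export
read_corners_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("view_id", "corner_row", "corner_col", "x_px", "y_px")
  if (!all(need %in% names(df)))
    stop("corner CSV must have columns: ", paste(need, collapse = ", "))
  df
}

## ---- unit conversions and the accuracy metric -----------------------------

#' Convert screen pixels to millimetres (and back)
#'
#' Linear scaling by the per-axis pixel pitch; `mm_to_px()` is the exact
#' inverse.
#'
#' @param point Length-2 vector or Nx2 matrix.
#' @param screen A [screen_geometry()].
#' @return Converted coordinates, same shape as the input.
#' @export
px_to_mm <- function(point, screen) {
  p <- rbind(point)
  out <- cbind(p[, 1] * screen$width_mm / screen$res_x,
               p[, 2] * screen$height_mm / screen$res_y)
  if (is.null(dim(point))) out[1, ] else out
}

#' @rdname px_to_mm
#' @export
mm_to_px <- function(point, screen) {
  p <- rbind(point)
  out <- cbind(p[, 1] * screen$res_x / screen$width_mm,
               p[, 2] * screen$res_y / screen$height_mm)
  if (is.null(dim(point))) out[1, ] else out
}

#' Visual-angle error between predicted and true gaze points
#'
#' The angle subtended at the eye by the separation of the two screen points:
#' `atan(separation_mm / viewing_distance_mm)`, in degrees. The standard
#' accuracy metric for gaze estimation; symmetric in its arguments and monotone
#' in the separation.
#'
#' @param pred,truth Length-2 vectors or Nx2 matrices of screen pixels.
#' @param screen A [screen_geometry()].
#' @param axis `"euclidean"` (default), `"x"` or `"y"` for per-axis variants.
#' @return Error(s) in degrees.
#' @export
visual_angle_error <- function(pred, truth, screen, axis = c("euclidean", "x", "y")) {
  axis <- match.arg(axis)
  pm <- rbind(px_to_mm(pred, screen))
  tm <- rbind(px_to_mm(truth, screen))
  if (nrow(pm) != nrow(tm)) {
    n <- max(nrow(pm), nrow(tm))
    if (nrow(pm) == 1) pm <- pm[rep(1, n), , drop = FALSE]
    else if (nrow(tm) == 1) tm <- tm[rep(1, n), , drop = FALSE]
    else stop("pred and truth must have the same number of points")
  }
  sep <- switch(axis,
                euclidean = sqrt(rowSums((pm - tm)^2)),
                x = abs(pm[, 1] - tm[, 1]),
                y = abs(pm[, 2] - tm[, 2]))
  rad2deg(atan(sep / screen$viewing_distance_mm))
}
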