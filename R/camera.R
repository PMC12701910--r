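#' Pinhole camera intrinsics with Brown-Conrady distortion
#'
#' Focal lengths and principal point are in pixels; the distortion vector
#' follows the common `(k1, k2, p1, p2, k3)` ordering (three radial, two
#' tangential coefficients, dimensionless). Pixel coordinates put integer
#' coordinates at pixel centers, origin at the top-left pixel, `u` along
#' columns and `v` along rows.
#'
#' @param fx,fy Focal lengths in pixels (positive).
#' @param cx,cy Principal point in pixels.
#' @param dist Length-5 distortion vector `(k1, k2, p1, p2, k3)`.
#' @param image_size Optional `c(width, height)` in pixels; when given, the
#'   principal point must lie within the image bounds plus a 25% margin.
#' @return An object of class `camera_params`.
#' @export
camera_params <- function(fx, fy, cx, cy, dist = c(0, 0, 0, 0, 0), image_size = NULL) {
  if (!is.finite(fx) || fx <= 0 || !is.finite(fy) || fy <= 0)
    stopf("focal lengths must be positive (fx=%s, fy=%s)", format(fx), format(fy))
  dist <- as.numeric(dist)
  if (length(dist) != 5L || !all(is.finite(dist)))
    stopf("'dist' must be 5 finite coefficients (k1, k2, p1, p2, k3)")
  if (!is.null(image_size)) {
    w <- image_size[1]; h <- image_size[2]
    m <- 0.25
    if (cx < -m * w || cx > (1 + m) * w || cy < -m * h || cy > (1 + m) * h)
      stopf("principal point (%.1f, %.1f) outside image bounds %d x %d (25%% tolerance)",
            cx, cy, as.integer(w), as.integer(h))
  }
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy, dist = dist,
                 image_size = if (is.null(image_size)) NULL else as.integer(image_size)),
            class = "camera_params")
}

#' Stereo rig: two cameras with relative extrinsics
#'
#' The right camera center sits at `(baseline_mm, 0, 0)` in the left camera
#' frame; `rotation` is the orientation of the right camera relative to the
#' left. A rectified rig has identity relative rotation, no distortion, and
#' shares `fx`, `fy`, `cy` between the eyes, so epipolar lines are
#' row-aligned and disparity is purely horizontal.
#'
#' @param left,right `camera_params` for each eye.
#' @param rotation 3x3 orthonormal matrix (right relative to left).
#' @param baseline_mm Positive inter-optical-center distance in mm.
#' @param rectified Logical flag.
#' @param image_size Optional `c(width, height)`.
#' @return An object of class `stereo_rig`.
#' @export
stereo_rig <- function(left, right, rotation = diag(3), baseline_mm,
                       rectified = FALSE, image_size = NULL) {
  stopifnot(inherits(left, "camera_params"), inherits(right, "camera_params"))
  if (!is_rotation_matrix(rotation))
    stopf("'rotation' must be orthonormal with det +1 (tolerance 1e-9)")
  if (!is.finite(baseline_mm) || baseline_mm <= 0)
    stopf("'baseline_mm' must be positive (got %s): a zero baseline carries no depth information",
          format(baseline_mm))
  if (isTRUE(rectified)) {
    if (max(abs(rotation - diag(3))) > 1e-9)
      stopf("a rectified rig must have identity relative rotation")
    if (abs(left$fx - right$fx) > 1e-9 || abs(left$fy - right$fy) > 1e-9 ||
        abs(left$cy - right$cy) > 1e-9)
      stopf("a rectified rig must share fx, fy and cy between eyes")
  }
  structure(list(left = left, right = right, rotation = rotation,
                 baseline_mm = baseline_mm, rectified = isTRUE(rectified),
                 image_size = if (is.null(image_size)) NULL else as.integer(image_size)),
            class = "stereo_rig")
}

# Brown-Conrady forward distortion on normalized coordinates.
distort_normalized <- function(xn, yn, dist) {
  k1 <- dist[1]; k2 <- dist[2]; p1 <- dist[3]; p2 <- dist[4]; k3 <- dist[5]
  r2 <- xn^2 + yn^2
  radial <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
  xd <- xn * radial + 2 * p1 * xn * yn + p2 * (r2 + 2 * xn^2)
  yd <- yn * radial + p1 * (r2 + 2 * yn^2) + 2 * p2 * xn * yn
  unname(cbind(xd, yd))
}

# Invert the distortion polynomial by fixed-point iteration
# (20 iterations or step < 1e-10, whichever first).
undistort_normalized <- function(xd, yd, dist, max_iter = 20L, tol = 1e-10) {
  k1 <- dist[1]; k2 <- dist[2]; p1 <- dist[3]; p2 <- dist[4]; k3 <- dist[5]
  xn <- xd; yn <- yd
  for (i in seq_len(max_iter)) {
    r2 <- xn^2 + yn^2
    radial <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
    dx <- 2 * p1 * xn * yn + p2 * (r2 + 2 * xn^2)
    dy <- p1 * (r2 + 2 * yn^2) + 2 * p2 * xn * yn
    xn_new <- (xd - dx) / radial
    yn_new <- (yd - dy) / radial
    step <- max(abs(xn_new - xn), abs(yn_new - yn))
    xn <- xn_new; yn <- yn_new
    if (step < tol) break
  }
  unname(cbind(xn, yn))
}

#' Project 3D camera-frame points to pixel coordinates
#'
#' Standard perspective projection `u = fx * (x/z)' + cx`,
#' `v = fy * (y/z)' + cy`, where the prime applies the Brown-Conrady
#' distortion polynomial when `apply_distortion` is `TRUE`.
#'
#' @param points N x 3 matrix of points in the camera frame, mm; all `z > 0`.
#' @param cam A `camera_params`.
#' @param apply_distortion Apply the distortion model (default `TRUE`).
#' @return N x 2 matrix of pixel coordinates `(u, v)`.
#' @export
project_points <- function(points, cam, apply_distortion = TRUE) {
  stopifnot(inherits(cam, "camera_params"))
  pts <- as_points_matrix(points)
  if (any(pts[, 3] <= 0))
    stopf("%d point(s) at or behind the camera (z <= 0) cannot be projected",
          sum(pts[, 3] <= 0))
  xn <- pts[, 1] / pts[, 3]
  yn <- pts[, 2] / pts[, 3]
  if (apply_distortion && any(cam$dist != 0)) {
    nd <- distort_normalized(xn, yn, cam$dist)
    xn <- nd[, 1]; yn <- nd[, 2]
  }
  cbind(u = cam$fx * xn + cam$cx, v = cam$fy * yn + cam$cy)
}

#' Back-project pixels to viewing rays or 3D points
#'
#' `pixel_to_ray` undoes the intrinsics (and, by fixed-point iteration, the
#' distortion) to return normalized ray directions `(x', y', 1)`;
#' `backproject_pixels` scales each ray by a depth to recover camera-frame
#' points.
#'
#' @param pixels N x 2 matrix of `(u, v)` pixel coordinates.
#' @param cam A `camera_params`.
#' @param undistort Apply iterative undistortion (default `TRUE`).
#' @param depth Vector of N depths (z-coordinates, mm).
#' @return `pixel_to_ray`: N x 3 matrix; `backproject_pixels`: N x 3 matrix
#'   of camera-frame points in mm.
#' @export
pixel_to_ray <- function(pixels, cam, undistort = TRUE) {
  stopifnot(inherits(cam, "camera_params"))
  px <- as.matrix(pixels)
  xd <- (px[, 1] - cam$cx) / cam$fx
  yd <- (px[, 2] - cam$cy) / cam$fy
  if (undistort && any(cam$dist != 0)) {
    nd <- undistort_normalized(xd, yd, cam$dist)
    xd <- nd[, 1]; yd <- nd[, 2]
  }
  unname(cbind(xd, yd, rep(1, length(xd))))
}

#' @rdname pixel_to_ray
#' @export
backproject_pixels <- function(pixels, depth, cam, undistort = TRUE) {
  rays <- pixel_to_ray(pixels, cam, undistort = undistort)
  rays * depth
}

#' Mean reprojection error in pixels
#'
#' Mean Euclidean pixel distance between observed image points and the
#' projections of their posed 3D counterparts; the standard calibration /
#' registration quality metric. Points from both eyes may be pooled.
#'
#' @param observed N x 2 matrix of observed pixel coordinates.
#' @param points3d N x 3 matrix of corresponding 3D points (world frame, mm).
#' @param cam A `camera_params`.
#' @param rotation,translation Pose mapping world to camera frame:
#'   `p_cam = R p + t`.
#' @param apply_distortion Use the distortion model when projecting.
#' @return Mean reprojection error in pixels (scalar).
#' @export
reprojection_error <- function(observed, points3d, cam,
                               rotation = diag(3), translation = c(0, 0, 0),
                               apply_distortion = TRUE) {
  obs <- as.matrix(observed)
  pts <- as_points_matrix(points3d, "points3d")
  if (nrow(obs) == 0L || nrow(pts) == 0L)
    stopf("reprojection_error needs at least one observation/point pair")
  if (nrow(obs) != nrow(pts))
    stopf("observed (%d) and 3D points (%d) must correspond one-to-one",
          nrow(obs), nrow(pts))
  cam_pts <- sweep(pts %*% t(rotation), 2, as.numeric(translation), "+")
  proj <- project_points(cam_pts, cam, apply_distortion = apply_distortion)
  mean(sqrt(rowSums((proj - obs)^2)))
}

#' Read and write stereo calibration files
#'
#' YAML (or JSON) schema: `image_size: [w, h]`, `left`/`right`:
#' `{fx, fy, cx, cy, dist: [k1, k2, p1, p2, k3]}`, `rotation` (row-major
#' length-9), `baseline_mm`, `rectified`. The reader validates every field
#' and returns a `stereo_rig`.
#'
#' @param rig A `stereo_rig`.
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return `read_calibration` returns a `stereo_rig`; `write_calibration`
#'   returns `path` invisibly.
#' @export
write_calibration <- function(rig, path) {
  stopifnot(inherits(rig, "stereo_rig"))
  eye <- function(cam) list(fx = cam$fx, fy = cam$fy, cx = cam$cx, cy = cam$cy,
                            dist = cam$dist)
  obj <- list(image_size = as.integer(rig$image_size %||% c(NA, NA)),
              left = eye(rig$left), right = eye(rig$right),
              rotation = as.numeric(t(rig$rotation)),
              baseline_mm = rig$baseline_mm,
              rectified = rig$rectified)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  else
    yaml::write_yaml(obj, path, precision = 12)   # full rotation precision
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stopf("calibration file not found: %s", path)
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  for (key in c("left", "right", "rotation", "baseline_mm", "rectified"))
    if (is.null(obj[[key]])) stopf("calibration file missing required key '%s'", key)
  image_size <- obj$image_size
  if (!is.null(image_size) && any(is.na(image_size))) image_size <- NULL
  eye <- function(e, which) {
    for (key in c("fx", "fy", "cx", "cy", "dist"))
      if (is.null(e[[key]])) stopf("calibration '%s' camera missing key '%s'", which, key)
    camera_params(e$fx, e$fy, e$cx, e$cy, as.numeric(e$dist), image_size = image_size)
  }
  rot <- as.numeric(unlist(obj$rotation))
  if (length(rot) != 9L) stopf("calibration 'rotation' must have 9 entries (row-major 3x3)")
  stereo_rig(left = eye(obj$left, "left"), right = eye(obj$right, "right"),
             rotation = matrix(rot, 3, 3, byrow = TRUE),
             baseline_mm = obj$baseline_mm,
             rectified = isTRUE(obj$rectified),
             image_size = image_size)
}
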