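# Bilinear interpolation of an H x W image at fractional pixel coords
# (u along columns, v along rows, pixel centers at integers, 0-based).
# Out-of-bounds samples return `fill`.
bilinear_sample <- function(img, u, v, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  u0 <- floor(u); v0 <- floor(v)
  du <- u - u0; dv <- v - v0
  inb <- u0 >= 0 & v0 >= 0 & u0 <= W - 1 & v0 <= H - 1
  # clamp the +1 neighbor so border pixels interpolate against themselves
  u1 <- pmin(u0 + 1, W - 1); v1 <- pmin(v0 + 1, H - 1)
  out <- rep(fill, length(u))
  if (any(inb)) {
    iu0 <- u0[inb] + 1; iu1 <- u1[inb] + 1
    iv0 <- v0[inb] + 1; iv1 <- v1[inb] + 1
    w00 <- (1 - du[inb]) * (1 - dv[inb]); w10 <- du[inb] * (1 - dv[inb])
    w01 <- (1 - du[inb]) * dv[inb];       w11 <- du[inb] * dv[inb]
    out[inb] <- w00 * img[cbind(iv0, iu0)] + w10 * img[cbind(iv0, iu1)] +
                w01 * img[cbind(iv1, iu0)] + w11 * img[cbind(iv1, iu1)]
  }
  out
}

# Warp one eye: for every output pixel of the rectified (ideal, row-aligned)
# camera, rotate its viewing ray into the source camera frame, project with
# the source intrinsics + distortion, and bilinearly sample the source image.
# `R_src_from_rect` carries rectified-frame directions into the source frame.
rectify_warp <- function(img, src_cam, rect_cam, R_src_from_rect) {
  H <- nrow(img); W <- ncol(img)
  uu <- rep(0:(W - 1), each = H)
  vv <- rep(0:(H - 1), times = W)
  rays <- cbind((uu - rect_cam$cx) / rect_cam$fx,
                (vv - rect_cam$cy) / rect_cam$fy,
                1)
  src <- rays %*% t(R_src_from_rect)
  xn <- src[, 1] / src[, 3]
  yn <- src[, 2] / src[, 3]
  if (any(src_cam$dist != 0)) {
    nd <- distort_normalized(xn, yn, src_cam$dist)
    xn <- nd[, 1]; yn <- nd[, 2]
  }
  us <- src_cam$fx * xn + src_cam$cx
  vs <- src_cam$fy * yn + src_cam$cy
  matrix(bilinear_sample(img, us, vs), H, W)
}

#' Undistort and rectify a stereo image pair
#'
#' Resamples both eyes so that the pair satisfies ideal rectified geometry:
#' zero distortion, identity relative rotation, shared intrinsics, and
#' row-aligned epipolar lines (corresponding points share the image row and
#' the correspondence search becomes one-dimensional). The rig's baseline is
#' assumed along the left camera x-axis, which is how [stereo_rig] defines
#' the extrinsics; the left rectified frame therefore coincides with the
#' left camera frame and only the right eye is rotationally compensated.
#' Resampling uses bilinear interpolation.
#'
#' @param left,right Grayscale image matrices (H x W, values in `[0, 1]`) of
#'   equal size.
#' @param rig An unrectified `stereo_rig`.
#' @return A list with `left`, `right` (rectified images) and `rig` (the
#'   rectified `stereo_rig` recording the new shared intrinsics).
#' @export
rectify_pair <- function(left, right, rig) {
  stopifnot(inherits(rig, "stereo_rig"))
  if (rig$rectified)
    stopf("rig is already rectified; rectify_pair expects a raw rig")
  if (!all(dim(left) == dim(right)))
    stopf("left (%s) and right (%s) images must have identical size",
          paste(dim(left), collapse = "x"), paste(dim(right), collapse = "x"))
  lc <- rig$left; rc <- rig$right
  rect_cam <- camera_params(
    fx = (lc$fx + rc$fx) / 2, fy = (lc$fy + rc$fy) / 2,
    cx = (lc$cx + rc$cx) / 2, cy = (lc$cy + rc$cy) / 2,
    dist = c(0, 0, 0, 0, 0),
    image_size = c(ncol(left), nrow(left)))
  # rectified frame = left camera frame; right-camera directions relate by
  # v_left = R v_right, so directions map into the right frame via t(R)
  left_rect <- rectify_warp(left, lc, rect_cam, diag(3))
  right_rect <- rectify_warp(right, rc, rect_cam, t(rig$rotation))
  new_rig <- stereo_rig(left = rect_cam, right = rect_cam, rotation = diag(3),
                        baseline_mm = rig$baseline_mm, rectified = TRUE,
                        image_size = c(ncol(left), nrow(left)))
  list(left = left_rect, right = right_rect, rig = new_rig)
}
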