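#' Metric point cloud container
#'
#' @param points N x 3 matrix, mm, in the left rectified camera frame.
#' @param colors Optional N x 3 matrix in `[0, 1]`.
#' @param source_pixels Optional N x 2 matrix of originating `(u, v)` pixels.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, colors = NULL, source_pixels = NULL) {
  points <- as_points_matrix(points)
  if (!all(is.finite(points))) stopf("point cloud coordinates must be finite")
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    stopifnot(nrow(colors) == nrow(points), ncol(colors) == 3L)
  }
  if (!is.null(source_pixels)) {
    source_pixels <- as.matrix(source_pixels)
    stopifnot(nrow(source_pixels) == nrow(points), ncol(source_pixels) == 2L)
  }
  structure(list(points = points, colors = colors, source_pixels = source_pixels),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points%s\n", nrow(x$points),
              if (is.null(x$colors)) "" else " (with colors)"))
  invisible(x)
}

as_cloud_matrix <- function(x, arg = "cloud") {
  if (inherits(x, "point_cloud")) x$points else as_points_matrix(x, arg)
}

# Sum of m over a (2r+1)^2 window centered at each pixel; NA where the
# window does not fit inside the image. Integral-image implementation.
box_sum <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  ii <- apply(m, 2, cumsum)
  ii <- t(apply(ii, 1, cumsum))
  ii <- rbind(0, cbind(0, ii))                  # (H+1) x (W+1), 1-based offsets
  out <- matrix(NA_real_, H, W)
  vr <- (r + 1):(H - r); ur <- (r + 1):(W - r)
  if (length(vr) < 1 || length(ur) < 1) return(out)
  out[vr, ur] <- ii[vr + r + 1, ur + r + 1, drop = FALSE] -
    ii[vr - r, ur + r + 1, drop = FALSE] -
    ii[vr + r + 1, ur - r, drop = FALSE] +
    ii[vr - r, ur - r, drop = FALSE]
  out
}

to_luminance <- function(img) {
  if (length(dim(img)) == 3L)
    0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  else img
}

#' Block-matching disparity map with sub-pixel refinement
#'
#' Winner-take-all block matching between a rectified pair using the
#' zero-mean normalized cross-correlation (ZNCC) cost, computed with
#' integral-image window sums. Disparity is left-referenced and positive
#' toward nearer objects (`u_right = u_left - d`). The winning integer
#' disparity is refined by fitting a 3-point parabola to the cost curve.
#' Pixels are invalidated by (a) a low-texture check on the local left-image
#' variance, (b) a left-right consistency check that recomputes the
#' right-referenced disparity from the same cost volume and rejects pixels
#' whose two disparities differ by more than `consistency_threshold`, and
#' (c) the window/search border.
#'
#' @param left,right Rectified grayscale images (H x W in `[0, 1]`), or
#'   H x W x 3 arrays (converted to luminance).
#' @param params List: `block_size` (odd, >= 3), `search_range` (number of
#'   candidate disparities, starting at 0), `consistency_threshold` (px),
#'   `texture_threshold` (minimum local intensity variance).
#' @param rig Optional `stereo_rig`; if supplied it must be rectified.
#' @return An object of class `disparity_map`: `values` (H x W, NA where
#'   invalid), `valid` (logical H x W), `block_size`, `search_range`,
#'   `params`.
#' @export
compute_disparity <- function(left, right,
                              params = list(), rig = NULL) {
  p <- utils::modifyList(list(block_size = 9L, search_range = 64L,
                              consistency_threshold = 1,
                              texture_threshold = 1e-4), params)
  if (!is.null(rig)) {
    stopifnot(inherits(rig, "stereo_rig"))
    if (!rig$rectified)
      stopf("compute_disparity requires a rectified rig; call rectify_pair first")
  }
  bs <- as.integer(p$block_size)
  if (bs < 3L || bs %% 2L == 0L)
    stopf("block_size must be odd and >= 3 (got %d)", bs)
  L <- to_luminance(left); R <- to_luminance(right)
  if (!all(dim(L) == dim(R))) stopf("left/right images must have identical size")
  H <- nrow(L); W <- ncol(L)
  D <- as.integer(p$search_range)
  if (D < 1L || D >= W) stopf("search_range must be in [1, image width)")
  r <- (bs - 1L) %/% 2L
  n <- bs * bs

  SL <- box_sum(L, r); SL2 <- box_sum(L * L, r)
  SR <- box_sum(R, r); SR2 <- box_sum(R * R, r)
  varL_num <- pmax(n * SL2 - SL^2, 0)   # n^2 * (biased variance)
  varR_num <- pmax(n * SR2 - SR^2, 0)

  cost <- array(-Inf, dim = c(H, W, D))
  eps <- 1e-12
  for (d in 0:(D - 1L)) {
    colsL <- (d + 1L):W
    colsR <- 1L:(W - d)
    SP <- box_sum(L[, colsL, drop = FALSE] * R[, colsR, drop = FALSE], r)
    num <- n * SP - SL[, colsL, drop = FALSE] * SR[, colsR, drop = FALSE]
    den <- sqrt(varL_num[, colsL, drop = FALSE] * varR_num[, colsR, drop = FALSE])
    zncc <- num / pmax(den, eps)
    zncc[!is.finite(zncc) | den < eps] <- -Inf
    cost[, colsL, d + 1L] <- zncc
  }

  cm <- matrix(cost, H * W, D)
  bi <- max.col(cm, ties.method = "first")
  bv <- cm[cbind(seq_len(H * W), bi)]
  valid <- is.finite(bv)
  # a winner abutting an unevaluable candidate (right window off-image) may
  # only be the best *available* disparity, not the true one: invalidate
  chk <- which(valid & bi < D)
  if (length(chk))
    valid[chk[!is.finite(cm[cbind(chk, bi[chk] + 1L)])]] <- FALSE

  # parabolic sub-pixel refinement on the three costs around the winner
  disp <- as.numeric(bi - 1L)
  interior <- valid & bi > 1L & bi < D
  if (any(interior)) {
    ii <- which(interior)
    c0 <- cm[cbind(ii, bi[ii] - 1L)]
    c1 <- bv[ii]
    c2 <- cm[cbind(ii, bi[ii] + 1L)]
    denom <- c0 - 2 * c1 + c2
    # a perfect correlation (ZNCC = 1) is already an exact integer match;
    # the parabola would only wander off it
    ok <- is.finite(c0) & is.finite(c2) & denom < -1e-12 & c1 < 1 - 1e-9
    delta <- rep(0, length(ii))
    delta[ok] <- pmin(pmax(0.5 * (c0[ok] - c2[ok]) / denom[ok], -0.5), 0.5)
    disp[ii] <- disp[ii] + delta
  }

  # texture gate on the left-image local variance
  texture_ok <- (varL_num / (n * (n - 1))) >= p$texture_threshold
  valid <- valid & as.vector(texture_ok) & !is.na(as.vector(texture_ok))

  # left-right consistency from the same cost volume:
  # cost_R(v, u_R, d) = cost_L(v, u_R + d, d)
  bestRv <- matrix(-Inf, H, W)
  bestRi <- matrix(0L, H, W)
  for (d in 0:(D - 1L)) {
    sl <- cost[, (d + 1L):W, d + 1L, drop = FALSE]
    dim(sl) <- c(H, W - d)
    cols <- 1L:(W - d)
    upd <- sl > bestRv[, cols, drop = FALSE]
    if (any(upd)) {
      sub <- bestRv[, cols, drop = FALSE]; sub[upd] <- sl[upd]
      bestRv[, cols] <- sub
      subi <- bestRi[, cols, drop = FALSE]; subi[upd] <- d
      bestRi[, cols] <- subi
    }
  }
  vmat <- matrix(valid, H, W)
  dmat <- matrix(disp, H, W)
  idx <- which(vmat, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    uR <- idx[, 2] - round(dmat[idx])            # 1-based right column
    inb <- uR >= 1 & uR <= W
    dR <- rep(NA_real_, nrow(idx))
    dR[inb] <- bestRi[cbind(idx[inb, 1], uR[inb])]
    consistent <- inb & is.finite(dR) &
      abs(dR - round(dmat[idx])) <= p$consistency_threshold
    vmat[idx[!consistent, , drop = FALSE]] <- FALSE
  }

  dmat[!vmat] <- NA_real_
  structure(list(values = dmat, valid = vmat, block_size = bs,
                 search_range = D, params = p),
            class = "disparity_map")
}

#' @export
print.disparity_map <- function(x, ...) {
  cat(sprintf("<disparity_map> %d x %d, %.1f%% valid, block %d, range %d\n",
              ncol(x$values), nrow(x$values), 100 * mean(x$valid),
              x$block_size, x$search_range))
  invisible(x)
}

#' Triangulate a disparity map into a metric point cloud
#'
#' For each valid pixel with disparity above `min_disparity`:
#' `z = fx * baseline / d`, `x = (u - cx) * z / fx`, `y = (v - cy) * z / fy`,
#' in the left rectified camera frame (mm). Points outside `[z_min, z_max]`
#' are dropped; non-positive disparities among valid pixels are filtered
#' out and counted, never an error.
#'
#' @param disp A `disparity_map`.
#' @param rig A rectified `stereo_rig`.
#' @param filters List: `z_min`, `z_max` (mm), `min_disparity` (px).
#'   Defaults `z` in `[20, 300]` mm, the plausible endoscopic working range.
#' @param left_image Optional left image used to color the cloud.
#' @return A `point_cloud` with `source_pixels` recording `(u, v)`.
#' @export
disparity_to_cloud <- function(disp, rig,
                               filters = list(),
                               left_image = NULL) {
  stopifnot(inherits(disp, "disparity_map"), inherits(rig, "stereo_rig"))
  if (!rig$rectified) stopf("disparity_to_cloud requires a rectified rig")
  f <- utils::modifyList(list(z_min = 20, z_max = 300, min_disparity = 0.5),
                         filters)
  cam <- rig$left
  H <- nrow(disp$values); W <- ncol(disp$values)
  idx <- which(disp$valid)
  d <- disp$values[idx]
  nonpos <- d <= 0
  if (any(nonpos))
    message(sprintf("disparity_to_cloud: dropped %d valid pixel(s) with non-positive disparity",
                    sum(nonpos)))
  keep <- !nonpos & d > f$min_disparity
  idx <- idx[keep]; d <- d[keep]
  u <- (idx - 1L) %/% H         # 0-based column
  v <- (idx - 1L) %% H          # 0-based row
  z <- cam$fx * rig$baseline_mm / d
  zin <- z >= f$z_min & z <= f$z_max
  idx <- idx[zin]; u <- u[zin]; v <- v[zin]; z <- z[zin]
  pts <- cbind((u - cam$cx) * z / cam$fx, (v - cam$cy) * z / cam$fy, z)
  colors <- NULL
  if (!is.null(left_image)) {
    lum <- to_luminance(left_image)
    g <- lum[cbind(v + 1L, u + 1L)]
    colors <- cbind(g, g, g)
  }
  point_cloud(pts, colors = colors, source_pixels = cbind(u, v))
}

# index of (and distance to) the single nearest neighbor in `ref` for every
# row of `query` (kd-tree spatial index)
nn1 <- function(query, ref) {
  query <- as_cloud_matrix(query, "query")
  ref <- as_cloud_matrix(ref, "ref")
  nn <- RANN::nn2(ref, query, k = 1L)
  list(index = as.integer(nn$nn.idx[, 1]), dist = nn$nn.dists[, 1])
}

# mean distance to the k nearest neighbors (excluding self) for each point
knn_mean_dist <- function(points, k) {
  nn <- RANN::nn2(points, points, k = k + 1L)
  rowMeans(nn$nn.dists[, -1, drop = FALSE])
}

#' Statistical outlier removal for point clouds
#'
#' Drops points whose mean distance to their `k` nearest neighbors exceeds
#' the global mean plus `sd_multiplier` standard deviations of that
#' statistic. Deterministic; standard cloud hygiene before ICP.
#'
#' @param cloud A `point_cloud` (or N x 3 matrix).
#' @param k Neighbor count.
#' @param sd_multiplier Threshold multiplier.
#' @return A `point_cloud` with outliers removed.
#' @export
clean_cloud <- function(cloud, k = 8L, sd_multiplier = 2) {
  pts <- as_cloud_matrix(cloud)
  n <- nrow(pts)
  if (n <= k) {
    warnf("clean_cloud: %d point(s) <= k = %d neighbors; returning input unchanged",
          n, k)
    return(if (inherits(cloud, "point_cloud")) cloud else point_cloud(pts))
  }
  md <- knn_mean_dist(pts, k)
  thr <- mean(md) + sd_multiplier * stats::sd(md)
  keep <- md <= thr
  if (!any(keep))
    stopf("clean_cloud would remove every point (sd_multiplier = %s); refusing",
          format(sd_multiplier))
  if (inherits(cloud, "point_cloud")) {
    point_cloud(cloud$points[keep, , drop = FALSE],
                colors = if (is.null(cloud$colors)) NULL else cloud$colors[keep, , drop = FALSE],
                source_pixels = if (is.null(cloud$source_pixels)) NULL else cloud$source_pixels[keep, , drop = FALSE])
  } else point_cloud(pts[keep, , drop = FALSE])
}

#' Pick landmarks on the stereo reconstruction
#'
#' Emulates picking annulus key points on the reconstructed scene: each
#' reference landmark is projected into the left rectified image, the
#' disparity is read as the median over valid pixels within a small
#' neighborhood of the projection, and the pick is triangulated back to 3D.
#' The returned positions therefore carry the reconstruction's error, like
#' real intraoperative picks.
#'
#' @param reference `landmark_set` (or K x 3 matrix) in the left camera
#'   frame giving where the picks are aimed.
#' @param disp A `disparity_map` of the rectified pair.
#' @param rig The rectified `stereo_rig`.
#' @param search_radius Neighborhood radius (px) for the disparity lookup.
#' @return A `landmark_set` in the intraoperative frame.
#' @export
landmarks_from_disparity <- function(reference, disp, rig, search_radius = 2L) {
  stopifnot(inherits(disp, "disparity_map"), inherits(rig, "stereo_rig"))
  if (!rig$rectified) stopf("landmarks_from_disparity requires a rectified rig")
  pts <- if (inherits(reference, "landmark_set")) reference$points
         else as_points_matrix(reference, "reference")
  nms <- if (inherits(reference, "landmark_set")) reference$names
         else paste0("landmark_", seq_len(nrow(pts)))
  cam <- rig$left
  uv <- project_points(pts, cam, apply_distortion = FALSE)
  H <- nrow(disp$values); W <- ncol(disp$values)
  out <- matrix(NA_real_, nrow(pts), 3)
  r <- as.integer(search_radius)
  for (i in seq_len(nrow(pts))) {
    u0 <- round(uv[i, 1]); v0 <- round(uv[i, 2])
    if (u0 < 0 || u0 > W - 1 || v0 < 0 || v0 > H - 1)
      stopf("landmark '%s' projects outside the image (pixel %d, %d)",
            nms[i], u0, v0)
    us <- max(0, u0 - r):min(W - 1, u0 + r)
    vs <- max(0, v0 - r):min(H - 1, v0 + r)
    win <- disp$values[vs + 1, us + 1, drop = FALSE]
    d <- stats::median(win[is.finite(win)])
    if (!is.finite(d) || d <= 0)
      stopf("no valid disparity near landmark '%s' (pixel %d, %d)", nms[i], u0, v0)
    z <- cam$fx * rig$baseline_mm / d
    out[i, ] <- c((uv[i, 1] - cam$cx) * z / cam$fx,
                  (uv[i, 2] - cam$cy) * z / cam$fy,
                  z)
  }
  landmark_set(nms, out, frame = "intraop")
}
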