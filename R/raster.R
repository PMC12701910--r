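#' Triangle mesh container
#'
#' @param vertices N x 3 matrix of vertex coordinates (mm).
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @param label Optional structure label.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, label = NULL) {
  vertices <- as_points_matrix(vertices, "vertices")
  if (!all(is.finite(vertices))) stopf("mesh vertices must be finite")
  faces <- as.matrix(faces)
  if (ncol(faces) != 3L) stopf("'faces' must be an M x 3 index matrix")
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stopf("face indices out of range [1, %d]", nrow(vertices))
  structure(list(vertices = vertices, faces = faces, label = label),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh%s> %d vertices, %d faces\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Per-vertex normals: area-weighted average of incident face normals
# (the cross product magnitude is twice the face area, so summing raw cross
# products weights by area for free).
vertex_normals <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- matrix(0, nrow(vertices), 3)
  for (k in 1:3) {
    acc <- rowsum(fn, group = faces[, k], reorder = FALSE)
    n[as.integer(rownames(acc)), ] <- n[as.integer(rownames(acc)), ] + acc
  }
  len <- sqrt(rowSums(n^2))
  len[len < 1e-12] <- 1
  n / len
}

# Z-buffered perspective rasterization of a triangle mesh.
#
# Projects vertices with the camera model (optionally with distortion --
# valid for small triangles), then scan-converts each triangle over its
# pixel bounding box with barycentric inside tests and perspective-correct
# interpolation of depth and one scalar vertex attribute.
#
# Returns list(depth = H x W (Inf where empty), attr = H x W (NA where
# empty), mask = logical H x W).
rasterize_mesh <- function(vertices, faces, cam, width, height,
                           vertex_attr = NULL, apply_distortion = FALSE,
                           near = 1e-6,
                           depth = NULL, attr = NULL) {
  stopifnot(inherits(cam, "camera_params"))
  if (is.null(depth)) depth <- matrix(Inf, height, width)
  if (is.null(attr)) attr <- matrix(NA_real_, height, width)
  if (nrow(faces) == 0L)
    return(list(depth = depth, attr = attr, mask = is.finite(depth)))
  z <- vertices[, 3]
  ok_v <- z > near
  uv <- matrix(NA_real_, nrow(vertices), 2)
  if (any(ok_v))
    uv[ok_v, ] <- project_points(vertices[ok_v, , drop = FALSE], cam,
                                 apply_distortion = apply_distortion)
  invz <- ifelse(ok_v, 1 / z, NA_real_)
  if (is.null(vertex_attr)) vertex_attr <- rep(1, nrow(vertices))
  eps <- 1e-9
  for (f in seq_len(nrow(faces))) {
    i <- faces[f, ]
    if (!all(ok_v[i])) next
    x1 <- uv[i[1], 1]; y1 <- uv[i[1], 2]
    x2 <- uv[i[2], 1]; y2 <- uv[i[2], 2]
    x3 <- uv[i[3], 1]; y3 <- uv[i[3], 2]
    u_lo <- max(0L, as.integer(ceiling(min(x1, x2, x3) - eps)))
    u_hi <- min(width - 1L, as.integer(floor(max(x1, x2, x3) + eps)))
    v_lo <- max(0L, as.integer(ceiling(min(y1, y2, y3) - eps)))
    v_hi <- min(height - 1L, as.integer(floor(max(y1, y2, y3) + eps)))
    if (u_lo > u_hi || v_lo > v_hi) next
    den <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    if (abs(den) < 1e-12) next
    nu <- u_hi - u_lo + 1L; nv <- v_hi - v_lo + 1L
    px <- rep(u_lo:u_hi, each = nv)
    py <- rep(v_lo:v_hi, times = nu)
    l1 <- ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / den
    l2 <- ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / den
    l3 <- 1 - l1 - l2
    inside <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    if (!any(inside)) next
    l1 <- l1[inside]; l2 <- l2[inside]; l3 <- l3[inside]
    w <- l1 * invz[i[1]] + l2 * invz[i[2]] + l3 * invz[i[3]]
    zpix <- 1 / w
    apix <- (l1 * invz[i[1]] * vertex_attr[i[1]] +
             l2 * invz[i[2]] * vertex_attr[i[2]] +
             l3 * invz[i[3]] * vertex_attr[i[3]]) / w
    idx <- px[inside] * height + py[inside] + 1L
    closer <- zpix < depth[idx]
    if (any(closer)) {
      idx <- idx[closer]
      depth[idx] <- zpix[closer]
      attr[idx] <- apix[closer]
    }
  }
  list(depth = depth, attr = attr, mask = is.finite(depth))
}
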