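#' Overlay style
#'
#' Per-structure presentation of the AR overlay: RGB color, opacity, render
#' mode (`fill`, `wireframe` or `silhouette`) and a visibility toggle, plus
#' an optional region-of-interest rectangle. The default palette follows
#' the usual presentation of these structures: mitral annulus yellow,
#' aortic valve red, Koch's triangle blue, circumflex red; default opacity
#' 0.45 so the tissue stays visible beneath the overlay.
#'
#' @param structures Named list; each entry is a list with `color`
#'   (length-3 RGB in `[0, 1]`), `opacity` in `[0, 1]`, `mode`, `visible`.
#' @param roi Optional `c(x0, y0, w, h)` pixel rectangle (0-based corner).
#' @return An object of class `overlay_style`.
#' @export
overlay_style <- function(structures = list(), roi = NULL) {
  defaults <- list(color = c(1, 1, 0), opacity = 0.45, mode = "fill", visible = TRUE)
  structures <- lapply(structures, function(s) {
    s <- utils::modifyList(defaults, s)
    if (s$opacity < 0 || s$opacity > 1) stopf("opacity must lie in [0, 1]")
    if (!s$mode %in% c("fill", "wireframe", "silhouette"))
      stopf("mode must be fill, wireframe or silhouette (got '%s')", s$mode)
    s
  })
  structure(list(structures = structures, roi = roi), class = "overlay_style")
}

#' @rdname overlay_style
#' @export
default_overlay_style <- function(roi = NULL) {
  overlay_style(list(
    annulus_ring = list(color = c(1, 1, 0), opacity = 0.45, mode = "fill"),
    aortic_valve = list(color = c(1, 0.1, 0.1), opacity = 0.45, mode = "fill"),
    koch_triangle = list(color = c(0.15, 0.3, 1), opacity = 0.45, mode = "fill"),
    circumflex = list(color = c(1, 0.1, 0.1), opacity = 0.45, mode = "fill")
  ), roi = roi)
}

to_rgb_array <- function(image) {
  if (length(dim(image)) == 3L) {
    if (dim(image)[3] >= 3L) return(image[, , 1:3, drop = FALSE])
    image <- image[, , 1]
  }
  array(rep(image, 3), dim = c(nrow(image), ncol(image), 3))
}

# 4-neighbor binary erosion
erode_mask <- function(m) {
  H <- nrow(m); W <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, m[-H, , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, m[, -W, drop = FALSE])
  m & up & dn & lf & rt
}

dilate_mask <- function(m) {
  H <- nrow(m); W <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, m[-H, , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, m[, -W, drop = FALSE])
  m | up | dn | lf | rt
}

# rasterize mesh edges: mark pixels along each projected edge
wireframe_mask <- function(mesh, cam, W, H, apply_distortion = FALSE) {
  V <- mesh$vertices
  keep <- V[, 3] > 1e-6
  uv <- matrix(NA_real_, nrow(V), 2)
  if (any(keep))
    uv[keep, ] <- project_points(V[keep, , drop = FALSE], cam, apply_distortion)
  edges <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  edges <- unique(t(apply(edges, 1, sort)))
  mask <- matrix(FALSE, H, W)
  for (e in seq_len(nrow(edges))) {
    p1 <- uv[edges[e, 1], ]; p2 <- uv[edges[e, 2], ]
    if (any(is.na(p1)) || any(is.na(p2))) next
    len <- max(abs(p2 - p1))
    tseq <- seq(0, 1, length.out = max(2L, ceiling(len) + 1L))
    us <- round(p1[1] + tseq * (p2[1] - p1[1]))
    vs <- round(p1[2] + tseq * (p2[2] - p1[2]))
    ok <- us >= 0 & us < W & vs >= 0 & vs < H
    mask[cbind(vs[ok] + 1, us[ok] + 1)] <- TRUE
  }
  mask
}

#' Render registered anatomy onto an endoscopic image
#'
#' Projects each visible structure mesh (already transformed into the
#' intraoperative camera frame by the registration result) with the camera
#' model, resolves inter-structure occlusion with a shared depth buffer,
#' and alpha-blends each structure's color over the image at its opacity.
#' `wireframe` draws projected mesh edges; `silhouette` draws a 2 px
#' depth-discontinuity contour of the structure footprint. Structures whose
#' entire geometry lies behind the camera are skipped with a warning.
#' Pixels outside projected structure footprints (and outside the style's
#' region of interest, when set) are never altered. Deterministic.
#'
#' @param image Background image (H x W grayscale matrix or H x W x 3 array,
#'   values in `[0, 1]`).
#' @param structures Named list of `tri_mesh` in the camera frame.
#' @param cam A `camera_params`.
#' @param style An `overlay_style`; structures without a style entry are
#'   not drawn.
#' @param apply_distortion Project with the distortion model.
#' @return H x W x 3 composite array.
#' @export
render_overlay <- function(image, structures, cam,
                           style = default_overlay_style(),
                           apply_distortion = FALSE) {
  stopifnot(inherits(cam, "camera_params"), inherits(style, "overlay_style"))
  img <- to_rgb_array(image)
  H <- dim(img)[1]; W <- dim(img)[2]
  zbuf <- matrix(Inf, H, W)
  sid <- matrix(0L, H, W)
  line_layers <- list()
  drawn <- character(0)
  for (nm in names(structures)) {
    st <- style$structures[[nm]]
    if (is.null(st) || !isTRUE(st$visible)) next
    mesh <- structures[[nm]]
    if (all(mesh$vertices[, 3] <= 0)) {
      warnf("structure '%s' lies entirely behind the camera; skipped", nm)
      next
    }
    drawn <- c(drawn, nm)
    if (st$mode == "wireframe") {
      line_layers[[nm]] <- wireframe_mask(mesh, cam, W, H, apply_distortion)
      next
    }
    rast <- rasterize_mesh(mesh$vertices, mesh$faces, cam, W, H,
                           apply_distortion = apply_distortion,
                           depth = zbuf)
    newpix <- rast$depth < zbuf
    zbuf <- rast$depth
    sid[newpix] <- match(nm, names(structures))
    if (st$mode == "silhouette") {
      fp <- sid == match(nm, names(structures))
      contour <- fp & !erode_mask(fp)
      line_layers[[nm]] <- dilate_mask(contour)     # ~2 px wide outline
      sid[fp] <- 0L                                  # footprint itself untouched
    }
  }
  out <- img
  for (nm in drawn) {
    st <- style$structures[[nm]]
    if (st$mode == "fill") {
      m <- sid == match(nm, names(structures))
      if (!any(m)) next
      for (ch in 1:3) {
        plane <- out[, , ch]
        plane[m] <- (1 - st$opacity) * plane[m] + st$opacity * st$color[ch]
        out[, , ch] <- plane
      }
    }
  }
  for (nm in names(line_layers)) {
    st <- style$structures[[nm]]
    m <- line_layers[[nm]]
    if (!any(m)) next
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[m] <- (1 - st$opacity) * plane[m] + st$opacity * st$color[ch]
      out[, , ch] <- plane
    }
  }
  if (!is.null(style$roi)) {
    roi <- style$roi
    keep <- matrix(TRUE, H, W)
    keep[(roi[2] + 1):(roi[2] + roi[4]), (roi[1] + 1):(roi[1] + roi[3])] <- FALSE
    for (ch in 1:3) {
      plane <- out[, , ch]; orig <- img[, , ch]
      plane[keep] <- orig[keep]
      out[, , ch] <- plane
    }
  }
  out
}

#' Stereo overlay frame
#'
#' @param left,right Composite images (H x W x 3).
#' @param transform The registration transform used (provenance).
#' @param style The `overlay_style` used.
#' @param frame_id Source frame identifier.
#' @return An object of class `overlay_frame`.
#' @export
overlay_frame <- function(left, right, transform = NULL, style = NULL,
                          frame_id = NA_character_) {
  if (!all(dim(left) == dim(right)))
    stopf("left and right composites must have equal size")
  structure(list(left = left, right = right,
                 provenance = list(transform = transform, style = style,
                                   frame_id = frame_id, roi = NULL)),
            class = "overlay_frame")
}

#' Crop an overlay frame to a region of interest
#'
#' Both composites are cropped identically and the ROI is recorded in the
#' frame's provenance.
#'
#' @param frame An `overlay_frame`.
#' @param roi `c(x0, y0, w, h)`, 0-based top-left corner, in pixels.
#' @return The cropped `overlay_frame`.
#' @export
crop_roi <- function(frame, roi) {
  stopifnot(inherits(frame, "overlay_frame"))
  roi <- as.integer(roi)
  H <- dim(frame$left)[1]; W <- dim(frame$left)[2]
  if (length(roi) != 4L || roi[1] < 0 || roi[2] < 0 || roi[3] < 1 || roi[4] < 1 ||
      roi[1] + roi[3] > W || roi[2] + roi[4] > H)
    stopf("roi (x0=%d, y0=%d, w=%d, h=%d) out of bounds for %d x %d image",
          roi[1], roi[2], roi[3], roi[4], W, H)
  rows <- (roi[2] + 1):(roi[2] + roi[4])
  cols <- (roi[1] + 1):(roi[1] + roi[3])
  frame$left <- frame$left[rows, cols, , drop = FALSE]
  frame$right <- frame$right[rows, cols, , drop = FALSE]
  frame$provenance$roi <- roi
  frame
}

#' Combine left/right composites into one stereo image
#'
#' `side_by_side` concatenates horizontally (lossless; [split_side_by_side]
#' recovers the inputs bit-exactly); `anaglyph` builds a red-cyan image with
#' the left eye's luminance in the red channel and the right eye's in green
#' and blue.
#'
#' @param left,right H x W x 3 arrays of equal size.
#' @param layout `"side_by_side"` or `"anaglyph"`.
#' @return The composite image array.
#' @export
stereo_composite <- function(left, right, layout = c("side_by_side", "anaglyph")) {
  layout <- match.arg(layout)
  left <- to_rgb_array(left); right <- to_rgb_array(right)
  if (!all(dim(left) == dim(right)))
    stopf("left and right images must have equal size")
  H <- dim(left)[1]; W <- dim(left)[2]
  if (layout == "side_by_side") {
    out <- array(0, dim = c(H, 2 * W, 3))
    out[, 1:W, ] <- left
    out[, (W + 1):(2 * W), ] <- right
    out
  } else {
    lum_l <- to_luminance(left); lum_r <- to_luminance(right)
    out <- array(0, dim = c(H, W, 3))
    out[, , 1] <- lum_l
    out[, , 2] <- lum_r
    out[, , 3] <- lum_r
    out
  }
}

#' @rdname stereo_composite
#' @param composite A side-by-side composite of even width.
#' @return `split_side_by_side` returns `list(left, right)`.
#' @export
split_side_by_side <- function(composite) {
  W2 <- dim(composite)[2]
  if (W2 %% 2L != 0L) stopf("side-by-side composite must have even width")
  W <- W2 %/% 2L
  list(left = composite[, 1:W, , drop = FALSE],
       right = composite[, (W + 1):W2, , drop = FALSE])
}
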