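#' Write a point cloud as PLY
#'
#' Binary little-endian PLY with `x, y, z` as float32 (mm) and, when the
#' cloud carries colors, `red, green, blue` as uchar. `format = "ascii"`
#' writes the ASCII dialect instead.
#'
#' @param cloud A `point_cloud`.
#' @param path Output path.
#' @param format `"binary_little_endian"` or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_ply_cloud <- function(cloud, path, format = c("binary_little_endian", "ascii")) {
  stopifnot(inherits(cloud, "point_cloud"))
  format <- match.arg(format)
  n <- nrow(cloud$points)
  has_rgb <- !is.null(cloud$colors)
  hdr <- c("ply", paste("format", format, "1.0"),
           "comment metric point cloud, units mm",
           paste("element vertex", n),
           "property float x", "property float y", "property float z")
  if (has_rgb) hdr <- c(hdr, "property uchar red", "property uchar green",
                        "property uchar blue")
  hdr <- c(hdr, "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (format == "ascii") {
    if (has_rgb) {
      rgb8 <- round(pmin(pmax(cloud$colors, 0), 1) * 255)
      lines <- paste(cloud$points[, 1], cloud$points[, 2], cloud$points[, 3],
                     rgb8[, 1], rgb8[, 2], rgb8[, 3])
    } else {
      lines <- paste(cloud$points[, 1], cloud$points[, 2], cloud$points[, 3])
    }
    writeLines(lines, con, sep = "\n")
  } else {
    xyz <- writeBin(as.vector(t(cloud$points)), raw(), size = 4, endian = "little")
    xyz <- matrix(xyz, nrow = 12)                  # 12 bytes per vertex
    if (has_rgb) {
      rgb8 <- as.raw(round(pmin(pmax(t(cloud$colors), 0), 1) * 255))
      rgb8 <- matrix(rgb8, nrow = 3)
      writeBin(as.vector(rbind(xyz, rgb8)), con)
    } else {
      writeBin(as.vector(xyz), con)
    }
  }
  invisible(path)
}

parse_ply_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character(0)
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) stopf("unexpected end of PLY header in %s", path)
    lines <- c(lines, ln)
    if (ln == "end_header") break
    if (length(lines) > 200) stopf("PLY header too long in %s", path)
  }
  offset <- seek(con)
  fmt <- sub("^format ([a-z_]+).*$", "\\1", grep("^format ", lines, value = TRUE)[1])
  elements <- list()
  cur <- NULL
  for (ln in lines) {
    if (grepl("^element ", ln)) {
      parts <- strsplit(ln, " +")[[1]]
      cur <- parts[2]
      elements[[cur]] <- list(count = as.integer(parts[3]), props = list())
    } else if (grepl("^property ", ln) && !is.null(cur)) {
      parts <- strsplit(ln, " +")[[1]]
      elements[[cur]]$props[[length(elements[[cur]]$props) + 1]] <- parts[-1]
    }
  }
  list(format = fmt, elements = elements, data_offset = offset, header = lines)
}

ply_type_size <- function(t) {
  switch(t, char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
         short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
         int = 4L, uint = 4L, int32 = 4L, uint32 = 4L, float = 4L, float32 = 4L,
         double = 8L, float64 = 8L,
         stopf("unsupported PLY type '%s'", t))
}

read_ply_vertices <- function(path, hdr, want_faces = FALSE) {
  ve <- hdr$elements$vertex
  if (is.null(ve)) stopf("PLY file %s has no vertex element", path)
  props <- vapply(ve$props, function(p) p[length(p)], character(1))
  types <- vapply(ve$props, function(p) p[1], character(1))
  n <- ve$count
  fe <- hdr$elements$face
  if (hdr$format == "ascii") {
    all_lines <- readLines(path)
    start <- which(all_lines == "end_header")[1] + 1
    vl <- all_lines[start:(start + n - 1)]
    vals <- matrix(as.numeric(unlist(strsplit(trimws(vl), " +"))), nrow = n, byrow = TRUE)
    verts <- vals[, match(c("x", "y", "z"), props), drop = FALSE]
    rgb <- if (all(c("red", "green", "blue") %in% props))
      vals[, match(c("red", "green", "blue"), props), drop = FALSE] / 255 else NULL
    faces <- NULL
    if (want_faces && !is.null(fe) && fe$count > 0) {
      fl <- all_lines[(start + n):(start + n + fe$count - 1)]
      fv <- lapply(strsplit(trimws(fl), " +"), as.integer)
      stopifnot(all(vapply(fv, `[`, integer(1), 1) == 3L))
      faces <- do.call(rbind, lapply(fv, function(x) x[2:4])) + 1L
    }
    return(list(vertices = verts, colors = rgb, faces = faces))
  }
  if (hdr$format != "binary_little_endian")
    stopf("unsupported PLY format '%s'", hdr$format)
  sizes <- vapply(types, ply_type_size, integer(1))
  stride <- sum(sizes)
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, hdr$data_offset)
  raw_v <- readBin(con, "raw", n = stride * n)
  m <- matrix(raw_v, nrow = stride)
  offs <- cumsum(c(0, sizes))
  grab <- function(name) {
    i <- match(name, props)
    if (is.na(i)) return(NULL)
    bytes <- m[(offs[i] + 1):(offs[i] + sizes[i]), , drop = FALSE]
    if (types[i] %in% c("float", "float32"))
      readBin(as.vector(bytes), "numeric", size = 4, n = n, endian = "little")
    else if (types[i] %in% c("double", "float64"))
      readBin(as.vector(bytes), "numeric", size = 8, n = n, endian = "little")
    else if (sizes[i] == 1L)
      as.integer(readBin(as.vector(bytes), "integer", size = 1, n = n, signed = FALSE))
    else
      readBin(as.vector(bytes), "integer", size = sizes[i], n = n, endian = "little")
  }
  verts <- cbind(grab("x"), grab("y"), grab("z"))
  rgb <- if (all(c("red", "green", "blue") %in% props))
    cbind(grab("red"), grab("green"), grab("blue")) / 255 else NULL
  faces <- NULL
  if (want_faces && !is.null(fe) && fe$count > 0) {
    # triangles only: 1 count byte (uchar) + 3 x int32
    fraw <- readBin(con, "raw", n = 13L * fe$count)
    fm <- matrix(fraw, nrow = 13L)
    counts <- as.integer(fm[1, ])
    if (!all(counts == 3L)) stopf("only triangle faces are supported (%s)", path)
    idx <- readBin(as.vector(fm[2:13, ]), "integer", size = 4,
                   n = 3L * fe$count, endian = "little")
    faces <- matrix(idx, ncol = 3, byrow = TRUE) + 1L
  }
  list(vertices = verts, colors = rgb, faces = faces)
}

#' @rdname write_ply_cloud
#' @export
read_ply_cloud <- function(path) {
  if (!file.exists(path)) stopf("PLY file not found: %s", path)
  hdr <- parse_ply_header(path)
  d <- read_ply_vertices(path, hdr, want_faces = FALSE)
  point_cloud(d$vertices, colors = d$colors)
}

#' Write and read triangle meshes as PLY
#'
#' Binary little-endian PLY with float32 vertices (mm) and triangle faces
#' (`list uchar int32`); the ASCII dialect is also read and written.
#'
#' @param mesh A `tri_mesh`.
#' @param path File path.
#' @param format `"binary_little_endian"` or `"ascii"`.
#' @return `read_ply_mesh` returns a `tri_mesh`; `write_ply_mesh` returns
#'   `path` invisibly.
#' @export
write_ply_mesh <- function(mesh, path, format = c("binary_little_endian", "ascii")) {
  stopifnot(inherits(mesh, "tri_mesh"))
  format <- match.arg(format)
  n <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  hdr <- c("ply", paste("format", format, "1.0"),
           if (!is.null(mesh$label)) paste("comment structure", mesh$label),
           paste("element vertex", n),
           "property float x", "property float y", "property float z",
           paste("element face", nf),
           "property list uchar int vertex_indices",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  f0 <- mesh$faces - 1L
  if (format == "ascii") {
    writeLines(paste(mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
    writeLines(paste(3L, f0[, 1], f0[, 2], f0[, 3]), con)
  } else {
    writeBin(as.vector(t(mesh$vertices)), con, size = 4, endian = "little")
    if (nf > 0) {
      idx <- writeBin(as.vector(t(f0)), raw(), size = 4, endian = "little")
      idx <- matrix(idx, nrow = 12)
      cnt <- matrix(as.raw(3L), nrow = 1, ncol = nf)
      writeBin(as.vector(rbind(cnt, idx)), con)
    }
  }
  invisible(path)
}

#' @rdname write_ply_mesh
#' @export
read_ply_mesh <- function(path) {
  if (!file.exists(path)) stopf("PLY file not found: %s", path)
  hdr <- parse_ply_header(path)
  d <- read_ply_vertices(path, hdr, want_faces = TRUE)
  label <- sub("^comment structure ", "",
               grep("^comment structure ", hdr$header, value = TRUE)[1])
  if (is.na(label)) label <- NULL
  tri_mesh(d$vertices, d$faces %||% matrix(integer(0), 0, 3), label = label)
}

#' Write and read ASCII STL meshes
#'
#' @param mesh A `tri_mesh`.
#' @param path File path.
#' @param name Solid name recorded in the file.
#' @return `read_stl_ascii` returns a `tri_mesh` (vertices are
#'   de-duplicated); `write_stl_ascii` returns `path` invisibly.
#' @export
write_stl_ascii <- function(mesh, path, name = mesh$label %||% "mesh") {
  stopifnot(inherits(mesh, "tri_mesh"))
  V <- mesh$vertices; F_ <- mesh$faces
  a <- V[F_[, 1], , drop = FALSE]; b <- V[F_[, 2], , drop = FALSE]
  c_ <- V[F_[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len < 1e-12] <- 1
  nrm <- nrm / len
  fmt <- function(p) sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])
  lines <- c(paste("solid", name),
             as.vector(rbind(paste("  facet normal", fmt(nrm)),
                             "    outer loop",
                             paste("      vertex", fmt(a)),
                             paste("      vertex", fmt(b)),
                             paste("      vertex", fmt(c_)),
                             "    endloop",
                             "  endfacet")),
             paste("endsolid", name))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_stl_ascii
#' @export
read_stl_ascii <- function(path) {
  if (!file.exists(path)) stopf("STL file not found: %s", path)
  lines <- readLines(path)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stopf("malformed ASCII STL: %s", path)
  nums <- matrix(as.numeric(unlist(strsplit(trimws(sub("^\\s*vertex\\s+", "", vl)),
                                            "\\s+"))),
                 ncol = 3, byrow = TRUE)
  key <- apply(round(nums, 9), 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  verts <- nums[uniq, , drop = FALSE]
  idx <- match(key, key[uniq])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  label <- sub("^solid\\s*", "", lines[1])
  tri_mesh(verts, faces, label = if (nzchar(label)) label else NULL)
}

#' Write and read landmark CSV files
#'
#' Schema: a `# frame: <preop|intraop>` comment line, then a header
#' `name,x_mm,y_mm,z_mm`. The reader also accepts stereo pixel-pair picks
#' with header `name,u_left,v_left,u_right,v_right`, returned as a data
#' frame of class `landmark_pixel_pairs` for triangulation with
#' [triangulate_pixel_pairs()].
#'
#' @param lm A `landmark_set`.
#' @param path File path.
#' @return `read_landmarks_csv` returns a `landmark_set` or a
#'   `landmark_pixel_pairs` data frame; `write_landmarks_csv` returns
#'   `path` invisibly.
#' @export
write_landmarks_csv <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame: %s", lm$frame), con)
  writeLines("name,x_mm,y_mm,z_mm", con)
  writeLines(paste(lm$names, lm$points[, 1], lm$points[, 2], lm$points[, 3],
                   sep = ","), con)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @export
read_landmarks_csv <- function(path) {
  if (!file.exists(path)) stopf("landmark file not found: %s", path)
  lines <- readLines(path)
  frame <- "intraop"
  fl <- grep("^#\\s*frame:", lines, value = TRUE)
  if (length(fl)) frame <- trimws(sub("^#\\s*frame:", "", fl[1]))
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]),
                        stringsAsFactors = FALSE)
  if (all(c("x_mm", "y_mm", "z_mm") %in% names(df))) {
    landmark_set(df$name, cbind(df$x_mm, df$y_mm, df$z_mm), frame = frame)
  } else if (all(c("u_left", "v_left", "u_right", "v_right") %in% names(df))) {
    class(df) <- c("landmark_pixel_pairs", class(df))
    attr(df, "frame") <- frame
    df
  } else {
    stopf("unrecognized landmark CSV header in %s", path)
  }
}

#' Triangulate stereo pixel-pair landmark picks
#'
#' For a rectified rig: `d = u_left - u_right`, `z = fx * baseline / d`,
#' and x/y from the left pixel and the intrinsics.
#'
#' @param pairs A `landmark_pixel_pairs` data frame from
#'   [read_landmarks_csv()].
#' @param rig A rectified `stereo_rig`.
#' @return A `landmark_set` in the intraoperative frame.
#' @export
triangulate_pixel_pairs <- function(pairs, rig) {
  stopifnot(inherits(pairs, "landmark_pixel_pairs"), inherits(rig, "stereo_rig"))
  if (!rig$rectified) stopf("pixel-pair triangulation requires a rectified rig")
  cam <- rig$left
  d <- pairs$u_left - pairs$u_right
  if (any(d <= 0)) stopf("non-positive disparity in landmark pixel pairs")
  z <- cam$fx * rig$baseline_mm / d
  pts <- cbind((pairs$u_left - cam$cx) * z / cam$fx,
               (pairs$v_left - cam$cy) * z / cam$fy,
               z)
  landmark_set(pairs$name, pts, frame = "intraop")
}

#' Write and read grayscale/color images as PNG
#'
#' Thin wrappers around the png package; images are H x W matrices or
#' H x W x 3 arrays with values in `[0, 1]`.
#'
#' @param img Image to write.
#' @param path File path.
#' @return `read_image_png` returns the image; `write_image_png` returns
#'   `path` invisibly.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  if (!file.exists(path)) stopf("image not found: %s", path)
  png::readPNG(path)
}

#' Write and read disparity maps as 16-bit fixed-point PNG
#'
#' Disparities are stored in 1/16 px fixed point across two 8-bit channels
#' (high byte in red, low byte in green; invalid pixels encode 0xFFFF), with
#' a JSON sidecar (`<path>.json`) recording the scaling and the matcher
#' parameters.
#'
#' @param disp A `disparity_map`.
#' @param path PNG path; the sidecar is written next to it.
#' @return `read_disparity_png` returns a `disparity_map`;
#'   `write_disparity_png` returns `path` invisibly.
#' @export
write_disparity_png <- function(disp, path) {
  stopifnot(inherits(disp, "disparity_map"))
  v16 <- round(disp$values * 16)
  v16[!disp$valid | is.na(v16)] <- 65535
  v16 <- pmin(pmax(v16, 0), 65535)
  H <- nrow(v16); W <- ncol(v16)
  img <- array(0, dim = c(H, W, 3))
  img[, , 1] <- (v16 %/% 256) / 255
  img[, , 2] <- (v16 %% 256) / 255
  png::writePNG(img, path)
  sidecar <- list(fixed_point_scale = 16, invalid_code = 65535,
                  encoding = "red = high byte, green = low byte",
                  block_size = disp$block_size, search_range = disp$search_range,
                  params = disp$params)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_disparity_png
#' @export
read_disparity_png <- function(path) {
  img <- png::readPNG(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v16 <- round(img[, , 1] * 255) * 256 + round(img[, , 2] * 255)
  valid <- v16 != meta$invalid_code
  values <- v16 / meta$fixed_point_scale
  values[!valid] <- NA_real_
  structure(list(values = values, valid = valid,
                 block_size = meta$block_size, search_range = meta$search_range,
                 params = meta$params),
            class = "disparity_map")
}
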