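#' Ordered landmark set
#'
#' A small ordered set of named 3D points on the mitral annulus, used for
#' initial registration. Correspondence between the preoperative and
#' intraoperative sets is by index; by convention landmarks 1 and 2 sit at
#' the anterior and posterior commissure (the two ends of the annulus long
#' axis). For registration use the set must contain 4 to 8 points.
#'
#' @param names Character vector of unique labels.
#' @param points K x 3 matrix in mm.
#' @param frame `"preop"` or `"intraop"`.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(names, points, frame = c("intraop", "preop")) {
  frame <- match.arg(frame)
  points <- as_points_matrix(points)
  if (!all(is.finite(points))) stopf("landmark coordinates must be finite")
  names <- as.character(names)
  if (length(names) != nrow(points)) stopf("one name per landmark required")
  if (anyDuplicated(names)) stopf("landmark names must be unique")
  structure(list(names = names, points = points, frame = frame),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d landmarks, frame '%s'\n", nrow(x$points), x$frame))
  df <- data.frame(name = x$names, x_mm = x$points[, 1], y_mm = x$points[, 2],
                   z_mm = x$points[, 3])
  print(df, row.names = FALSE)
  invisible(x)
}

#' Phantom generator configuration
#'
#' Defaults emulate the geometry of an arrested mitral valve seen through a
#' stereo endoscope: a saddle-shaped annulus of ~35 mm long-axis diameter on
#' a textured tissue surface ~85 mm in front of the camera, a "preoperative"
#' model of the same anatomy inflated by the inverse of a scale factor in
#' the clinically observed 0.61-0.79 range, and manual-pick-level landmark
#' noise of 1 mm.
#'
#' @param semi_major_mm,semi_minor_mm Annulus ellipse radii (long axis x),
#'   mm; must be positive.
#' @param saddle_height_mm Out-of-plane amplitude of the annulus saddle, mm.
#' @param ridge_height_mm,ridge_width_mm Height and width of the raised
#'   fibrous rim along the annulus (mm): the annulus is a geometric ridge on
#'   the tissue surface, not merely a painted curve, so the reconstruction
#'   carries the shape that registration anchors on.
#' @param center_mm Scene center in the left camera frame (x right, y down,
#'   z along the optical axis), mm.
#' @param tilt_deg Tilt of the tissue plane about the x-axis, degrees.
#' @param n_landmarks Number of annulus landmarks, 4 to 8.
#' @param scale True similarity scale mapping preop to intraop, in `(0, 1.5]`.
#' @param landmark_noise_sd_mm Isotropic Gaussian noise added to the
#'   preoperative landmark picks, mm.
#' @param preop_rotation Optional fixed 3x3 rotation of the true transform;
#'   `NULL` draws a random rotation of at most `preop_max_rot_deg`.
#' @param preop_translation Optional fixed translation (mm); `NULL` draws
#'   uniformly from `[-30, 30]^3`.
#' @param preop_max_rot_deg Cap on the random true-transform rotation.
#' @param grid_n Tissue surface grid resolution per side.
#' @param surface_margin Surface half-extent as a multiple of the annulus radii.
#' @param curve_n Number of segments of the annulus polyline.
#' @param texture Band-limited procedural texture parameters:
#'   `n_waves`, `min_wavelength_mm`, `max_wavelength_mm`.
#' @param seed RNG seed; every random draw in the generator derives from it.
#' @return A named list of parameters for [generate_phantom()].
#' @export
phantom_config <- function(semi_major_mm = 17.5,
                           semi_minor_mm = 13,
                           saddle_height_mm = 3,
                           ridge_height_mm = 2.5,
                           ridge_width_mm = 2.5,
                           center_mm = c(0, 0, 85),
                           tilt_deg = 12,
                           n_landmarks = 6,
                           scale = 0.72,
                           landmark_noise_sd_mm = 1,
                           preop_rotation = NULL,
                           preop_translation = NULL,
                           preop_max_rot_deg = 25,
                           grid_n = 96,
                           surface_margin = 1.45,
                           curve_n = 192,
                           texture = list(n_waves = 60, min_wavelength_mm = 1.5,
                                          max_wavelength_mm = 8),
                           seed = 1) {
  list(semi_major_mm = semi_major_mm, semi_minor_mm = semi_minor_mm,
       saddle_height_mm = saddle_height_mm,
       ridge_height_mm = ridge_height_mm, ridge_width_mm = ridge_width_mm,
       center_mm = center_mm,
       tilt_deg = tilt_deg, n_landmarks = n_landmarks, scale = scale,
       landmark_noise_sd_mm = landmark_noise_sd_mm,
       preop_rotation = preop_rotation, preop_translation = preop_translation,
       preop_max_rot_deg = preop_max_rot_deg, grid_n = grid_n,
       surface_margin = surface_margin, curve_n = curve_n, texture = texture,
       seed = seed)
}

# Tube mesh of radius r around an open or closed 3D polyline.
tube_mesh <- function(curve, radius = 1.2, n_around = 10, label = NULL,
                      closed = TRUE) {
  if (closed) curve <- curve[-nrow(curve), , drop = FALSE]  # drop duplicate end
  n <- nrow(curve)
  nxt <- if (closed) c(2:n, 1) else c(2:n, n)
  prv <- if (closed) c(n, 1:(n - 1)) else c(1, 1:(n - 1))
  tang <- curve[nxt, ] - curve[prv, ]
  tang <- tang / sqrt(rowSums(tang^2))
  # a frame per segment: pick a helper vector least aligned with the tangent
  helper <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  flat <- abs(tang[, 3]) > 0.9
  helper[flat, ] <- matrix(rep(c(0, 1, 0), each = sum(flat)), ncol = 3)
  n1 <- cbind(tang[, 2] * helper[, 3] - tang[, 3] * helper[, 2],
              tang[, 3] * helper[, 1] - tang[, 1] * helper[, 3],
              tang[, 1] * helper[, 2] - tang[, 2] * helper[, 1])
  n1 <- n1 / sqrt(rowSums(n1^2))
  n2 <- cbind(tang[, 2] * n1[, 3] - tang[, 3] * n1[, 2],
              tang[, 3] * n1[, 1] - tang[, 1] * n1[, 3],
              tang[, 1] * n1[, 2] - tang[, 2] * n1[, 1])
  ang <- 2 * pi * (0:(n_around - 1)) / n_around
  verts <- matrix(0, n * n_around, 3)
  for (j in seq_len(n_around)) {
    offs <- radius * (cos(ang[j]) * n1 + sin(ang[j]) * n2)
    verts[(j - 1) * n + seq_len(n), ] <- curve + offs
  }
  vid <- function(i, j) (j - 1) * n + i   # i along curve, j around
  faces <- matrix(0L, 0, 3)
  i2 <- if (closed) c(2:n, 1) else 2:n
  i1 <- if (closed) 1:n else 1:(n - 1)
  fl <- vector("list", n_around)
  for (j in seq_len(n_around)) {
    jn <- if (j == n_around) 1L else j + 1L
    fl[[j]] <- rbind(cbind(vid(i1, j), vid(i2, j), vid(i2, jn)),
                     cbind(vid(i1, j), vid(i2, jn), vid(i1, jn)))
  }
  tri_mesh(verts, do.call(rbind, fl), label = label)
}

# Regular-grid height-field surface z = f(x, y), triangulated.
grid_surface <- function(xr, yr, n, fz) {
  xs <- seq(xr[1], xr[2], length.out = n)
  ys <- seq(yr[1], yr[2], length.out = n)
  gx <- rep(xs, times = n)
  gy <- rep(ys, each = n)
  verts <- cbind(gx, gy, fz(gx, gy))
  vid <- function(i, j) (j - 1L) * n + i
  i <- rep(1:(n - 1), times = n - 1)
  j <- rep(1:(n - 1), each = n - 1)
  faces <- rbind(cbind(vid(i, j), vid(i + 1, j), vid(i + 1, j + 1)),
                 cbind(vid(i, j), vid(i + 1, j + 1), vid(i, j + 1)))
  list(vertices = verts, faces = faces, nx = n)
}

# Band-limited procedural texture: a sum of random-plane sinusoids with
# wavelengths in a stated band, rescaled to [0.15, 0.95]. Guarantees local
# image structure at the block-matching scale.
procedural_texture <- function(x, y, params) {
  nw <- params$n_waves %||% 60
  wl <- stats::runif(nw, params$min_wavelength_mm %||% 1.5,
                     params$max_wavelength_mm %||% 8)
  th <- stats::runif(nw, 0, 2 * pi)
  ph <- stats::runif(nw, 0, 2 * pi)
  amp <- stats::runif(nw, 0.4, 1)
  val <- rep(0, length(x))
  for (i in seq_len(nw)) {
    k <- 2 * pi / wl[i]
    val <- val + amp[i] * sin(k * (cos(th[i]) * x + sin(th[i]) * y) + ph[i])
  }
  rng <- range(val)
  0.15 + 0.8 * (val - rng[1]) / max(rng[2] - rng[1], 1e-12)
}

#' Generate a ground-truthed synthetic mitral phantom
#'
#' Builds an intraoperative scene — a textured, tilted tissue surface
#' carrying a saddle-shaped mitral annulus, with labeled structure meshes
#' (annulus ring, aortic valve, Koch's triangle, circumflex artery) and
#' ordered annulus landmarks — together with a "preoperative" model of the
#' same anatomy related by a known ground-truth similarity transform. The
#' annulus is an ellipse with a sinusoidal out-of-plane saddle term,
#' \eqn{(a\cos\theta, b\sin\theta, h\sin 2\theta)}, which lies exactly on
#' the hyperbolic-paraboloid tissue surface \eqn{z = 2h(x/a)(y/b)}.
#' Landmarks 1 and 2 are the anterior and posterior commissures at the ends
#' of the long axis; the remaining landmarks are spread around the annulus.
#' The preoperative landmark set is the inverse true transform applied to
#' the intraoperative landmarks plus isotropic Gaussian noise of the
#' configured standard deviation.
#'
#' All outputs are a pure function of `(config, seed)`.
#'
#' @param config Parameter list from [phantom_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return A list with `scene` (the intraoperative `PhantomScene`: fields
#'   `surface_mesh`, `surface_texture`, `annulus_curve`, `annulus_landmarks`,
#'   `structure_meshes`, `true_intraop_diameter_mm`) and `preop` (the
#'   `PreopModel`: `structure_meshes`, `annulus_curve`, `annulus_landmarks`,
#'   `true_transform`).
#' @export
generate_phantom <- function(config = phantom_config(), seed = config$seed) {
  a <- config$semi_major_mm; b <- config$semi_minor_mm
  h <- config$saddle_height_mm
  if (!is.finite(a) || a <= 0 || !is.finite(b) || b <= 0)
    stopf("annulus radii must be positive (got a=%s, b=%s)", format(a), format(b))
  K <- config$n_landmarks
  if (!is.numeric(K) || K < 4 || K > 8)
    stopf("landmark count must be between 4 and 8 (got %s)", format(K))
  s_true <- config$scale
  if (!is.finite(s_true) || s_true <= 0 || s_true > 1.5)
    stopf("scale factor must lie in (0, 1.5] (got %s)", format(s_true))
  if (is.null(seed)) stopf("a seed is required: the phantom is fully reproducible")

  with_seed(seed, {
    curve_n <- config$curve_n
    stopifnot(curve_n %% 2 == 0)
    rh <- config$ridge_height_mm %||% 0
    rw <- config$ridge_width_mm %||% 2.5
    theta <- 2 * pi * (0:curve_n) / curve_n          # closed: first == last
    # the annulus sits on the crest of a raised rim (height rh) running
    # along the ellipse of the saddle surface
    curve <- cbind(a * cos(theta), b * sin(theta), h * sin(2 * theta) + rh)

    # landmarks on the sampled curve: 1 = anterior commissure (theta = 0),
    # 2 = posterior commissure (theta = pi), rest evenly spread around the
    # annulus (nudged off 0.5 so they never collide with a commissure)
    fr_rest <- (1:(K - 2)) / (K - 1)
    fr_rest[abs(fr_rest - 0.5) < 1e-9] <- 0.5 + 1 / (2 * (K - 1))
    lm_idx <- 1L + as.integer(round(curve_n * c(0, 0.5, fr_rest)))
    stopifnot(!anyDuplicated(lm_idx))
    lm_names <- c("anterior_commissure", "posterior_commissure",
                  paste0("annulus_", seq_len(max(0, K - 2))))[seq_len(K)]

    # tissue surface: hyperbolic paraboloid plus a Gaussian rim along the
    # annulus ellipse; the curve above lies exactly on it (rim peak on the
    # ellipse, where the normalized elliptical radius is 1)
    m <- config$surface_margin
    we <- rw / sqrt(a * b)
    surf <- grid_surface(c(-m * a, m * a), c(-m * b, m * b), config$grid_n,
                         function(x, y) {
                           e <- sqrt((x / a)^2 + (y / b)^2)
                           2 * h * (x / a) * (y / b) +
                             rh * exp(-(e - 1)^2 / (2 * we^2))
                         })
    tex <- procedural_texture(surf$vertices[, 1], surf$vertices[, 2],
                              config$texture)

    # labeled anatomical structure meshes (local frame)
    ring <- tube_mesh(curve, radius = 1.2, n_around = 10,
                      label = "annulus_ring", closed = TRUE)
    av_ang <- seq(0, 2 * pi, length.out = 33)
    av_curve <- cbind(7 * cos(av_ang), -(b + 9) + 4 * sin(av_ang),
                      -4 + 0 * av_ang)
    aortic <- tube_mesh(av_curve, radius = 1.5, n_around = 8,
                        label = "aortic_valve", closed = TRUE)
    kt <- tri_mesh(rbind(c(0.75 * a, -0.45 * b, -5),
                         c(0.95 * a, -0.05 * b, -4),
                         c(0.55 * a, -0.12 * b, -7)),
                   matrix(c(1L, 2L, 3L), 1, 3), label = "koch_triangle")
    cx_ang <- seq(0.12 * pi, 0.88 * pi, length.out = 48)
    cx_curve <- cbind(1.22 * a * cos(cx_ang), 1.22 * b * sin(cx_ang),
                      -2 + h * sin(2 * cx_ang))
    circum <- tube_mesh(cx_curve, radius = 1.0, n_around = 8,
                        label = "circumflex", closed = FALSE)
    # annulus-region surface patch (rim + nearby tissue): the dense-ICP
    # source, carrying the ridge profile that makes scale observable
    e_surf <- sqrt((surf$vertices[, 1] / a)^2 + (surf$vertices[, 2] / b)^2)
    in_band <- abs(e_surf - 1) * sqrt(a * b) <= 3 * rw
    f_in <- in_band[surf$faces[, 1]] & in_band[surf$faces[, 2]] &
      in_band[surf$faces[, 3]]
    keep_v <- sort(unique(as.vector(surf$faces[f_in, ])))
    remap <- integer(nrow(surf$vertices)); remap[keep_v] <- seq_along(keep_v)
    patch <- tri_mesh(surf$vertices[keep_v, , drop = FALSE],
                      matrix(remap[surf$faces[f_in, ]], ncol = 3),
                      label = "annulus_surface")

    # place the scene in the left camera frame: tilt, then translate
    Rt <- rot_x(config$tilt_deg)
    place <- function(p) sweep(p %*% t(Rt), 2, config$center_mm, "+")
    place_mesh <- function(msh) { msh$vertices <- place(msh$vertices); msh }
    curve_w <- place(curve)
    surface_mesh <- tri_mesh(place(surf$vertices), surf$faces, label = "tissue")
    structures <- list(annulus_ring = place_mesh(ring),
                       aortic_valve = place_mesh(aortic),
                       koch_triangle = place_mesh(kt),
                       circumflex = place_mesh(circum),
                       annulus_surface = place_mesh(patch))
    lm_intraop <- landmark_set(lm_names, curve_w[lm_idx, , drop = FALSE],
                               frame = "intraop")
    diameter <- max(stats::dist(curve_w[-nrow(curve_w), ]))

    scene <- list(surface_mesh = surface_mesh,
                  surface_texture = tex,
                  annulus_curve = curve_w,
                  annulus_landmarks = lm_intraop,
                  landmark_curve_index = lm_idx,
                  structure_meshes = structures,
                  true_intraop_diameter_mm = diameter,
                  config = config)
    class(scene) <- "phantom_scene"

    # ground-truth similarity transform preop -> intraop
    R_true <- config$preop_rotation %||% random_rotation(config$preop_max_rot_deg)
    t_true <- config$preop_translation %||% stats::runif(3, -30, 30)
    true_transform <- similarity_transform(s_true, R_true, t_true)
    inv_T <- st_invert(true_transform)

    noise <- matrix(stats::rnorm(3 * K, sd = config$landmark_noise_sd_mm), K, 3)
    lm_preop <- landmark_set(lm_names,
                             apply_transform(inv_T, lm_intraop$points) + noise,
                             frame = "preop")
    preop <- list(structure_meshes = lapply(structures,
                                            function(m) apply_transform(inv_T, m)),
                  annulus_curve = apply_transform(inv_T, curve_w),
                  annulus_landmarks = lm_preop,
                  true_transform = true_transform)
    class(preop) <- "preop_model"

    list(scene = scene, preop = preop)
  })
}

#' Render a stereo image pair of a phantom scene
#'
#' Z-buffered Lambertian rasterization of the textured tissue surface into
#' both eyes of a stereo rig, with the left camera at the origin and the
#' right camera at `(baseline, 0, 0)` oriented by the rig's relative
#' rotation. For an unrectified rig the per-eye distortion models are
#' applied during projection. Returns the per-pixel ground-truth depth map
#' of each eye (the z-coordinate of the nearest surface point along the
#' ray, `Inf` on background), which downstream stereo reconstruction can be
#' validated against. Optional additive Gaussian pixel noise is seeded and
#' expressed in 8-bit gray levels.
#'
#' @param scene A `phantom_scene` from [generate_phantom()] (any list with
#'   `surface_mesh` and `surface_texture` works).
#' @param rig A `stereo_rig`.
#' @param image_size `c(width, height)` in pixels.
#' @param noise_sd_gray Gaussian pixel noise standard deviation, gray levels
#'   out of 255.
#' @param seed RNG seed for the pixel noise.
#' @param background Background intensity in `[0, 1]`.
#' @return List with `left`, `right` (H x W matrices in `[0, 1]`),
#'   `depth_left`, `depth_right` (mm, `Inf` where no surface).
#' @export
render_stereo_pair <- function(scene, rig, image_size = c(256, 192),
                               noise_sd_gray = 0, seed = 1,
                               background = 0.05) {
  stopifnot(inherits(rig, "stereo_rig"))
  W <- as.integer(image_size[1]); H <- as.integer(image_size[2])
  V <- scene$surface_mesh$vertices
  F_ <- scene$surface_mesh$faces
  if (any(V[, 3] <= 0))
    stopf("%d scene vertex/vertices behind the left camera (z <= 0)",
          sum(V[, 3] <= 0))
  # lambertian shading under a headlight at the camera
  nrm <- vertex_normals(V, F_)
  shade <- 0.35 + 0.65 * abs(nrm[, 3])
  attr_left <- scene$surface_texture * shade

  left_r <- rasterize_mesh(V, F_, rig$left, W, H, vertex_attr = attr_left,
                           apply_distortion = !rig$rectified && any(rig$left$dist != 0))
  V_right <- sweep(V, 2, c(rig$baseline_mm, 0, 0)) %*% rig$rotation
  if (any(V_right[, 3] <= 0))
    stopf("%d scene vertex/vertices behind the right camera (z <= 0)",
          sum(V_right[, 3] <= 0))
  right_r <- rasterize_mesh(V_right, F_, rig$right, W, H, vertex_attr = attr_left,
                            apply_distortion = !rig$rectified && any(rig$right$dist != 0))

  compose <- function(rr) {
    img <- rr$attr
    img[!rr$mask] <- background
    img
  }
  left <- compose(left_r); right <- compose(right_r)
  if (noise_sd_gray > 0) {
    noise <- with_seed(seed, stats::rnorm(2 * H * W, sd = noise_sd_gray / 255))
    left <- pmin(pmax(left + matrix(noise[1:(H * W)], H, W), 0), 1)
    right <- pmin(pmax(right + matrix(noise[(H * W + 1):(2 * H * W)], H, W), 0), 1)
  }
  list(left = left, right = right,
       depth_left = left_r$depth, depth_right = right_r$depth)
}
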