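# Shared fixtures: a small rectified rig and a down-scaled phantom that keep
# the suite fast while exercising every code path.

tiny_rig <- function(width = 160, height = 120, fx = 280, baseline_mm = 5) {
  cam <- camera_params(fx = fx, fy = fx, cx = (width - 1) / 2,
                       cy = (height - 1) / 2, image_size = c(width, height))
  stereo_rig(cam, cam, baseline_mm = baseline_mm, rectified = TRUE,
             image_size = c(width, height))
}

tiny_phantom_config <- function(...) {
  phantom_config(grid_n = 56, curve_n = 96, ...)
}

# a fronto-parallel textured plane at depth z_mm filling the view
plane_scene <- function(z_mm = 100, half_extent = 30, grid_n = 64, seed = 42) {
  surf <- mitralAR:::grid_surface(c(-half_extent, half_extent),
                                  c(-half_extent, half_extent), grid_n,
                                  function(x, y) rep(z_mm, length(x)))
  tex <- mitralAR:::with_seed(seed, mitralAR:::procedural_texture(
    surf$vertices[, 1], surf$vertices[, 2],
    list(n_waves = 50, min_wavelength_mm = 2, max_wavelength_mm = 10)))
  list(surface_mesh = tri_mesh(surf$vertices, surf$faces),
       surface_texture = tex)
}

rotation_angle_deg <- function(R1, R2 = diag(3)) {
  tr <- sum(diag(crossprod(R1, R2)))
  acos(pmin(pmax((tr - 1) / 2, -1), 1)) * 180 / pi
}
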