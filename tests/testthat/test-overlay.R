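make_overlay_fixture <- function(seed = 12) {
  ph <- generate_phantom(tiny_phantom_config(landmark_noise_sd_mm = 0,
                                             preop_rotation = diag(3),
                                             preop_translation = c(0, 0, 0),
                                             scale = 1), seed = seed)
  rig <- tiny_rig()
  rend <- render_stereo_pair(ph$scene, rig, image_size = c(160, 120))
  list(ph = ph, rig = rig, rend = rend)
}

test_that("invisible structures leave the image bit-identical", {
  fx <- make_overlay_fixture()
  style <- overlay_style(list(annulus_ring = list(visible = FALSE)))
  out <- render_overlay(fx$rend$left, fx$ph$scene$structure_meshes["annulus_ring"],
                        fx$rig$left, style)
  expect_identical(out, mitralAR:::to_rgb_array(fx$rend$left))
})

test_that("opacity-1 fill paints the structure color exactly, and only inside", {
  fx <- make_overlay_fixture()
  style <- overlay_style(list(annulus_ring = list(color = c(0, 1, 0),
                                                  opacity = 1, mode = "fill")))
  ring <- fx$ph$scene$structure_meshes["annulus_ring"]
  out <- render_overlay(fx$rend$left, ring, fx$rig$left, style)
  rast <- mitralAR:::rasterize_mesh(ring[[1]]$vertices, ring[[1]]$faces,
                                    fx$rig$left, 160, 120)
  inside <- rast$mask
  expect_true(any(inside))
  expect_true(all(out[, , 1][inside] == 0))
  expect_true(all(out[, , 2][inside] == 1))
  # pixels outside the footprint are untouched
  orig <- mitralAR:::to_rgb_array(fx$rend$left)
  for (ch in 1:3)
    expect_identical(out[, , ch][!inside], orig[, , ch][!inside])
})

test_that("a perfectly registered annulus overlay traces the true annulus curve", {
  fx <- make_overlay_fixture()
  # preop == intraop here, so the registered annulus is the scene annulus
  # itself; a thin tube isolates alignment from the prosthesis width
  thin <- mitralAR:::tube_mesh(fx$ph$scene$annulus_curve, radius = 0.4,
                               n_around = 8, label = "annulus_ring",
                               closed = TRUE)
  style <- overlay_style(list(annulus_ring = list(color = c(1, 1, 0),
                                                  opacity = 1, mode = "fill")))
  out <- render_overlay(fx$rend$left, list(annulus_ring = thin),
                        fx$rig$left, style)
  painted <- which(out[, , 1] == 1 & out[, , 2] == 1 & out[, , 3] == 0,
                   arr.ind = TRUE)
  uv <- project_points(fx$ph$scene$annulus_curve, fx$rig$left,
                       apply_distortion = FALSE)
  # mean distance from painted pixels to the projected true curve < 2 px
  d <- vapply(seq_len(nrow(painted)), function(i) {
    min(sqrt((uv[, 1] - (painted[i, 2] - 1))^2 + (uv[, 2] - (painted[i, 1] - 1))^2))
  }, numeric(1))
  expect_lt(mean(d), 2)
})

test_that("wireframe and silhouette modes draw thin outlines", {
  fx <- make_overlay_fixture()
  for (mode in c("wireframe", "silhouette")) {
    style <- overlay_style(list(annulus_ring = list(color = c(1, 0, 0),
                                                    opacity = 1, mode = mode)))
    out <- render_overlay(fx$rend$left,
                          fx$ph$scene$structure_meshes["annulus_ring"],
                          fx$rig$left, style)
    changed <- out[, , 1] != mitralAR:::to_rgb_array(fx$rend$left)[, , 1]
    expect_gt(sum(changed), 0)
    # outlines cover less area than the filled footprint would
    rast <- mitralAR:::rasterize_mesh(
      fx$ph$scene$structure_meshes$annulus_ring$vertices,
      fx$ph$scene$structure_meshes$annulus_ring$faces, fx$rig$left, 160, 120)
    expect_lt(sum(changed), 1.5 * sum(rast$mask))
  }
})

test_that("structures entirely behind the camera are skipped with a warning", {
  fx <- make_overlay_fixture()
  behind <- fx$ph$scene$structure_meshes$annulus_ring
  behind$vertices[, 3] <- -behind$vertices[, 3]
  expect_warning(
    out <- render_overlay(fx$rend$left, list(annulus_ring = behind),
                          fx$rig$left, default_overlay_style()),
    "behind")
  expect_identical(out, mitralAR:::to_rgb_array(fx$rend$left))
})

test_that("ROI cropping and the style ROI restrict edits to the rectangle", {
  fx <- make_overlay_fixture()
  img <- fx$rend$left
  frame <- overlay_frame(mitralAR:::to_rgb_array(img), mitralAR:::to_rgb_array(img))
  whole <- crop_roi(frame, c(0, 0, 160, 120))
  expect_identical(whole$left, frame$left)
  crp <- crop_roi(frame, c(10, 20, 64, 48))
  expect_identical(dim(crp$left), c(48L, 64L, 3L))
  expect_identical(dim(crp$right), c(48L, 64L, 3L))
  expect_identical(crp$provenance$roi, c(10L, 20L, 64L, 48L))
  expect_error(crop_roi(frame, c(150, 0, 64, 48)), "out of bounds")

  # style ROI: pixels outside it never change even where structures project
  style <- overlay_style(list(annulus_ring = list(opacity = 1, mode = "fill")),
                         roi = c(0, 0, 80, 120))
  out <- render_overlay(img, fx$ph$scene$structure_meshes["annulus_ring"],
                        fx$rig$left, style)
  orig <- mitralAR:::to_rgb_array(img)
  expect_identical(out[, 81:160, ], orig[, 81:160, ])
})

test_that("stereo composites are lossless and geometrically consistent", {
  fx <- make_overlay_fixture()
  L <- mitralAR:::to_rgb_array(fx$rend$left)
  R <- mitralAR:::to_rgb_array(fx$rend$right)
  sbs <- stereo_composite(L, R, "side_by_side")
  expect_identical(dim(sbs), c(120L, 320L, 3L))
  back <- split_side_by_side(sbs)
  expect_identical(back$left, L)
  expect_identical(back$right, R)

  ana <- stereo_composite(L, L, "anaglyph")
  expect_equal(ana[, , 1], ana[, , 2])   # zero parallax: red equals cyan
  expect_error(stereo_composite(L, R[1:60, , ]), "equal size")

  # disparity of an overlay vertex between the eyes is f * B / z
  v <- fx$ph$scene$structure_meshes$annulus_ring$vertices[1, , drop = FALSE]
  ul <- unname(project_points(v, fx$rig$left)[1, 1])
  ur <- unname(project_points(v - rep(c(fx$rig$baseline_mm, 0, 0), each = 1),
                              fx$rig$right)[1, 1])
  expect_equal(ul - ur, fx$rig$left$fx * fx$rig$baseline_mm / v[1, 3],
               tolerance = 0.5)
})

test_that("overlay rendering is deterministic", {
  fx <- make_overlay_fixture()
  style <- default_overlay_style()
  o1 <- render_overlay(fx$rend$left, fx$ph$scene$structure_meshes,
                       fx$rig$left, style)
  o2 <- render_overlay(fx$rend$left, fx$ph$scene$structure_meshes,
                       fx$rig$left, style)
  expect_identical(o1, o2)
})
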