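test_that("identical images match at zero disparity; flat images match nowhere", {
  img <- mitralAR:::with_seed(1, matrix(stats::runif(120 * 160), 120, 160))
  disp <- compute_disparity(img, img, params = list(search_range = 32))
  expect_true(any(disp$valid))
  expect_true(all(disp$values[disp$valid] == 0))

  flat <- matrix(0.5, 120, 160)
  dflat <- compute_disparity(flat, flat, params = list(search_range = 32))
  expect_false(any(dflat$valid))
})

test_that("disparity parameters are validated", {
  img <- matrix(stats::runif(120 * 160), 120, 160)
  expect_error(compute_disparity(img, img, params = list(block_size = 8)), "odd")
  cam <- camera_params(280, 280, 80, 60)
  raw <- stereo_rig(cam, cam, baseline_mm = 5, rectified = FALSE)
  expect_error(compute_disparity(img, img, rig = raw), "rectified")
})

test_that("triangulation follows the closed-form stereo equations", {
  cam <- camera_params(1000, 1000, 80, 60)
  rig <- stereo_rig(cam, cam, baseline_mm = 5, rectified = TRUE)
  H <- 120; W <- 160
  vals <- matrix(50, H, W)
  valid <- matrix(TRUE, H, W)
  disp <- structure(list(values = vals, valid = valid, block_size = 9L,
                         search_range = 64L, params = list()),
                    class = "disparity_map")
  cloud <- disparity_to_cloud(disp, rig, filters = list(z_min = 1, z_max = 1000))
  # pixel at the principal point maps to (0, 0, fx * B / d) = (0, 0, 100)
  at_pp <- which(cloud$source_pixels[, 1] == rig$left$cx &
                 cloud$source_pixels[, 2] == rig$left$cy)
  expect_equal(unname(cloud$points[at_pp, ]), c(0, 0, 100), tolerance = 1e-12)
  # doubling the baseline doubles z exactly
  rig2 <- stereo_rig(cam, cam, baseline_mm = 10, rectified = TRUE)
  cloud2 <- disparity_to_cloud(disp, rig2, filters = list(z_min = 1, z_max = 1000))
  expect_equal(cloud2$points[, 3], 2 * cloud$points[, 3], tolerance = 1e-12)
})

test_that("phantom reconstruction is metrically faithful (noiseless)", {
  ph <- generate_phantom(tiny_phantom_config(), seed = 8)
  rig <- tiny_rig()
  rend <- render_stereo_pair(ph$scene, rig, image_size = c(160, 120))
  disp <- compute_disparity(rend$left, rend$right,
                            params = list(search_range = 32))
  ok <- disp$valid & is.finite(rend$depth_left)
  z <- rig$left$fx * rig$baseline_mm / disp$values[ok]
  expect_lt(stats::median(abs(z - rend$depth_left[ok])), 1)

  # epipolar consistency: reprojecting each cloud point into the right
  # camera lands at (u - d, v) within the consistency threshold
  cloud <- disparity_to_cloud(disp, rig, filters = list(z_min = 40, z_max = 160))
  pr <- sweep(cloud$points, 2, c(rig$baseline_mm, 0, 0))
  uv_r <- project_points(pr, rig$right, apply_distortion = FALSE)
  d_at <- disp$values[cbind(cloud$source_pixels[, 2] + 1,
                            cloud$source_pixels[, 1] + 1)]
  expect_lt(max(abs(uv_r[, 1] - (cloud$source_pixels[, 1] - d_at))), 1)
  expect_lt(max(abs(uv_r[, 2] - cloud$source_pixels[, 2])), 1e-9)
})

test_that("landmark spread in the reconstruction scales with the true scale", {
  # metric fidelity: reconstructed landmark max-pairwise distance tracks the
  # phantom's true intraop size linearly (slope 1 within 2% on noiseless data)
  rig <- tiny_rig()
  sizes <- c(0.85, 1.0)
  ratio <- vapply(sizes, function(f) {
    cfg <- tiny_phantom_config(semi_major_mm = 17.5 * f, semi_minor_mm = 13 * f,
                               landmark_noise_sd_mm = 0)
    ph <- generate_phantom(cfg, seed = 9)
    rend <- render_stereo_pair(ph$scene, rig, image_size = c(160, 120))
    disp <- compute_disparity(rend$left, rend$right,
                              params = list(search_range = 32))
    lm <- landmarks_from_disparity(ph$scene$annulus_landmarks, disp, rig)
    max(stats::dist(lm$points)) / max(stats::dist(ph$scene$annulus_landmarks$points))
  }, numeric(1))
  expect_true(all(abs(ratio - 1) < 0.02))
})

test_that("disparity validity is monotone in its gating parameters", {
  ph <- generate_phantom(tiny_phantom_config(), seed = 10)
  rig <- tiny_rig()
  rend <- render_stereo_pair(ph$scene, rig, image_size = c(160, 120),
                             noise_sd_gray = 2, seed = 10)
  loose <- compute_disparity(rend$left, rend$right,
                             params = list(search_range = 32,
                                           consistency_threshold = 2))
  tight <- compute_disparity(rend$left, rend$right,
                             params = list(search_range = 32,
                                           consistency_threshold = 0.5))
  expect_lte(sum(tight$valid), sum(loose$valid))

  disp <- loose
  n_narrow <- nrow(disparity_to_cloud(disp, rig,
                                      filters = list(z_min = 40, z_max = 100))$points)
  n_wide <- nrow(disparity_to_cloud(disp, rig,
                                    filters = list(z_min = 40, z_max = 160))$points)
  expect_gte(n_wide, n_narrow)
})

test_that("statistical outlier removal drops exactly the planted outlier", {
  # a uniform ring lattice: every point has an identical neighborhood, so a
  # sane multiplier removes nothing
  ang <- 2 * pi * (0:99) / 100
  g <- cbind(30 * cos(ang), 30 * sin(ang), 0)
  kept <- clean_cloud(point_cloud(g), k = 8, sd_multiplier = 3)
  expect_equal(nrow(kept$points), 100)

  with_out <- rbind(g, c(1000, 1000, 1000))
  cleaned <- clean_cloud(point_cloud(with_out), k = 8, sd_multiplier = 2)
  expect_equal(nrow(cleaned$points), 100)
  expect_true(all(cleaned$points[, 1] <= 30))

  # brute-force oracle: the implementation's kept set equals thresholding
  # mean-of-8-nearest distances computed directly from the distance matrix
  D <- as.matrix(stats::dist(with_out)); diag(D) <- Inf
  md <- apply(D, 1, function(r) mean(sort(r)[1:8]))
  keep_oracle <- md <= mean(md) + 2 * stats::sd(md)
  expect_equal(nrow(cleaned$points), sum(keep_oracle))

  expect_error(clean_cloud(point_cloud(with_out), k = 8, sd_multiplier = -10),
               "every point")
  expect_warning(small <- clean_cloud(point_cloud(g[1:5, ]), k = 8), "unchanged")
  expect_equal(nrow(small$points), 5)
})
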