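test_that("landmark similarity recovers constructed transforms exactly", {
  src <- matrix(stats::rnorm(24, sd = 15), 8, 3)
  # identity case
  fit0 <- landmark_similarity(src, src)
  expect_equal(fit0$scale, 1, tolerance = 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit0$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_lt(attr(fit0, "residual_rms_mm"), 1e-12)

  T1 <- similarity_transform(0.7, rot_z(30), c(1, 2, 3))
  fit <- landmark_similarity(src, apply_transform(T1, src))
  expect_equal(fit$scale, 0.7, tolerance = 1e-9)
  expect_equal(fit$rotation, rot_z(30), tolerance = 1e-9)
  expect_equal(fit$translation, c(1, 2, 3), tolerance = 1e-9)
})

test_that("landmark similarity is exact on noiseless pairs for any K and scale", {
  # property: random K in [4, 8], scales across [0.3, 1.5], arbitrary rotations
  for (trial in 1:25) {
    mitralAR:::with_seed(trial, {
      K <- sample(4:8, 1)
      s <- stats::runif(1, 0.3, 1.5)
      R <- mitralAR:::random_rotation(180)
      t_ <- stats::runif(3, -50, 50)
      src <- matrix(stats::rnorm(3 * K, sd = 12), K, 3)
      T_true <- similarity_transform(s, R, t_)
      fit <- landmark_similarity(src, apply_transform(T_true, src))
      expect_equal(fit$scale, s, tolerance = 1e-9)
      expect_lt(max(abs(fit$rotation - R)), 1e-9)
      expect_lt(attr(fit, "residual_rms_mm"), 1e-9)
    })
  }
})

test_that("scale recovery is robust to 0.5 mm landmark noise (Monte-Carlo)", {
  errs <- vapply(1:100, function(trial) {
    mitralAR:::with_seed(1000 + trial, {
      src <- matrix(stats::rnorm(24, sd = 12), 8, 3)
      T_true <- similarity_transform(stats::runif(1, 0.5, 1.2),
                                     mitralAR:::random_rotation(90),
                                     stats::runif(3, -20, 20))
      dst <- apply_transform(T_true, src) + matrix(stats::rnorm(24, sd = 0.5), 8, 3)
      abs(landmark_similarity(src, dst)$scale - T_true$scale)
    })
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("degenerate and mirrored configurations are handled", {
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(landmark_similarity(line, line * 2), "collinear")
  expect_error(landmark_similarity(matrix(0, 4, 3), matrix(0, 4, 3)), "coincident")
  expect_error(landmark_similarity(matrix(1, 2, 3), matrix(1, 2, 3)), "at least 3")

  # reflection guard: a mirrored target must still yield det(R) = +1
  src <- matrix(stats::rnorm(18, sd = 10), 6, 3)
  mirrored <- src %*% diag(c(-1, 1, 1))
  fit <- landmark_similarity(src, mirrored)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
})

test_that("SICP at the ground-truth fixed point stays put", {
  ph <- generate_phantom(tiny_phantom_config(landmark_noise_sd_mm = 0), seed = 1)
  tt <- ph$preop$true_transform
  src <- sample_mesh_points(ph$preop$structure_meshes$annulus_surface, 800, seed = 1)
  tgt <- apply_transform(tt, src)
  reg <- scale_adaptive_icp(src, tgt, init = tt, params = list(seed = 1))
  expect_true(reg$converged)
  expect_lte(reg$iterations, 2)
  expect_equal(reg$transform$scale, tt$scale, tolerance = 1e-6)
  expect_lt(max(abs(reg$transform$rotation - tt$rotation)), 1e-6)
  expect_lt(max(abs(reg$transform$translation - tt$translation)), 1e-6)
})

test_that("SICP refines a noisy landmark initialization to the true transform", {
  ph <- generate_phantom(tiny_phantom_config(landmark_noise_sd_mm = 1,
                                             scale = 0.72, n_landmarks = 4),
                         seed = 21)
  tt <- ph$preop$true_transform
  init <- landmark_similarity(ph$preop$annulus_landmarks,
                              ph$scene$annulus_landmarks)
  src <- sample_mesh_points(ph$preop$structure_meshes$annulus_surface, 1500, seed = 1)
  tgt <- sample_mesh_points(ph$scene$surface_mesh, 12000, seed = 2)
  reg <- scale_adaptive_icp(src, tgt, init = init,
                            params = list(seed = 1, target_band_mm = 6))
  expect_true(reg$converged)
  expect_lt(abs(reg$transform$scale - 0.72), 0.02)
  expect_lt(rotation_angle_deg(reg$transform$rotation, tt$rotation), 1)
  expect_lt(sqrt(sum((reg$transform$translation - tt$translation)^2)), 1)
  # objective monotonicity on the surviving-pair RMS
  expect_true(all(diff(reg$rms_trace) <= 1e-9))
})

test_that("clamping the scale to 1 degenerates SICP to exact rigid ICP", {
  mitralAR:::with_seed(5, {
    src <- matrix(stats::rnorm(900, sd = 10), 300, 3)
    Tr <- similarity_transform(1, mitralAR:::random_rotation(20), c(3, -2, 5))
    tgt <- apply_transform(Tr, src)
    reg <- scale_adaptive_icp(src, tgt, init = st_identity(),
                              params = list(scale_bounds = c(1, 1),
                                            reject_distance = 50, seed = 1))
    expect_identical(reg$transform$scale, 1)
    expect_lt(max(abs(reg$transform$rotation - Tr$rotation)), 1e-6)
    expect_lt(max(abs(reg$transform$translation - Tr$translation)), 1e-6)
  })
})

test_that("SICP reports divergence when every correspondence is rejected", {
  src <- matrix(stats::rnorm(90), 30, 3)
  tgt <- src + 1000
  expect_error(scale_adaptive_icp(src, tgt, params = list(reject_distance = 10)),
               "iteration 1")
  expect_error(scale_adaptive_icp(src[0, , drop = FALSE], tgt), "nonempty")
})

test_that("a grossly wrong initialization may converge to a symmetric alias", {
  # the annulus is nearly 180-degree rotationally symmetric about its normal:
  # starting > 60 degrees off, convergence to the true pose is NOT guaranteed.
  # This documents the basin limit rather than hiding it.
  ph <- generate_phantom(tiny_phantom_config(landmark_noise_sd_mm = 0,
                                             preop_rotation = diag(3),
                                             preop_translation = c(0, 0, 0),
                                             scale = 1), seed = 31)
  src <- sample_mesh_points(ph$preop$structure_meshes$annulus_surface, 1000, seed = 1)
  tgt <- sample_mesh_points(ph$scene$surface_mesh, 8000, seed = 2)
  center <- colMeans(ph$scene$annulus_curve)
  flip <- rot_z(180)
  bad_init <- similarity_transform(1, flip,
                                   as.numeric(center - flip %*% center))
  reg <- scale_adaptive_icp(src, tgt, init = bad_init,
                            params = list(seed = 1, reject_distance = 20))
  expect_true(reg$converged)
  expect_gt(rotation_angle_deg(reg$transform$rotation, diag(3)), 60)
})

test_that("nearest-neighbor queries agree with the brute-force oracle", {
  mitralAR:::with_seed(8, {
    ref <- matrix(stats::runif(600, 0, 50), 200, 3)
    q <- matrix(stats::runif(150, 0, 50), 50, 3)
    got <- mitralAR:::nn1(q, ref)
    D <- outer(rowSums(q^2), rep(1, 200)) + outer(rep(1, 50), rowSums(ref^2)) -
      2 * q %*% t(ref)
    expect_identical(got$index, apply(D, 1, which.min))
    expect_equal(got$dist, sqrt(apply(D, 1, min)), tolerance = 1e-9)
  })
})
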