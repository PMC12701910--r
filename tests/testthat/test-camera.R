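test_that("projection follows the pinhole model", {
  cam <- camera_params(fx = 1000, fy = 900, cx = 320, cy = 240)
  # optical axis maps to the principal point regardless of focal length
  expect_equal(unname(project_points(c(0, 0, 100), cam)), matrix(c(320, 240), 1, 2))
  # u = fx * x / z + cx
  expect_equal(unname(project_points(c(10, 0, 100), cam)[1, "u"]), 420)
  expect_error(project_points(c(0, 0, -5), cam), "behind")
})

test_that("Brown-Conrady radial distortion applies the documented polynomial", {
  # normalized radius 0.1 with k1 = 0.1: radial factor 1 + 0.1 * 0.01 = 1.001
  nd <- mitralAR:::distort_normalized(0.1, 0, c(0.1, 0, 0, 0, 0))
  expect_equal(nd[1, 1], 0.1 * 1.001, tolerance = 1e-15)
  cam <- camera_params(1000, 1000, 320, 240, dist = c(0.1, 0, 0, 0, 0))
  px <- project_points(c(10, 0, 100), cam, apply_distortion = TRUE)
  expect_equal(unname(px[1, "u"]), 320 + 1000 * 0.1 * 1.001, tolerance = 1e-12)
})

test_that("project / undistort / backproject recovers 3D points", {
  pts <- cbind(stats::runif(50, -20, 20), stats::runif(50, -15, 15),
               stats::runif(50, 60, 140))
  cam0 <- camera_params(800, 780, 127.5, 95.5)
  px <- project_points(pts, cam0, apply_distortion = FALSE)
  back <- backproject_pixels(px, pts[, 3], cam0)
  expect_lt(max(abs(back - pts)), 1e-6)

  camd <- camera_params(800, 780, 127.5, 95.5,
                        dist = c(-0.2, 0.05, 1e-3, -5e-4, 0.01))
  pxd <- project_points(pts, camd, apply_distortion = TRUE)
  backd <- backproject_pixels(pxd, pts[, 3], camd)
  expect_lt(max(abs(backd - pts)), 1e-3)
})

test_that("reprojection error matches its definition and closed forms", {
  cam <- camera_params(700, 700, 80, 60)
  pts <- cbind(stats::runif(100, -10, 10), stats::runif(100, -8, 8),
               stats::runif(100, 50, 120))
  obs <- project_points(pts, cam)
  expect_equal(reprojection_error(obs, pts, cam), 0)
  # uniform 1 px offset in u gives exactly 1 px mean error
  expect_equal(reprojection_error(sweep(obs, 2, c(1, 0), "+"), pts, cam), 1)
  expect_error(reprojection_error(obs[0, ], pts[0, ], cam), "at least one")

  # isotropic Gaussian pixel noise sd sigma -> Rayleigh mean sigma * sqrt(pi/2)
  sigma <- 1.0
  n <- 1e4
  pts_mc <- cbind(stats::runif(n, -10, 10), stats::runif(n, -8, 8),
                  stats::runif(n, 50, 120))
  obs_mc <- project_points(pts_mc, cam)
  noisy <- mitralAR:::with_seed(99, obs_mc + matrix(stats::rnorm(2 * n, sd = sigma), n, 2))
  expect_equal(reprojection_error(noisy, pts_mc, cam), sigma * sqrt(pi / 2),
               tolerance = 0.03)
})

test_that("reprojection error is invariant under a common rigid motion", {
  cam <- camera_params(700, 700, 80, 60)
  pts <- cbind(stats::runif(40, -10, 10), stats::runif(40, -8, 8),
               stats::runif(40, 50, 120))
  obs <- project_points(pts, cam) + matrix(stats::rnorm(80, sd = 0.5), 40, 2)
  e0 <- reprojection_error(obs, pts, cam)
  # move the world and compensate with the pose
  Rm <- rot_y(20) %*% rot_x(-10); tm <- c(4, -2, 7)
  moved <- sweep(pts %*% t(Rm), 2, tm, "+")
  e1 <- reprojection_error(obs, moved, cam,
                           rotation = t(Rm), translation = -as.numeric(t(Rm) %*% tm))
  expect_equal(e1, e0, tolerance = 1e-9)
})

test_that("camera and rig validation rejects bad parameters", {
  expect_error(camera_params(-1, 1, 0, 0), "positive")
  expect_error(camera_params(800, 800, 5000, 10, image_size = c(640, 480)),
               "principal point")
  cam <- camera_params(800, 800, 320, 240)
  expect_error(stereo_rig(cam, cam, baseline_mm = 0), "baseline")
  expect_error(stereo_rig(cam, cam, rotation = rot_y(5), baseline_mm = 5,
                          rectified = TRUE), "identity")
  cam2 <- camera_params(750, 800, 320, 240)
  expect_error(stereo_rig(cam, cam2, baseline_mm = 5, rectified = TRUE), "share")
})

test_that("calibration files round-trip through the documented schema", {
  left <- camera_params(810, 805, 321, 239, dist = c(-0.1, 0.02, 0, 0, 0))
  right <- camera_params(812, 807, 318, 241, dist = c(-0.12, 0.025, 0, 0, 0))
  rig <- stereo_rig(left, right, rotation = rot_y(1.5), baseline_mm = 5.2,
                    image_size = c(640, 480))
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_calibration(rig, path)
    back <- read_calibration(path)
    expect_equal(back$left$fx, 810)
    expect_equal(back$right$dist, right$dist, tolerance = 1e-12)
    expect_equal(back$rotation, rig$rotation, tolerance = 1e-12)
    expect_equal(back$baseline_mm, 5.2)
    expect_false(back$rectified)
  }
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(left = list(fx = 1)), bad)
  expect_error(read_calibration(bad), "missing required key")
})
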