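#' Validate a pipeline configuration
#'
#' Schema checks performed before any computation: required paths exist,
#' the landmark files parse and contain 4 to 8 corresponding landmarks,
#' numeric parameters are in range, and a seed is present.
#'
#' @param config Named list (or path to a YAML file).
#' @return The normalized config list, invisibly on success; errors name
#'   the offending field.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    base <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    # resolve relative paths against the config file location
    for (key in c("calibration", "left_image", "right_image",
                  "preop_landmarks", "intraop_landmarks", "output_dir")) {
      if (!is.null(config$paths[[key]]) && !grepl("^/", config$paths[[key]]))
        config$paths[[key]] <- file.path(base, config$paths[[key]])
    }
    if (!is.null(config$paths$preop_meshes))
      config$paths$preop_meshes <- lapply(config$paths$preop_meshes, function(p)
        if (grepl("^/", p)) p else file.path(base, p))
  }
  if (is.null(config$paths)) stopf("config missing 'paths' section")
  req <- c("calibration", "left_image", "right_image",
           "preop_landmarks", "intraop_landmarks", "output_dir")
  for (key in req)
    if (is.null(config$paths[[key]])) stopf("config missing required path '%s'", key)
  for (key in setdiff(req, "output_dir"))
    if (!file.exists(config$paths[[key]]))
      stopf("config path '%s' does not exist: %s", key, config$paths[[key]])
  if (is.null(config$paths$preop_meshes) || length(config$paths$preop_meshes) == 0)
    stopf("config missing 'paths$preop_meshes' (named list of structure mesh files)")
  for (p in config$paths$preop_meshes)
    if (!file.exists(p)) stopf("preop mesh file does not exist: %s", p)
  if (is.null(config$seed)) stopf("config missing 'seed'")
  pre_lm <- read_landmarks_csv(config$paths$preop_landmarks)
  if (inherits(pre_lm, "landmark_set")) {
    K <- nrow(pre_lm$points)
    if (K < 4 || K > 8)
      stopf("preop landmark file has %d landmarks; registration uses 4 to 8 key points", K)
  }
  config$stereo <- utils::modifyList(
    list(block_size = 9L, search_range = 64L, consistency_threshold = 1,
         texture_threshold = 1e-4, z_min = 20, z_max = 300, min_disparity = 0.5),
    config$stereo %||% list())
  config$icp <- utils::modifyList(
    list(max_iterations = 100L, rms_tol = 1e-4, reject_distance = 10,
         scale_bounds = c(0.3, 1.5), subsample_source = 2000L,
         subsample_target = 8000L, target_band_mm = 5,
         points = "landmarks", structure = "annulus_ring"),
    config$icp %||% list())
  if (!config$icp$points %in% c("dense", "landmarks"))
    stopf("icp$points must be 'dense' or 'landmarks'")
  config$clean <- utils::modifyList(list(enabled = TRUE, k = 8L, sd_multiplier = 2,
                                         max_points = 15000L),
                                    config$clean %||% list())
  config$diameter_mode <- config$diameter_mode %||% "max_pairwise"
  if (!config$diameter_mode %in% c("max_pairwise", "intercommissural"))
    stopf("diameter_mode must be 'max_pairwise' or 'intercommissural'")
  config$ring_size_mm <- config$ring_size_mm %||% NA_real_
  invisible(config)
}

#' Run the full overlay pipeline for one case
#'
#' Executes the stepwise workflow — rectification, disparity, triangulation
#' to a metric cloud, outlier cleaning, landmark-initialized scale-adaptive
#' ICP, validation metrics and stereo overlay rendering — writing every
#' intermediate artifact plus a run manifest into the configured output
#' directory. Any stage failure aborts with an error naming the stage after
#' writing a partial manifest. Runs are hermetic (only files named in the
#' config are read) and reproducible: the manifest records an MD5 hash of
#' every output.
#'
#' @param config Config list or YAML path (see [validate_pipeline_config()]).
#' @return The run manifest, invisibly.
#' @export
run_case <- function(config) {
  config <- validate_pipeline_config(config)
  out_dir <- config$paths$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config,
                   version = as.character(utils::packageVersion("mitralAR")),
                   stages = list(), outputs = list(), warnings = character(0))
  env <- new.env()

  finish <- function() {
    files <- list.files(out_dir, full.names = TRUE, recursive = TRUE)
    files <- files[!grepl("manifest\\.json$", files)]
    manifest$outputs <- lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE, null = "null")
    manifest
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "error", message = conditionMessage(e))
      finish()
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$stages[[name]] <<- list(status = "ok",
                                     seconds = proc.time()[["elapsed"]] - t0)
    res
  }

  stage("load_inputs", {
    env$rig <- read_calibration(config$paths$calibration)
    env$left <- to_luminance(read_image_png(config$paths$left_image))
    env$right <- to_luminance(read_image_png(config$paths$right_image))
    env$preop_lm <- read_landmarks_csv(config$paths$preop_landmarks)
    intraop <- read_landmarks_csv(config$paths$intraop_landmarks)
    env$meshes <- lapply(config$paths$preop_meshes, read_ply_mesh)
    names(env$meshes) <- names(config$paths$preop_meshes)
    env$intraop_raw <- intraop
  })
  stage("rectify", {
    if (!env$rig$rectified) {
      rp <- rectify_pair(env$left, env$right, env$rig)
      env$left <- rp$left; env$right <- rp$right; env$rig <- rp$rig
      write_image_png(env$left, file.path(out_dir, "rectified_left.png"))
      write_image_png(env$right, file.path(out_dir, "rectified_right.png"))
    }
    if (inherits(env$intraop_raw, "landmark_pixel_pairs"))
      env$intraop_lm <- triangulate_pixel_pairs(env$intraop_raw, env$rig)
    else env$intraop_lm <- env$intraop_raw
    K <- nrow(env$intraop_lm$points)
    if (K < 4 || K > 8)
      stopf("intraop landmark set has %d landmarks; registration uses 4 to 8 key points", K)
  })
  stage("disparity", {
    env$disp <- compute_disparity(env$left, env$right,
                                  params = config$stereo, rig = env$rig)
    write_disparity_png(env$disp, file.path(out_dir, "disparity.png"))
  })
  stage("cloud", {
    cloud <- disparity_to_cloud(env$disp, env$rig,
                                filters = config$stereo[c("z_min", "z_max", "min_disparity")],
                                left_image = env$left)
    # uniform seeded downsampling keeps the outlier statistics tractable
    if (!is.null(config$clean$max_points) &&
        nrow(cloud$points) > config$clean$max_points) {
      keep <- with_seed(config$seed,
                        sort(sample.int(nrow(cloud$points), config$clean$max_points)))
      cloud <- point_cloud(cloud$points[keep, , drop = FALSE],
                           colors = cloud$colors[keep, , drop = FALSE],
                           source_pixels = cloud$source_pixels[keep, , drop = FALSE])
    }
    if (isTRUE(config$clean$enabled) && nrow(cloud$points) > config$clean$k)
      cloud <- clean_cloud(cloud, k = config$clean$k,
                           sd_multiplier = config$clean$sd_multiplier)
    if (nrow(cloud$points) == 0) stopf("empty point cloud after filtering")
    env$cloud <- cloud
    write_ply_cloud(cloud, file.path(out_dir, "cloud.ply"))
  })
  stage("register", {
    init <- landmark_similarity(env$preop_lm, env$intraop_lm)
    icp_par <- config$icp
    icp_par$seed <- config$seed
    if (icp_par$points == "landmarks") {
      src <- env$preop_lm$points; tgt <- env$intraop_lm$points
    } else {
      src_mesh <- env$meshes[[icp_par$structure]] %||% env$meshes[[1]]
      src <- sample_mesh_points(src_mesh, icp_par$subsample_source,
                                seed = config$seed)
      tgt <- env$cloud
    }
    keep <- setdiff(names(icp_par), c("points", "structure"))
    env$reg <- scale_adaptive_icp(src, tgt, init = init, params = icp_par[keep])
    write_transform_json(env$reg$transform, file.path(out_dir, "transform.json"))
    write_registration_report(env$reg, file.path(out_dir, "registration.json"))
  })
  stage("validate", {
    env$report <- build_validation_report(
      env$reg$transform, env$preop_lm, env$intraop_lm,
      ring_size_mm = config$ring_size_mm,
      diameter_mode = config$diameter_mode)
    write_validation_report(env$report,
                            json_path = file.path(out_dir, "validation.json"),
                            csv_path = file.path(out_dir, "validation.csv"))
  })
  stage("overlay", {
    registered <- lapply(env$meshes, function(m) apply_transform(env$reg$transform, m))
    style <- if (is.null(config$style)) default_overlay_style()
             else overlay_style(config$style$structures %||% config$style,
                                roi = config$style$roi)
    left_c <- render_overlay(env$left, registered, env$rig$left, style)
    to_right <- function(m) {
      m$vertices <- sweep(m$vertices, 2, c(env$rig$baseline_mm, 0, 0)) %*% env$rig$rotation
      m
    }
    right_c <- render_overlay(env$right, lapply(registered, to_right),
                              env$rig$right, style)
    env$frame <- overlay_frame(left_c, right_c, transform = env$reg$transform,
                               style = style, frame_id = basename(config$paths$left_image))
    write_image_png(left_c, file.path(out_dir, "overlay_left.png"))
    write_image_png(right_c, file.path(out_dir, "overlay_right.png"))
    write_image_png(stereo_composite(left_c, right_c, "side_by_side"),
                    file.path(out_dir, "overlay_stereo.png"))
  })
  manifest$result <- list(
    converged = env$reg$converged,
    iterations = env$reg$iterations,
    final_rms_mm = env$reg$final_rms_mm,
    lre_mm = env$report$lre_mm,
    scaling_factor = env$report$scaling_factor,
    intraop_diameter_mm = env$report$intraop_diameter_mm,
    diameter_error_mm = env$report$diameter_error_mm)
  manifest <- finish()
  invisible(manifest)
}

#' Generate a complete runnable demo case
#'
#' One call writes a fully ground-truthed phantom case into a directory:
#' stereo calibration YAML, rendered left/right PNG frames, preoperative
#' structure meshes (PLY), preoperative and intraoperative landmark CSVs,
#' ground-truth transform JSON, and a `config.yaml` that [run_case()] can
#' execute end to end. The annuloplasty ring size is set to the phantom's
#' true intraoperative diameter rounded to the nearest even millimeter,
#' mirroring how ring sizes are labeled.
#'
#' @param dir Output directory (created if needed).
#' @param seed RNG seed controlling the whole case.
#' @param phantom Phantom parameters from [phantom_config()].
#' @param image_size `c(width, height)` of the rendered frames.
#' @param noise_sd_gray Pixel noise in gray levels (out of 255).
#' @return Path to the written `config.yaml`, invisibly.
#' @export
make_demo <- function(dir, seed = 1, phantom = phantom_config(seed = seed),
                      image_size = c(256, 192), noise_sd_gray = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(dir, 2) != 0) stopf("output directory not writable: %s", dir)
  phantom$seed <- seed
  ph <- generate_phantom(phantom, seed = seed)
  W <- image_size[1]; H <- image_size[2]
  # wide-angle endoscope-like geometry: the whole annulus must fit the view
  cam <- camera_params(fx = 450, fy = 450, cx = (W - 1) / 2, cy = (H - 1) / 2,
                       image_size = image_size)
  rig <- stereo_rig(cam, cam, baseline_mm = 5, rectified = TRUE,
                    image_size = image_size)
  rend <- render_stereo_pair(ph$scene, rig, image_size = image_size,
                             noise_sd_gray = noise_sd_gray, seed = seed)
  write_calibration(rig, file.path(dir, "calibration.yaml"))
  write_image_png(rend$left, file.path(dir, "left.png"))
  write_image_png(rend$right, file.path(dir, "right.png"))
  mesh_paths <- list()
  for (nm in names(ph$preop$structure_meshes)) {
    p <- file.path(dir, paste0("preop_", nm, ".ply"))
    write_ply_mesh(ph$preop$structure_meshes[[nm]], p)
    mesh_paths[[nm]] <- basename(p)
  }
  write_landmarks_csv(ph$preop$annulus_landmarks, file.path(dir, "preop_landmarks.csv"))
  write_landmarks_csv(ph$scene$annulus_landmarks, file.path(dir, "intraop_landmarks.csv"))
  write_transform_json(ph$preop$true_transform, file.path(dir, "true_transform.json"))
  ring <- 2 * round(ph$scene$true_intraop_diameter_mm / 2)
  zc <- phantom$center_mm[3]
  config <- list(
    paths = list(calibration = "calibration.yaml",
                 left_image = "left.png", right_image = "right.png",
                 preop_meshes = mesh_paths,
                 preop_landmarks = "preop_landmarks.csv",
                 intraop_landmarks = "intraop_landmarks.csv",
                 output_dir = "output"),
    stereo = list(block_size = 9L,
                  search_range = as.integer(ceiling(cam$fx * rig$baseline_mm /
                                                      (zc * 0.6))),
                  z_min = round(zc * 0.5), z_max = round(zc * 1.8)),
    icp = list(points = "landmarks", structure = "annulus_ring"),
    diameter_mode = "max_pairwise",
    ring_size_mm = ring,
    seed = seed)
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  invisible(cfg_path)
}
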