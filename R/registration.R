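# Closed-form least-squares similarity fit (Umeyama-style):
# minimizes sum_i || s R x_i + t - y_i ||^2 over scale, rotation, translation.
# Centroid alignment, SVD of the cross-covariance with a reflection guard on
# the smallest singular value, scale from the trace ratio; the scale may be
# clamped to `scale_bounds` (translation is recomputed with the clamped
# scale). Degenerate (collinear) configurations are rejected.
umeyama_fit <- function(src, dst, scale_bounds = NULL, with_scale = TRUE) {
  X <- as_points_matrix(src, "src"); Y <- as_points_matrix(dst, "dst")
  K <- nrow(X)
  if (nrow(Y) != K) stopf("source (%d) and destination (%d) point counts differ", K, nrow(Y))
  if (K < 3L) stopf("at least 3 corresponding points are required (got %d)", K)
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  sigma2 <- mean(rowSums(Xc^2))
  if (sigma2 < 1e-18) stopf("degenerate configuration: source points are coincident")
  Sxy <- crossprod(Yc, Xc) / K
  sv <- svd(Sxy)
  # collinearity check: rank < 2 leaves the rotation under-determined
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-18))
    stopf("degenerate configuration: points are (near-)collinear, rotation is under-determined")
  S <- diag(3)
  if (det(sv$u) * det(sv$v) < 0) S[3, 3] <- -1
  R <- sv$u %*% S %*% t(sv$v)
  s <- if (with_scale) sum(sv$d * diag(S)) / sigma2 else 1
  if (!is.null(scale_bounds))
    s <- min(max(s, scale_bounds[1]), scale_bounds[2])
  t_ <- my - s * as.numeric(R %*% mx)
  fit <- similarity_transform(s, R, t_)
  resid <- apply_transform(fit, X) - Y
  attr(fit, "residual_rms_mm") <- sqrt(mean(rowSums(resid^2)))
  fit
}

#' Closed-form similarity transform from ordered landmark pairs
#'
#' Initial registration: the least-squares similarity transform (scale,
#' rotation, translation) mapping the source landmark set onto the
#' destination set, with correspondence by index. Solved in closed form by
#' centroid alignment and SVD of the cross-covariance matrix, with a
#' reflection guard so the rotation always has determinant +1; the scale is
#' the trace ratio. The residual RMS (mm) is attached as attribute
#' `residual_rms_mm`.
#'
#' @param src,dst `landmark_set`s (or K x 3 matrices) with equal K >= 3 and
#'   index correspondence; typically the 4-8 annulus landmark picks.
#' @return A `similarity_transform` with attribute `residual_rms_mm`.
#' @export
landmark_similarity <- function(src, dst) {
  sp <- if (inherits(src, "landmark_set")) src$points else src
  dp <- if (inherits(dst, "landmark_set")) dst$points else dst
  if (inherits(src, "landmark_set") && inherits(dst, "landmark_set") &&
      nrow(sp) == nrow(dp) && !identical(src$names, dst$names))
    warnf("landmark names differ between sets; correspondence is by index")
  umeyama_fit(sp, dp)
}

#' Uniform-by-area surface sampling of a triangle mesh
#'
#' @param mesh A `tri_mesh`.
#' @param n Number of samples.
#' @param seed RNG seed.
#' @return N x 3 matrix of surface points.
#' @export
sample_mesh_points <- function(mesh, n, seed = 1) {
  stopifnot(inherits(mesh, "tri_mesh"))
  V <- mesh$vertices; F_ <- mesh$faces
  a <- V[F_[, 1], , drop = FALSE]
  b <- V[F_[, 2], , drop = FALSE]
  c_ <- V[F_[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- 0.5 * sqrt(rowSums(cr^2))
  with_seed(seed, {
    fi <- sample.int(nrow(F_), n, replace = TRUE, prob = area)
    r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
    w1 <- 1 - r1; w2 <- r1 * (1 - r2); w3 <- r1 * r2
    w1 * a[fi, , drop = FALSE] + w2 * b[fi, , drop = FALSE] + w3 * c_[fi, , drop = FALSE]
  })
}

#' Scale-adaptive iterative closest point registration
#'
#' Refines an initial similarity transform by alternating (1) transforming
#' the source cloud by the current estimate, (2) nearest-neighbor
#' correspondence into the target, (3) rejection of pairs farther apart
#' than `reject_distance`, (4) a closed-form similarity re-fit (as in
#' [landmark_similarity]) on the surviving pairs, with the scale clamped to
#' `scale_bounds`, until the RMS change falls below `rms_tol` or
#' `max_iterations` is reached. Setting `scale_bounds = c(1, 1)` degenerates
#' to classic rigid ICP. The seed governs the optional subsampling only;
#' everything else is deterministic.
#'
#' @param source Preoperative model surface samples (`point_cloud` or
#'   N x 3 matrix).
#' @param target Intraoperative reconstruction (`point_cloud` or matrix).
#' @param init Initial `similarity_transform` (e.g. from
#'   [landmark_similarity]); identity by default.
#' @param params List overriding any of: `max_iterations` (100), `rms_tol`
#'   (1e-4 mm), `reject_distance` (10 mm), `scale_bounds` (`c(0.3, 1.5)`),
#'   `subsample_source` (2000), `subsample_target` (8000), `target_band_mm`
#'   (`NULL`), `seed` (1). When `target_band_mm` is set, the target is first
#'   restricted to points within that distance of the init-transformed
#'   source — the annulus-region gating that keeps a thin model structure
#'   from collapsing onto a dense whole-scene cloud.
#' @return An object of class `registration_result`: `transform`,
#'   `iterations`, `converged`, `final_rms_mm`, `rms_trace`,
#'   `correspondence_count`.
#' @export
scale_adaptive_icp <- function(source, target, init = st_identity(),
                               params = list()) {
  p <- utils::modifyList(list(max_iterations = 100L, rms_tol = 1e-4,
                              reject_distance = 10, scale_bounds = c(0.3, 1.5),
                              subsample_source = 2000L, subsample_target = 8000L,
                              target_band_mm = NULL, seed = 1L),
                         params, keep.null = TRUE)
  src <- as_cloud_matrix(source, "source")
  tgt <- as_cloud_matrix(target, "target")
  if (nrow(src) == 0L || nrow(tgt) == 0L)
    stopf("scale_adaptive_icp requires nonempty source and target clouds")
  stopifnot(inherits(init, "similarity_transform"))
  sb <- p$scale_bounds
  if (length(sb) != 2L || sb[1] <= 0 || sb[2] < sb[1])
    stopf("scale_bounds must be an increasing positive pair")
  if (!is.null(p$subsample_source) && nrow(src) > p$subsample_source)
    src <- with_seed(p$seed, src[sample.int(nrow(src), p$subsample_source), , drop = FALSE])
  if (!is.null(p$target_band_mm)) {
    band <- nn1(tgt, apply_transform(init, src))
    tgt <- tgt[band$dist <= p$target_band_mm, , drop = FALSE]
    if (nrow(tgt) == 0L)
      stopf("no target points within target_band_mm = %s of the initial alignment",
            format(p$target_band_mm))
  }
  if (!is.null(p$subsample_target) && nrow(tgt) > p$subsample_target)
    tgt <- with_seed(p$seed + 1L, tgt[sample.int(nrow(tgt), p$subsample_target), , drop = FALSE])

  est <- init
  rms_trace <- numeric(0)
  n_corr <- integer(0)
  converged <- FALSE
  iter <- 0L
  rms_prev <- Inf
  while (iter < p$max_iterations) {
    iter <- iter + 1L
    moved <- apply_transform(est, src)
    nn <- nn1(moved, tgt)
    surv <- nn$dist <= p$reject_distance
    if (!any(surv))
      stopf("scale_adaptive_icp diverged: all correspondences rejected at iteration %d (reject_distance = %s mm)",
            iter, format(p$reject_distance))
    est <- umeyama_fit(src[surv, , drop = FALSE],
                       tgt[nn$index[surv], , drop = FALSE],
                       scale_bounds = sb)
    rms <- attr(est, "residual_rms_mm")
    rms_trace <- c(rms_trace, rms)
    n_corr <- c(n_corr, sum(surv))
    if (abs(rms_prev - rms) < p$rms_tol) { converged <- TRUE; break }
    rms_prev <- rms
  }
  structure(list(transform = est, iterations = iter, converged = converged,
                 final_rms_mm = rms_trace[length(rms_trace)],
                 rms_trace = rms_trace, correspondence_count = n_corr,
                 params = p),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> %s after %d iteration(s), RMS %.4f mm, scale %.4f\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$final_rms_mm, x$transform$scale))
  invisible(x)
}

#' Serialize a registration result report
#'
#' Writes iterations, convergence flag, the RMS trace, correspondence
#' counts and the final transform as JSON.
#'
#' @param result A `registration_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_registration_report <- function(result, path) {
  stopifnot(inherits(result, "registration_result"))
  obj <- list(iterations = result$iterations, converged = result$converged,
              final_rms_mm = result$final_rms_mm,
              rms_trace = result$rms_trace,
              correspondence_count = result$correspondence_count,
              transform = list(scale = result$transform$scale,
                               rotation = as.numeric(t(result$transform$rotation)),
                               translation_mm = result$transform$translation))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
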