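#' Landmark registration error (root-mean-square distance)
#'
#' The registration quality metric: the root of the mean squared Euclidean
#' distance between corresponding landmarks of the registered preoperative
#' set and the intraoperative set, in mm. Correspondence is by index.
#'
#' @param preop Registered preoperative landmarks (`landmark_set` or
#'   K x 3 matrix, already transformed into the intraoperative frame).
#' @param intraop Intraoperative landmarks (`landmark_set` or K x 3 matrix).
#' @return RMS distance in mm (scalar, >= 0).
#' @export
landmark_registration_error <- function(preop, intraop) {
  p <- if (inherits(preop, "landmark_set")) preop$points else as_points_matrix(preop, "preop")
  q <- if (inherits(intraop, "landmark_set")) intraop$points else as_points_matrix(intraop, "intraop")
  if (nrow(p) != nrow(q))
    stopf("landmark correspondence requires equal counts (got %d and %d)",
          nrow(p), nrow(q))
  sqrt(mean(rowSums((p - q)^2)))
}

#' Annulus diameter measurement
#'
#' The paper-style validation measurement on the reconstructed annulus. Two
#' definitions are exposed: the maximum pairwise Euclidean distance among
#' the annulus points (default), and the intercommissural distance between
#' the two commissure landmarks (by convention landmarks 1 and 2).
#'
#' @param annulus_points Ordered annulus points (`landmark_set` or N x 3
#'   matrix, mm); at least 3 points.
#' @param mode `"max_pairwise"` or `"intercommissural"`.
#' @param commissure_idx Indices of the two commissure points (default 1:2).
#' @return Diameter in mm.
#' @export
annulus_diameter <- function(annulus_points,
                             mode = c("max_pairwise", "intercommissural"),
                             commissure_idx = c(1L, 2L)) {
  mode <- match.arg(mode)
  pts <- if (inherits(annulus_points, "landmark_set")) annulus_points$points
         else as_points_matrix(annulus_points, "annulus_points")
  if (nrow(pts) < 3L)
    stopf("annulus diameter needs at least 3 points (got %d)", nrow(pts))
  if (mode == "max_pairwise") {
    max(stats::dist(pts))
  } else {
    sqrt(sum((pts[commissure_idx[1], ] - pts[commissure_idx[2], ])^2))
  }
}

#' Median and interquartile range by the (n+1)-position rule
#'
#' Median is the middle order statistic (mean of the two middles for even
#' n). Quartiles interpolate linearly at positions `(n+1)/4` and
#' `3(n+1)/4` among the order statistics (equivalently
#' `stats::quantile(type = 6)`), the rule under which the cohort's printed
#' interquartile ranges are recovered from the per-case values.
#'
#' @param values Numeric vector, `n >= 1`.
#' @return List with `median`, `q1`, `q3`.
#' @export
summary_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L || any(!is.finite(values)))
    stopf("summary_stats requires at least one finite value")
  q <- stats::quantile(values, probs = c(0.25, 0.75), type = 6, names = FALSE)
  list(median = stats::median(values), q1 = q[1], q3 = q[2])
}

#' Per-case validation report
#'
#' Aggregates the quantitative validation of one registered case: the
#' landmark registration error between the registered preoperative and the
#' intraoperative landmark sets, the measured intraoperative annulus
#' diameter, its signed difference from the implanted annuloplasty ring
#' size (`intraop_diameter - ring_size`), the recovered scaling factor, and
#' the landmark count.
#'
#' @param transform Final registration `similarity_transform`
#'   (preop to intraop).
#' @param preop_landmarks Preoperative `landmark_set` (untransformed).
#' @param intraop_landmarks Intraoperative `landmark_set`.
#' @param ring_size_mm Implanted annuloplasty ring size (mm).
#' @param annulus_points Points used for the diameter measurement; defaults
#'   to the intraoperative landmarks.
#' @param diameter_mode Passed to [annulus_diameter()].
#' @return An object of class `validation_report`.
#' @export
build_validation_report <- function(transform, preop_landmarks, intraop_landmarks,
                                    ring_size_mm,
                                    annulus_points = NULL,
                                    diameter_mode = "max_pairwise") {
  stopifnot(inherits(transform, "similarity_transform"),
            inherits(preop_landmarks, "landmark_set"),
            inherits(intraop_landmarks, "landmark_set"))
  K <- nrow(intraop_landmarks$points)
  if (K < 4L || K > 8L)
    stopf("registration uses 4 to 8 landmarks (got %d)", K)
  registered <- apply_transform(transform, preop_landmarks)
  lre <- landmark_registration_error(registered, intraop_landmarks)
  if (is.null(annulus_points)) annulus_points <- intraop_landmarks
  dia <- annulus_diameter(annulus_points, mode = diameter_mode)
  structure(list(lre_mm = lre,
                 intraop_diameter_mm = dia,
                 ring_size_mm = ring_size_mm,
                 diameter_error_mm = dia - ring_size_mm,
                 scaling_factor = transform$scale,
                 landmarks_n = K,
                 diameter_mode = diameter_mode),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  landmark registration error : %.3f mm (n = %d landmarks)\n",
              x$lre_mm, x$landmarks_n))
  cat(sprintf("  intraop annulus diameter    : %.2f mm (%s)\n",
              x$intraop_diameter_mm, x$diameter_mode))
  cat(sprintf("  annuloplasty ring size      : %.1f mm\n", x$ring_size_mm))
  cat(sprintf("  diameter error (signed)     : %.2f mm\n", x$diameter_error_mm))
  cat(sprintf("  scaling factor              : %.3f\n", x$scaling_factor))
  invisible(x)
}

#' @export
as.data.frame.validation_report <- function(x, ...) {
  data.frame(lre_mm = x$lre_mm, intraop_diameter_mm = x$intraop_diameter_mm,
             ring_size_mm = x$ring_size_mm, diameter_error_mm = x$diameter_error_mm,
             scaling_factor = x$scaling_factor, landmarks_n = x$landmarks_n,
             diameter_mode = x$diameter_mode)
}

#' Write a validation report as JSON and/or a one-row CSV
#'
#' @param report A `validation_report`.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_validation_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  if (!is.null(json_path))
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE)
  invisible(report)
}
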