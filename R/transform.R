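#' Similarity (7-DoF) transform
#'
#' A similarity transform maps a point \eqn{p} to \eqn{s R p + t}: one
#' isotropic scale factor, a proper rotation, and a translation. It is the
#' output of both the closed-form landmark alignment and the scale-adaptive
#' ICP refinement, and encodes the size difference between the preoperative
#' CT anatomy and the intraoperative unloaded heart.
#'
#' @param scale Positive scalar (dimensionless).
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Length-3 numeric vector, in mm.
#' @return An object of class `similarity_transform`.
#' @examples
#' T1 <- similarity_transform(0.72, rot_z(30), c(1, 2, 3))
#' p <- matrix(rnorm(15), 5, 3)
#' all.equal(apply_transform(st_invert(T1), apply_transform(T1, p)), p)
#' @export
similarity_transform <- function(scale = 1, rotation = diag(3), translation = c(0, 0, 0)) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stopf("'scale' must be a positive finite scalar (got %s)", format(scale))
  if (!is_rotation_matrix(rotation))
    stopf("'rotation' must be a 3x3 orthonormal matrix with det +1 (tolerance 1e-9)")
  translation <- as.numeric(translation)
  if (length(translation) != 3L || !all(is.finite(translation)))
    stopf("'translation' must be a finite length-3 vector (mm)")
  structure(list(scale = scale, rotation = rotation, translation = translation),
            class = "similarity_transform")
}

#' @rdname similarity_transform
#' @export
st_identity <- function() similarity_transform()

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> scale=%.6g, translation=(%.3f, %.3f, %.3f) mm\n",
              x$scale, x$translation[1], x$translation[2], x$translation[3]))
  cat("rotation:\n")
  print(round(x$rotation, 6))
  invisible(x)
}

#' Compose two similarity transforms
#'
#' `st_compose(a, b)` returns the transform equivalent to applying `b`
#' first, then `a` (i.e. \eqn{a \circ b}).
#'
#' @param a,b `similarity_transform` objects.
#' @return A `similarity_transform`.
#' @export
st_compose <- function(a, b) {
  stopifnot(inherits(a, "similarity_transform"), inherits(b, "similarity_transform"))
  similarity_transform(
    scale = a$scale * b$scale,
    rotation = a$rotation %*% b$rotation,
    translation = as.numeric(a$scale * a$rotation %*% b$translation + a$translation)
  )
}

#' Invert a similarity transform
#'
#' The inverse has scale `1/s`, rotation `t(R)` and translation
#' `-(1/s) t(R) t`.
#'
#' @param x A `similarity_transform`.
#' @return A `similarity_transform`.
#' @export
st_invert <- function(x) {
  stopifnot(inherits(x, "similarity_transform"))
  Rt <- t(x$rotation)
  similarity_transform(
    scale = 1 / x$scale,
    rotation = Rt,
    translation = as.numeric(-(1 / x$scale) * Rt %*% x$translation)
  )
}

#' Apply a similarity transform to geometry
#'
#' Maps every point/vertex through \eqn{p \mapsto s R p + t}. Connectivity,
#' names, labels and auxiliary fields are preserved.
#'
#' @param transform A `similarity_transform`.
#' @param x An N x 3 matrix, `point_cloud`, `tri_mesh`, or `landmark_set`.
#' @return The same type as `x`, transformed.
#' @export
apply_transform <- function(transform, x) {
  stopifnot(inherits(transform, "similarity_transform"))
  UseMethod("apply_transform", x)
}

#' @export
apply_transform.default <- function(transform, x) {
  pts <- as_points_matrix(x)
  out <- pts %*% t(transform$rotation) * transform$scale
  sweep(out, 2, transform$translation, "+")
}

#' @export
apply_transform.matrix <- function(transform, x) {
  out <- as_points_matrix(x) %*% t(transform$rotation) * transform$scale
  sweep(out, 2, transform$translation, "+")
}

#' @export
apply_transform.point_cloud <- function(transform, x) {
  x$points <- apply_transform.matrix(transform, x$points)
  x
}

#' @export
apply_transform.tri_mesh <- function(transform, x) {
  x$vertices <- apply_transform.matrix(transform, x$vertices)
  x
}

#' @export
apply_transform.landmark_set <- function(transform, x) {
  x$points <- apply_transform.matrix(transform, x$points)
  x
}

#' Read and write similarity transforms as JSON
#'
#' The JSON schema is `{scale, rotation (length-9 row-major), translation_mm}`.
#'
#' @param x A `similarity_transform`.
#' @param path File path.
#' @return `read_transform_json` returns a `similarity_transform`;
#'   `write_transform_json` returns `path` invisibly.
#' @export
write_transform_json <- function(x, path) {
  stopifnot(inherits(x, "similarity_transform"))
  obj <- list(scale = x$scale,
              rotation = as.numeric(t(x$rotation)),
              translation_mm = x$translation)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  similarity_transform(scale = obj$scale,
                       rotation = matrix(obj$rotation, 3, 3, byrow = TRUE),
                       translation = obj$translation_mm)
}
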