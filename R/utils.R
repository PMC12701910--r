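#' @keywords internal
"_PACKAGE"

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(deg) deg * pi / 180

#' Elementary rotation matrices
#'
#' Right-handed rotations about the coordinate axes, in degrees.
#'
#' @param deg Rotation angle in degrees.
#' @return A 3x3 orthonormal rotation matrix.
#' @export
rot_x <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' @rdname rot_x
#' @export
rot_y <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' @rdname rot_x
#' @export
rot_z <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Rotation about an arbitrary axis (Rodrigues formula)
#'
#' @param axis Length-3 axis vector (normalized internally).
#' @param angle_rad Rotation angle in radians.
#' @return A 3x3 rotation matrix.
#' @export
axis_angle_rotation <- function(axis, angle_rad) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

# Uniform random axis, angle uniform in [0, max]; draws from the current RNG.
random_rotation <- function(max_angle_deg = 180) {
  v <- stats::rnorm(3)
  axis_angle_rotation(v, stats::runif(1, 0, deg2rad(max_angle_deg)))
}

is_rotation_matrix <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3, 3)) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

as_points_matrix <- function(x, arg = "points") {
  if (is.null(dim(x))) {
    if (length(x) != 3L) stopf("'%s' must be an N x 3 matrix of coordinates", arg)
    x <- matrix(x, 1, 3)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stopf("'%s' must be an N x 3 matrix of coordinates", arg)
  storage.mode(x) <- "double"
  x
}

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
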