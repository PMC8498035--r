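# Small 3D vector helpers shared across modules. All coordinates are in mm.

#' Normalize a 3-vector to unit length
#' @param v numeric length-3 vector.
#' @return unit vector parallel to `v`.
#' @keywords internal
unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-300) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

#' Cross product of two 3-vectors
#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Clamp x into [lo, hi]; used before arccos to absorb rounding.
clamp <- function(x, lo = -1, hi = 1) pmin(pmax(x, lo), hi)  # keeps dims of x

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

# Angle in degrees between two vectors (not necessarily unit).
angle_between_deg <- function(a, b) {
  d <- sum(unit_vector(a) * unit_vector(b))
  deg(acos(clamp(d)))
}

# Polygonal (chord) length of an ordered point matrix.
polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

as_point_matrix <- function(x, what = "points") {
  m <- if (is.matrix(x)) x else matrix(unlist(x), ncol = 3, byrow = TRUE)
  if (ncol(m) != 3) stop(sprintf("%s must have 3 columns (x, y, z)", what), call. = FALSE)
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

#' Draw a uniformly distributed random 3D rotation matrix
#'
#' Uses the QR decomposition of a Gaussian matrix with sign correction,
#' which yields a Haar-uniform rotation.
#'
#' @return a 3x3 rotation matrix with determinant +1.
#' @export
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  d[d == 0] <- 1
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Apply a rigid pose (rotation R then translation t) to an n x 3 point matrix.
apply_pose <- function(pts, pose) {
  if (is.null(pose)) return(pts)
  sweep(pts %*% t(pose$R), 2, pose$t, `+`)
}

apply_pose_dir <- function(v, pose) {
  if (is.null(pose)) return(v)
  as.numeric(pose$R %*% v)
}
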