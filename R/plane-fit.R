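# Canal plane fitting: arc-length spline resampling followed by orthogonal
# (total) least-squares plane fitting, and direction angles of the unit
# normal in the standard frame.
#
# Centerline points are denser in curved regions than straight ones, which
# would bias a direct fit; resampling the interpolating spline at uniform
# arc length removes that bias. The plane is fitted orthogonally (smallest
# principal direction of the centered covariance) rather than as a
# functional surface z = f(x, y), because canal planes can be near-vertical
# in image coordinates where functional fits degenerate.

#' Resample an arc at uniform arc length along an interpolating spline
#'
#' Fits a chord-length-parameterized cubic interpolating spline through the
#' input points and returns `n_out` points at equal arc-length steps, with
#' the input endpoints preserved exactly. Coincident consecutive input points
#' are dropped with a warning.
#'
#' @param arc ordered n x 3 point matrix (mm), at least 4 distinct points.
#' @param n_out number of output points (>= 10).
#' @return an n_out x 3 matrix, uniformly spaced by arc length.
#' @export
spline_resample <- function(arc, n_out = 200) {
  arc <- as_point_matrix(arc, "arc")
  if (n_out < 10) stop("n_out must be >= 10", call. = FALSE)
  steps <- sqrt(rowSums((arc[-1, , drop = FALSE] - arc[-nrow(arc), , drop = FALSE])^2))
  if (any(steps == 0)) {
    warning("removing coincident consecutive points before spline fitting")
    arc <- arc[c(TRUE, steps > 0), , drop = FALSE]
    steps <- steps[steps > 0]
  }
  if (nrow(arc) < 4) stop("spline resampling needs at least 4 distinct points", call. = FALSE)
  tt <- c(0, cumsum(steps))
  fx <- stats::splinefun(tt, arc[, 1], method = "fmm")
  fy <- stats::splinefun(tt, arc[, 2], method = "fmm")
  fz <- stats::splinefun(tt, arc[, 3], method = "fmm")
  # dense evaluation to build the arc-length parameterization of the spline
  td <- seq(0, tt[length(tt)], length.out = max(20 * n_out, 2000))
  dense <- cbind(fx(td), fy(td), fz(td))
  ds <- sqrt(rowSums((dense[-1, , drop = FALSE] - dense[-nrow(dense), , drop = FALSE])^2))
  s <- c(0, cumsum(ds))
  targets <- seq(0, s[length(s)], length.out = n_out)
  tpar <- stats::approx(s, td, xout = targets, ties = "ordered")$y
  out <- cbind(fx(tpar), fy(tpar), fz(tpar))
  out[1, ] <- arc[1, ]
  out[n_out, ] <- arc[nrow(arc), ]
  out
}

#' Orthogonal least-squares plane fit
#'
#' Returns the plane through the centroid whose normal minimizes the sum of
#' squared perpendicular distances (the smallest principal direction of the
#' centered point covariance), together with the root-mean-square
#' perpendicular residual.
#'
#' @param points n x 3 point matrix, n >= 3, not collinear.
#' @return list with `plane` (a [plane3d()]), `normal` (unit 3-vector) and
#'   `fit_rms` (mm).
#' @export
fit_plane_tls <- function(points) {
  points <- as_point_matrix(points, "points")
  if (nrow(points) < 3) stop("plane fit needs at least 3 points", call. = FALSE)
  centroid <- colMeans(points)
  centered <- sweep(points, 2, centroid)
  sv <- svd(centered, nu = 0)
  s <- sv$d
  if (s[2]^2 - s[3]^2 <= 1e-12 * max(s[1]^2, .Machine$double.eps))
    stop("degenerate point set: plane normal is not unique (points collinear or isotropic)",
         call. = FALSE)
  normal <- sv$v[, 3]
  fit_rms <- sqrt(mean((centered %*% normal)^2))
  list(plane = plane3d(centroid, normal), normal = as.numeric(normal),
       fit_rms = fit_rms)
}

#' Orient a canal normal by the superior-positive sign convention
#'
#' A plane normal is defined up to sign; the convention used throughout is a
#' positive superior (third) component, tie-broken by positive anterior
#' (second), then left (first) component. Idempotent.
#'
#' @param normal unit 3-vector.
#' @return the sign-fixed unit vector.
#' @export
orient_normal <- function(normal) {
  v <- as.numeric(normal)
  tol <- 1e-9
  flip <- if (abs(v[3]) >= tol) v[3] < 0 else if (abs(v[2]) >= tol) v[2] < 0 else v[1] < 0
  if (flip) -v else v
}

#' Direction angles of a unit normal
#'
#' The angle between the canal plane and each coordinate plane (sagittal,
#' coronal, horizontal) equals the angle between their normals, i.e. the
#' arccosine of the corresponding component of the canal's unit normal.
#' Angles are reported in degrees on [0, 180] with no folding, so obtuse
#' attitudes are preserved. Components are used as given (no renormalization),
#' so a vector printed to 3 decimals reproduces the angles tabulated from it;
#' `unit_tol` bounds the acceptable norm deviation.
#'
#' @param normal 3-vector with norm within `unit_tol` of 1.
#' @param unit_tol allowed deviation of the norm from 1 (default 1e-3, which
#'   admits unit vectors rounded to 3 decimals).
#' @return named numeric vector `c(sagittal, coronal, horizontal)`, degrees.
#' @export
direction_angles <- function(normal, unit_tol = 1e-3) {
  v <- as.numeric(normal)
  if (length(v) != 3 || abs(sqrt(sum(v^2)) - 1) > unit_tol)
    stop("direction_angles expects a unit vector (within unit_tol)", call. = FALSE)
  stats::setNames(deg(acos(clamp(v))), c("sagittal", "coronal", "horizontal"))
}

#' Fit one labelled canal and express its attitude in the head frame
#'
#' Resamples the canal arc, fits the plane orthogonally, transforms the
#' normal into the frame, orients it superior-positive and computes the
#' direction angles.
#'
#' @param canal a labelled canal from [identify_canals()].
#' @param frame a [build_frame()] result.
#' @param n_out spline resample count.
#' @return list with `side`, `canal`, `normal` (unit, in-frame),
#'   `angles` (degrees), `fit_rms` (mm).
#' @export
canal_attitude <- function(canal, frame, n_out = 200) {
  res <- spline_resample(canal$path, n_out = n_out)
  fit <- fit_plane_tls(res)
  n_frame <- orient_normal(to_frame(fit$normal, frame, is_direction = TRUE))
  list(side = canal$side, canal = canal$canal, normal = n_frame,
       angles = direction_angles(n_frame, unit_tol = 1e-9),
       fit_rms = fit$fit_rms)
}
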