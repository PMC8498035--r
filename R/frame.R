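# Standard head coordinate frame.
#
# The horizontal reference ("fundus") plane passes through the bilateral
# common-crus bifurcations and the lowest point of the eyeball, the latter
# found by a fixed-point iteration: starting from the vertex with minimum
# third coordinate, form the plane with both crus points, take the eyeball
# vertex farthest on the inferior side, and repeat until the selection is
# stable. The frame is then Z = plane normal (superior), X = the crus-to-crus
# line (orthogonalized), Y completing the triple, origin midway between the
# crus points.

#' Construct a plane from a point and normal
#' @param point a point on the plane (mm).
#' @param normal plane normal (normalized internally).
#' @return an object of class `plane3d`.
#' @export
plane3d <- function(point, normal) {
  structure(list(point = as.numeric(point), normal = unit_vector(normal)),
            class = "plane3d")
}

#' @export
print.plane3d <- function(x, ...) {
  cat(sprintf("<plane3d> point (%.3f, %.3f, %.3f), normal (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Plane through three points
#'
#' The normal sign is fixed by convention: positive third component in the
#' input coordinates, tie-broken by positive second, then first component, so
#' the same three points in any order yield the same plane.
#'
#' @param p1,p2,p3 3D points (mm), non-collinear.
#' @return a [plane3d()].
#' @export
plane_from_points <- function(p1, p2, p3) {
  n <- cross3(p2 - p1, p3 - p1)
  if (sqrt(sum(n^2)) / 2 <= 1e-9)
    stop("degenerate geometry: points are (nearly) collinear", call. = FALSE)
  n <- unit_vector(n)
  tol <- 1e-12
  flip <- if (abs(n[3]) > tol) n[3] < 0 else if (abs(n[2]) > tol) n[2] < 0 else n[1] < 0
  if (flip) n <- -n
  plane3d(p1, n)
}

#' Signed distance from a plane to point(s)
#'
#' Positive on the side the plane normal points to.
#'
#' @param plane a [plane3d()].
#' @param q a 3-vector or n x 3 matrix of points.
#' @return numeric vector of signed distances (mm).
#' @export
signed_distance <- function(plane, q) {
  stopifnot(inherits(plane, "plane3d"))
  if (is.matrix(q))
    as.numeric(sweep(q, 2, plane$point, `-`) %*% plane$normal)
  else
    sum(plane$normal * (q - plane$point))
}

#' Locate the lowest eyeball point and the horizontal fundus plane
#'
#' Fixed-point iteration over the pooled eyeball vertices: start from the
#' vertex with minimum third coordinate, form the plane through it and both
#' crus bifurcations (normal oriented toward the bulk of the eyeball cloud,
#' i.e. superiorly), then reselect the vertex farthest on the inferior side;
#' stop when the selection no longer changes. On discrete meshes the
#' iteration can in principle cycle; after `max_iter` the vertex with the
#' largest inferior excursion seen is kept, with a warning status.
#'
#' @param eyeballs an [eyeball_surface()] or list of them (both sides pooled).
#' @param crus_left,crus_right bilateral common-crus bifurcation points (mm).
#' @param max_iter iteration cap.
#' @param superior_hint optional approximate superior direction (e.g. from
#'   the utricle toward the common-crus bifurcation). The tangent-plane fixed
#'   point comes in a superior/inferior pair; the hint selects the inferior
#'   tangent regardless of the subject's pose. Without it, the third image
#'   axis is assumed approximately superior (head-up acquisition).
#' @return list: `point` (the fundus vertex), `index` (into the pooled
#'   vertices), `side` (which eyeball supplied it), `plane` (final
#'   [plane3d()], normal superior), `iterations`, `converged`,
#'   `inferior_trace` (inferior distance of the selected vertex per
#'   iteration).
#' @export
fundus_point <- function(eyeballs, crus_left, crus_right, max_iter = 100,
                         superior_hint = NULL) {
  if (inherits(eyeballs, "eyeball_surface")) eyeballs <- list(eyeballs)
  stopifnot(length(eyeballs) >= 1)
  pts <- do.call(rbind, lapply(eyeballs, `[[`, "points"))
  sides <- unlist(lapply(eyeballs, function(e) rep(e$side, nrow(e$points))))
  if (nrow(pts) == 0) stop("no eyeball points", call. = FALSE)
  if (sqrt(sum((crus_left - crus_right)^2)) <= 0)
    stop("crus points must be distinct", call. = FALSE)

  superior_plane <- function(v) {
    pl <- plane_from_points(crus_left, crus_right, v)
    up <- if (is.null(superior_hint)) mean(signed_distance(pl, pts)) else
      sum(pl$normal * superior_hint)
    if (up < 0) pl$normal <- -pl$normal
    pl
  }
  idx <- if (is.null(superior_hint)) which.min(pts[, 3]) else
    which.min(as.numeric(pts %*% unit_vector(superior_hint)))
  trace <- numeric(0)
  converged <- FALSE
  best_idx <- idx; best_excursion <- -Inf
  iterations <- 0
  for (k in seq_len(max_iter)) {
    iterations <- k
    pl <- superior_plane(pts[idx, ])
    d <- signed_distance(pl, pts)
    nxt <- which.min(d)
    excursion <- -d[nxt]
    trace <- c(trace, excursion)
    if (excursion > best_excursion) { best_excursion <- excursion; best_idx <- nxt }
    if (nxt == idx) { converged <- TRUE; break }
    idx <- nxt
  }
  if (!converged) {
    warning(sprintf("fundus_point did not converge in %d iterations; keeping the most inferior vertex seen", max_iter))
    idx <- best_idx
  }
  pl <- superior_plane(pts[idx, ])
  list(point = pts[idx, ], index = idx, side = sides[idx], plane = pl,
       iterations = iterations, converged = converged, inferior_trace = trace)
}

#' Build the standard head coordinate frame
#'
#' Z is the fundus-plane normal oriented superiorly (toward the crus side
#' when the crus points are off-plane, otherwise as supplied); X runs from
#' the right to the left crus bifurcation (convention `"las"`) or right-ward
#' (convention `"ras"`), Gram-Schmidt-orthogonalized against Z; Y = Z x X
#' completes the triple (anterior); the origin is the midpoint of the crus
#' points.
#'
#' @param crus_left,crus_right crus bifurcation points (mm), > 1 mm apart.
#' @param fundus_plane a [plane3d()], normal oriented superiorly.
#' @param convention `"las"` (x positive to the left) or `"ras"`
#'   (x positive to the right).
#' @return an object of class `head_frame`: `origin`, `axes` (3 x 3 matrix,
#'   columns X, Y, Z), `convention`.
#' @export
build_frame <- function(crus_left, crus_right, fundus_plane,
                        convention = c("las", "ras")) {
  convention <- match.arg(convention)
  stopifnot(inherits(fundus_plane, "plane3d"))
  sep <- sqrt(sum((crus_left - crus_right)^2))
  if (sep <= 1) stop("degenerate geometry: crus separation must exceed 1 mm", call. = FALSE)
  z <- fundus_plane$normal
  mid <- (crus_left + crus_right) / 2
  s <- signed_distance(fundus_plane, mid)
  if (abs(s) > 1e-9 && s < 0) z <- -z
  x_raw <- if (convention == "las") crus_left - crus_right else crus_right - crus_left
  x_raw <- x_raw / sep
  x_perp <- x_raw - sum(x_raw * z) * z
  if (sqrt(sum(x_perp^2)) < 1e-6)
    stop("degenerate geometry: crus line is parallel to the fundus normal", call. = FALSE)
  x <- unit_vector(x_perp)
  y <- cross3(z, x)
  frame <- structure(list(origin = mid, axes = cbind(X = x, Y = y, Z = z),
                          convention = convention),
                     class = "head_frame")
  validate_frame(frame)
  frame
}

validate_frame <- function(frame) {
  g <- crossprod(frame$axes)
  if (max(abs(g - diag(3))) > 1e-10)
    stop("head frame axes are not orthonormal", call. = FALSE)
  invisible(frame)
}

#' @export
print.head_frame <- function(x, ...) {
  cat(sprintf("<head_frame> convention '%s', origin (%.2f, %.2f, %.2f)\n",
              x$convention, x$origin[1], x$origin[2], x$origin[3]))
  ax <- t(x$axes)
  for (i in 1:3)
    cat(sprintf("  %s = (%+.4f, %+.4f, %+.4f)\n", c("X", "Y", "Z")[i],
                ax[i, 1], ax[i, 2], ax[i, 3]))
  invisible(x)
}

#' Transform coordinates into the head frame
#'
#' Points are translated to the frame origin then projected on the axes;
#' directions are projected only.
#'
#' @param x a 3-vector or n x 3 matrix.
#' @param frame a [build_frame()] result.
#' @param is_direction treat `x` as direction vector(s) (no translation).
#' @return transformed coordinates, same shape as `x`.
#' @export
to_frame <- function(x, frame, is_direction = FALSE) {
  stopifnot(inherits(frame, "head_frame"))
  if (is.matrix(x)) {
    if (!is_direction) x <- sweep(x, 2, frame$origin, `-`)
    out <- x %*% frame$axes
    dimnames(out) <- dimnames(x)
    out
  } else {
    if (!is_direction) x <- x - frame$origin
    as.numeric(x %*% frame$axes)
  }
}

#' Inverse of [to_frame()]
#' @inheritParams to_frame
#' @export
from_frame <- function(x, frame, is_direction = FALSE) {
  stopifnot(inherits(frame, "head_frame"))
  if (is.matrix(x)) {
    out <- x %*% t(frame$axes)
    if (!is_direction) out <- sweep(out, 2, frame$origin, `+`)
    dimnames(out) <- dimnames(x)
    out
  } else {
    out <- as.numeric(x %*% t(frame$axes))
    if (!is_direction) out <- out + frame$origin
    out
  }
}
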