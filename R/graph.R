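# Centerline graph analysis: junction detection, segment extraction, canal
# identification and anatomical key points A-E.
#
# The centerline model of one subject is a set of polylines whose shared
# coordinates mark anatomical branch points. A coordinate is a junction when
# it occurs in at least three polyline incidences (after welding within
# weld_tol); polylines are split at interior junction occurrences into
# segments; the three canal rings per side are told apart by the positions of
# their midpoints (posterior ring rearmost, superior ring uppermost, lateral
# ring outermost, the cochlea-utricle line foremost), with the expected
# length ordering posterior > superior > lateral checked afterwards.

#' Find junction points of a centerline set
#'
#' Welds coordinates within `weld_tol` and returns those occurring in at
#' least three polyline incidences. Junctions closer together than
#' `min_separation` are merged (multiplicities summed) to absorb spurious
#' near-duplicate intersections.
#'
#' @param centerlines a [centerline_set()].
#' @param weld_tol welding tolerance in mm (>= 0).
#' @param min_separation minimum distance between distinct junctions, mm.
#' @return data.frame with columns x, y, z, multiplicity (possibly 0 rows).
#' @export
find_junctions <- function(centerlines, weld_tol = 1e-6, min_separation = 1.0) {
  stopifnot(inherits(centerlines, "centerline_set"))
  if (weld_tol < 0) stop("weld_tol must be >= 0", call. = FALSE)
  pts <- do.call(rbind, centerlines$polylines)
  key <- if (weld_tol > 0)
    apply(round(pts / weld_tol), 1, paste, collapse = ",")
  else
    apply(pts, 1, function(p) paste(sprintf("%.17g", p), collapse = ","))
  counts <- table(key)
  jkeys <- names(counts)[counts >= 3]
  if (length(jkeys) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      multiplicity = integer(0)))
  first_idx <- match(jkeys, key)
  out <- data.frame(x = pts[first_idx, 1], y = pts[first_idx, 2],
                    z = pts[first_idx, 3],
                    multiplicity = as.integer(counts[jkeys]))
  out <- out[order(-out$multiplicity), , drop = FALSE]
  # greedy merge of junctions closer than min_separation, highest multiplicity kept
  keep <- integer(0)
  for (i in seq_len(nrow(out))) {
    p <- as.numeric(out[i, 1:3])
    if (length(keep) > 0) {
      d <- sqrt(colSums((t(as.matrix(out[keep, 1:3])) - p)^2))
      if (any(d < min_separation)) {
        out$multiplicity[keep[which.min(d)]] <-
          out$multiplicity[keep[which.min(d)]] + out$multiplicity[i]
        next
      }
    }
    keep <- c(keep, i)
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split polylines into segments at junction points
#'
#' Every polyline is cut at interior occurrences of junction coordinates;
#' each resulting segment records its ordered path, polygonal arc length and
#' endpoint coordinates.
#'
#' @param centerlines a [centerline_set()].
#' @param junctions data.frame from [find_junctions()].
#' @param weld_tol tolerance used to match path points to junctions, mm.
#' @return list of segments, each a list with `path`, `arc_length`,
#'   `endpoints` (2 x 3), `polyline` (source index).
#' @export
extract_segments <- function(centerlines, junctions, weld_tol = 1e-6) {
  stopifnot(inherits(centerlines, "centerline_set"))
  jmat <- as.matrix(junctions[, c("x", "y", "z"), drop = FALSE])
  segs <- list()
  for (pi in seq_along(centerlines$polylines)) {
    path <- centerlines$polylines[[pi]]
    n <- nrow(path)
    cuts <- c(1L, n)
    if (nrow(jmat) > 0 && n > 2) {
      interior <- 2:(n - 1)
      ipts <- path[interior, , drop = FALSE]
      hit <- rep(FALSE, length(interior))
      for (jj in seq_len(nrow(jmat)))
        hit <- hit | sqrt(rowSums(sweep(ipts, 2, jmat[jj, ])^2)) <= weld_tol
      cuts <- sort(unique(c(cuts, interior[hit])))
    }
    for (k in seq_len(length(cuts) - 1)) {
      sub <- path[cuts[k]:cuts[k + 1], , drop = FALSE]
      segs[[length(segs) + 1]] <- list(
        path = sub,
        arc_length = polyline_length(sub),
        endpoints = rbind(sub[1, ], sub[nrow(sub), ]),
        polyline = pi)
    }
  }
  segs
}

# Interpolated point at half the polygonal arc length of a path.
segment_midpoint <- function(path) {
  steps <- sqrt(rowSums((path[-1, , drop = FALSE] - path[-nrow(path), , drop = FALSE])^2))
  cum <- c(0, cumsum(steps))
  s <- cum[length(cum)] / 2
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(path) - 1L)
  f <- if (steps[i] > 0) (s - cum[i]) / steps[i] else 0
  path[i, ] * (1 - f) + path[i + 1, ] * f
}

points_close <- function(p, q, tol) sqrt(sum((p - q)^2)) <= tol

#' Split centerline segments into left and right labyrinths
#'
#' The two labyrinths are disjoint point sets; segments are grouped into
#' connected components by shared (welded) endpoints. Left/right naming uses
#' proximity to the side-labelled eyeball surfaces when given, otherwise the
#' sign of the first coordinate relative to the midpoint of the component
#' centroids.
#'
#' @param segments list from [extract_segments()].
#' @param eyeballs optional list of [eyeball_surface()] objects.
#' @param weld_tol endpoint welding tolerance, mm.
#' @return `segments` with a `side` ("left"/"right") element added to each.
#' @export
split_sides <- function(segments, eyeballs = NULL, weld_tol = 1e-6) {
  n <- length(segments)
  if (n == 0) stop("no segments to split", call. = FALSE)
  comp <- seq_len(n)
  find_root <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    touch <- FALSE
    for (a in 1:2) for (b in 1:2)
      if (points_close(segments[[i]]$endpoints[a, ], segments[[j]]$endpoints[b, ], weld_tol))
        touch <- TRUE
    if (touch) comp[find_root(j)] <- find_root(i)
  }
  roots <- vapply(seq_len(n), find_root, 1L)
  comps <- unique(roots)
  if (length(comps) != 2)
    stop(sprintf("expected 2 connected labyrinth components, found %d", length(comps)),
         call. = FALSE)
  centroids <- lapply(comps, function(r) {
    pts <- do.call(rbind, lapply(segments[roots == r], `[[`, "path"))
    colMeans(pts)
  })
  if (!is.null(eyeballs) && length(eyeballs) > 0) {
    eb_centers <- lapply(eyeballs, function(e) colMeans(e$points))
    eb_sides <- vapply(eyeballs, function(e) e$side, "")
    side_of <- vapply(centroids, function(ct) {
      d <- vapply(eb_centers, function(c0) sqrt(sum((ct - c0)^2)), numeric(1))
      eb_sides[which.min(d)]
    }, "")
    if (length(unique(side_of)) != 2)
      stop("could not assign distinct sides from eyeball proximity", call. = FALSE)
  } else {
    mid_x <- mean(vapply(centroids, `[`, numeric(1), 1))
    side_of <- ifelse(vapply(centroids, `[`, numeric(1), 1) > mid_x, "left", "right")
  }
  for (i in seq_len(n))
    segments[[i]]$side <- side_of[match(roots[i], comps)]
  segments
}

#' Identify the three canal rings per side
#'
#' Ring candidates (segments longer than `min_ring_length`) are labelled by
#' midpoint position: the posterior canal midpoint is rearmost, the superior
#' canal midpoint uppermost, the lateral canal midpoint outermost (assigned
#' greedily in that order). Position coordinates are taken in `frame` when
#' given, otherwise image axes are assumed to approximate the anatomical ones
#' (x left, y anterior, z superior). The expected size ordering posterior >
#' superior > lateral is checked afterwards on fitted ring radii (robust to
#' point noise, unlike raw polygonal length); violations warn rather than
#' fail, since position is the primary cue.
#'
#' @param segments list from [split_sides()] (each with a `side`).
#' @param frame optional [build_frame()] result for in-frame positions.
#' @param min_ring_length minimum arc length of a ring candidate, mm.
#' @param tie_tol positions closer than this along the deciding axis raise an
#'   ambiguity error, mm.
#' @return list of labelled canals (`side`, `canal`, `path`, `arc_length`,
#'   `endpoints`), with a character vector of warnings in
#'   `attr(, "warnings")`.
#' @export
identify_canals <- function(segments, frame = NULL, min_ring_length = 8.0,
                            tie_tol = 1e-6) {
  if (is.null(segments[[1]]$side))
    stop("segments must carry side labels; run split_sides() first", call. = FALSE)
  warnings_out <- character(0)
  result <- list()
  for (side in unique(vapply(segments, `[[`, "", "side"))) {
    side_segs <- Filter(function(s) s$side == side, segments)
    cand <- Filter(function(s) s$arc_length >= min_ring_length, side_segs)
    if (length(cand) < 3)
      stop(sprintf("identification error: %d ring candidates on %s side (need 3)",
                   length(cand), side), call. = FALSE)
    mids <- t(vapply(cand, function(s) segment_midpoint(s$path), numeric(3)))
    if (!is.null(frame)) mids <- to_frame(mids, frame)
    side_sign <- if (side == "left") 1 else -1
    scores <- list(posterior = -mids[, 2],              # rearmost
                   superior  =  mids[, 3],              # uppermost
                   lateral   =  side_sign * mids[, 1])  # outermost
    taken <- integer(0)
    for (canal in c("posterior", "superior", "lateral")) {
      sc <- scores[[canal]]
      sc[taken] <- -Inf
      ord <- order(sc, decreasing = TRUE)
      if (length(ord) >= 2 && is.finite(sc[ord[2]]) &&
          sc[ord[1]] - sc[ord[2]] < tie_tol)
        stop(sprintf("ambiguous %s canal on %s side: segments %d and %d tie on position",
                     canal, side, ord[1], ord[2]), call. = FALSE)
      pick <- ord[1]
      taken <- c(taken, pick)
      s <- cand[[pick]]
      result[[length(result) + 1]] <- list(side = side, canal = canal,
                                           path = s$path,
                                           arc_length = s$arc_length,
                                           endpoints = s$endpoints)
    }
    rsz <- vapply(result[(length(result) - 2):length(result)], function(cn)
      estimate_ring_radius(cn$path), numeric(1))
    if (!(rsz[1] > rsz[2] && rsz[2] > rsz[3]))
      warnings_out <- c(warnings_out, sprintf(
        "%s side: ring sizes violate posterior > superior > lateral (radii %.2f, %.2f, %.2f mm); labels follow position rules",
        side, rsz[1], rsz[2], rsz[3]))
  }
  attr(result, "warnings") <- warnings_out
  result
}

# Junctions arising only from short spurious connections are rejected: a
# junction survives only if at least one incident segment is min_arc or
# longer. Returns the pruned junction table.
prune_junctions <- function(junctions, segments, min_arc = 2.0, weld_tol = 1e-6) {
  if (nrow(junctions) == 0) return(junctions)
  keep <- vapply(seq_len(nrow(junctions)), function(i) {
    p <- as.numeric(junctions[i, 1:3])
    any(vapply(segments, function(s)
      s$arc_length >= min_arc &&
        (points_close(s$endpoints[1, ], p, weld_tol) ||
         points_close(s$endpoints[2, ], p, weld_tol)), logical(1)))
  }, logical(1))
  junctions[keep, , drop = FALSE]
}

# Noise-robust ring size: fit the segment's plane orthogonally, project the
# path into it and fit a circle algebraically (Kasa). Polygonal arc length is
# inflated by point noise (each noisy step adds length), whereas the fitted
# radius averages the noise out; ring ordering decisions use this.
estimate_ring_radius <- function(path) {
  fit <- fit_plane_tls(path)
  centered <- sweep(path, 2, fit$plane$point)
  b1 <- unit_vector(centered[1, ] - sum(centered[1, ] * fit$normal) * fit$normal)
  b2 <- cross3(fit$normal, b1)
  xy <- cbind(centered %*% b1, centered %*% b2)
  A <- cbind(xy, 1)
  rhs <- -rowSums(xy^2)
  coef <- qr.solve(A, rhs)
  ctr <- -coef[1:2] / 2
  sqrt(max(sum(ctr^2) - coef[3], 0))
}

# Other-endpoint coordinates of short link segments incident (within tol) to
# point p, excluding the canal arcs themselves.
link_far_ends <- function(p, segments, canal_paths_len, tol) {
  out <- list()
  for (s in segments) {
    if (s$arc_length %in% canal_paths_len) next
    for (a in 1:2)
      if (points_close(s$endpoints[a, ], p, tol))
        out[[length(out) + 1]] <- s$endpoints[3 - a, ]
  }
  out
}

#' Identify the anatomical key points A-E per side
#'
#' A is the endpoint shared by the posterior and superior canal arcs (the
#' superior one if they share both); D and C are those arcs' other endpoints;
#' B is the lateral arc endpoint away from C (set equal to D when they
#' coincide within `weld_tol`); E is the utricle point, the far endpoint
#' shared by the link segments leaving D and C.
#'
#' @param canals labelled canals from [identify_canals()].
#' @param segments all segments of the same subject (with sides).
#' @param weld_tol welding tolerance, mm.
#' @param frame optional frame used to resolve "superior" when the posterior
#'   and superior arcs share both endpoints.
#' @return named list per side, each a 5 x 3 matrix with rows A, B, C, D, E.
#' @export
identify_key_points <- function(canals, segments, weld_tol = 1e-6, frame = NULL) {
  out <- list()
  for (side in unique(vapply(canals, `[[`, "", "side"))) {
    get_canal <- function(which) {
      hit <- Filter(function(cn) cn$side == side && cn$canal == which, canals)
      if (length(hit) != 1) stop(sprintf("missing %s canal on %s side", which, side), call. = FALSE)
      hit[[1]]
    }
    post <- get_canal("posterior"); sup <- get_canal("superior"); lat <- get_canal("lateral")
    shared <- list()
    for (a in 1:2) for (b in 1:2)
      if (points_close(post$endpoints[a, ], sup$endpoints[b, ], weld_tol))
        shared[[length(shared) + 1]] <- list(a = a, b = b)
    if (length(shared) == 0)
      stop(sprintf("topology error: posterior and superior arcs share no endpoint on %s side", side),
           call. = FALSE)
    if (length(shared) > 1) {
      # both endpoints shared: A is the more superior one
      zs <- vapply(shared, function(sh) {
        p <- post$endpoints[sh$a, ]
        if (!is.null(frame)) to_frame(p, frame)[3] else p[3]
      }, numeric(1))
      shared <- shared[order(-zs)]
    }
    A <- post$endpoints[shared[[1]]$a, ]
    D <- post$endpoints[3 - shared[[1]]$a, ]
    C <- sup$endpoints[3 - shared[[1]]$b, ]
    lat_at_c <- which(vapply(1:2, function(a)
      points_close(lat$endpoints[a, ], C, weld_tol), logical(1)))
    if (length(lat_at_c) != 1)
      stop(sprintf("topology error: lateral arc does not meet C exactly once on %s side", side),
           call. = FALSE)
    B <- lat$endpoints[3 - lat_at_c, ]
    if (points_close(B, D, weld_tol)) B <- D

    side_segs <- Filter(function(s) s$side == side, segments)
    canal_lens <- vapply(list(post, sup, lat), `[[`, numeric(1), "arc_length")
    fromD <- link_far_ends(D, side_segs, canal_lens, weld_tol)
    fromC <- link_far_ends(C, side_segs, canal_lens, weld_tol)
    fromA <- link_far_ends(A, side_segs, canal_lens, weld_tol)
    E <- NULL
    for (pd in c(fromD, fromA)) {
      for (pc in fromC)
        if (points_close(pd, pc, weld_tol)) { E <- pd; break }
      if (!is.null(E)) break
    }
    if (is.null(E)) {
      # fall back: most frequent far endpoint among all links at A, C, D
      allp <- c(fromA, fromC, fromD)
      if (length(allp) == 0)
        stop(sprintf("topology error: no utricle link found on %s side", side), call. = FALSE)
      counts <- vapply(allp, function(p)
        sum(vapply(allp, function(q) points_close(p, q, weld_tol), logical(1))), 1L)
      E <- allp[[which.max(counts)]]
    }
    kp <- rbind(A = A, B = B, C = C, D = D, E = E)
    out[[side]] <- kp
  }
  out
}
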