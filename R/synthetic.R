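# Synthetic labyrinth generator.
#
# Builds subjects whose centerline models realize the canonical inner-ear
# graph: per side a posterior canal arc A-D, a superior canal arc A-C, a
# lateral canal arc B-C, a common-crus link A-E, utricle links D-E and C-E,
# and a cochlea-utricle line leaving E. Junction coordinates are bit-identical
# across the polylines that meet there; arc/link endpoints are noise-free so
# junctions weld exactly, while interior points carry isotropic Gaussian noise
# emulating centerline-extraction jitter. Ground truth (key points, canal
# normals, pose) is returned alongside, so every downstream stage can be
# validated without real image data.
#
# Geometry is constructed in a canonical "standard" frame (x positive to the
# left, y anterior, z superior, origin midway between the two common-crus
# bifurcations) and then moved by an arbitrary rigid pose into image
# coordinates. The pipeline must recover attitudes independent of that pose.

#' Reference adult semicircular-canal plane normals
#'
#' Unit normals of the six canal planes (right/left posterior, superior,
#' lateral) in the standard head frame (x left, y anterior, z superior),
#' consistent with published adult averages. Used as the generator's default
#' population orientations.
#'
#' @return a 6 x 3 matrix with rows RP, RA, RH, LP, LA, LH.
#' @export
standard_canal_normals <- function() {
  m <- rbind(
    RP = c(-0.651,  0.702, 0.287),
    RA = c( 0.749,  0.577, 0.324),
    RH = c(-0.017, -0.299, 0.954),
    LP = c( 0.660,  0.702, 0.266),
    LA = c(-0.739,  0.588, 0.329),
    LH = c( 0.025, -0.279, 0.960))
  t(apply(m, 1, unit_vector))
}

# Typical angular dispersion (mean deviation, degrees) of individual canal
# normals about the population mean, per canal; posterior/superior canals are
# more consistent across subjects than the lateral canal.
default_canal_dispersion <- function() {
  c(RP = 5.26, RA = 5.31, RH = 6.94, LP = 5.40, LA = 5.60, LH = 6.73)
}

#' Map a target mean angular deviation to a von Mises-Fisher concentration
#'
#' Uses the high-concentration (tangent-plane Rayleigh) approximation: for
#' vMF(kappa) on the sphere the off-axis angle is approximately Rayleigh with
#' scale 1/sqrt(kappa), so the mean deviation is sqrt(pi / (2 kappa)).
#'
#' @param mean_deviation_deg target mean angular deviation in degrees.
#' @return concentration parameter kappa.
#' @seealso [deviation_for_kappa()]
#' @export
kappa_for_deviation <- function(mean_deviation_deg) {
  stopifnot(mean_deviation_deg > 0)
  pi / (2 * rad(mean_deviation_deg)^2)
}

#' @rdname kappa_for_deviation
#' @param kappa concentration parameter (> 0).
#' @export
deviation_for_kappa <- function(kappa) {
  stopifnot(kappa > 0)
  deg(sqrt(pi / (2 * kappa)))
}

#' Sample from the von Mises-Fisher distribution on the unit sphere
#'
#' Wood's (1994) rejection sampler for the axial component, with a uniform
#' tangential direction, rotated so the distribution's mean is `mu`. Draws use
#' the current RNG state; seed via [withr::with_seed()] or `set.seed()`.
#'
#' @param n number of draws.
#' @param mu mean direction (3-vector, normalized internally).
#' @param kappa concentration (> 0); large kappa concentrates draws near `mu`.
#' @return an n x 3 matrix of unit vectors.
#' @export
rvmf <- function(n, mu, kappa) {
  if (kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  mu <- unit_vector(mu)
  d <- 3
  # conjugate form of (-2k + sqrt(4k^2 + (d-1)^2))/(d-1): stable at large kappa
  b <- (d - 1) / (2 * kappa + sqrt(4 * kappa^2 + (d - 1)^2))
  x0 <- (1 - b) / (1 + b)
  cc <- kappa * x0 + (d - 1) * log(1 - x0^2)
  w <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      z <- stats::rbeta(1, (d - 1) / 2, (d - 1) / 2)
      u <- stats::runif(1)
      wi <- (1 - (1 + b) * z) / (1 - (1 - b) * z)
      if (kappa * wi + (d - 1) * log(1 - x0 * wi) - cc >= log(u)) break
    }
    w[i] <- wi
  }
  theta <- stats::runif(n, 0, 2 * pi)
  vperp <- sqrt(pmax(0, 1 - w^2))
  samples_pole <- cbind(vperp * cos(theta), vperp * sin(theta), w)
  # rotate the pole (0,0,1) onto mu via the connecting rotation
  pole <- c(0, 0, 1)
  if (sum((mu - pole)^2) < 1e-24) return(samples_pole)
  if (sum((mu + pole)^2) < 1e-24) return(samples_pole %*% diag(c(1, -1, -1)))
  v <- cross3(pole, mu)
  s <- sqrt(sum(v^2)); co <- sum(pole * mu)
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  rot <- diag(3) + vx + vx %*% vx * ((1 - co) / s^2)
  samples_pole %*% t(rot)
}

#' Specify one canal's circular-arc centerline
#'
#' @param true_normal unit normal of the canal plane (normalized internally,
#'   must be non-zero).
#' @param center circle center (mm).
#' @param radius circle radius in mm (> 0).
#' @param arc_span swept angle in degrees (0 < span <= 360).
#' @param n_points number of points emitted along the arc (>= 3).
#' @param start_dir unit in-plane direction from `center` to the arc's first
#'   endpoint; a deterministic in-plane reference is chosen when `NULL`.
#' @param sweep +1 or -1, direction of travel around `true_normal`.
#' @return an object of class `canal_spec`.
#' @export
canal_spec <- function(true_normal, center = c(0, 0, 0), radius = 3.0,
                       arc_span = 240, n_points = 120,
                       start_dir = NULL, sweep = 1) {
  n <- unit_vector(true_normal)
  if (abs(sqrt(sum(n^2)) - 1) > 1e-12) stop("true_normal could not be normalized", call. = FALSE)
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (arc_span <= 0 || arc_span > 360) stop("arc_span must be in (0, 360]", call. = FALSE)
  if (is.null(start_dir)) {
    ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    start_dir <- unit_vector(ref - sum(ref * n) * n)
  } else {
    start_dir <- unit_vector(start_dir - sum(start_dir * n) * n)
  }
  stopifnot(sweep %in% c(-1, 1))
  structure(list(true_normal = n, center = as.numeric(center), radius = radius,
                 arc_span = arc_span, n_points = as.integer(n_points),
                 start_dir = start_dir, sweep = sweep),
            class = "canal_spec")
}

#' Generate a canal arc polyline from its specification
#'
#' Points lie exactly on the circular arc in the plane through `center` with
#' normal `true_normal`; when `noise_sd > 0`, isotropic Gaussian noise is
#' added to interior points only, keeping both endpoints exact so junctions
#' weld across polylines.
#'
#' @param spec a [canal_spec()].
#' @param noise_sd isotropic noise standard deviation in mm (interior points).
#' @return an ordered n x 3 point matrix.
#' @export
make_canal_arc <- function(spec, noise_sd = 0) {
  stopifnot(inherits(spec, "canal_spec"))
  if (spec$n_points < 3) stop("n_points must be >= 3", call. = FALSE)
  u0 <- spec$start_dir
  w0 <- spec$sweep * cross3(spec$true_normal, u0)
  th <- seq(0, rad(spec$arc_span), length.out = spec$n_points)
  pts <- t(vapply(th, function(a)
    spec$center + spec$radius * (cos(a) * u0 + sin(a) * w0), numeric(3)))
  if (noise_sd > 0 && spec$n_points > 2) {
    interior <- 2:(spec$n_points - 1)
    pts[interior, ] <- pts[interior, ] +
      matrix(stats::rnorm(3 * length(interior), sd = noise_sd), ncol = 3)
  }
  pts
}

# Straight link polyline from p to q with noisy interior points.
straight_link <- function(p, q, n_points = 5, noise_sd = 0) {
  tt <- seq(0, 1, length.out = n_points)
  pts <- outer(1 - tt, p) + outer(tt, q)
  if (noise_sd > 0 && n_points > 2) {
    interior <- 2:(n_points - 1)
    pts[interior, ] <- pts[interior, ] +
      matrix(stats::rnorm(3 * length(interior), sd = noise_sd), ncol = 3)
  }
  pts
}

#' Triangulated sphere mesh (icosphere)
#'
#' Subdivided icosahedron oriented with vertices exactly at the inferior and
#' superior poles, so the lowest mesh vertex of an axis-aligned eyeball is the
#' exact tangent point of a horizontal plane.
#'
#' @param center sphere center (mm).
#' @param radius sphere radius (mm).
#' @param subdivisions recursive 4-way face subdivisions (0 = icosahedron).
#' @return list with `points` (n x 3) and `faces` (m x 3, 1-based).
#' @export
icosphere <- function(center = c(0, 0, 0), radius = 1, subdivisions = 2) {
  # polar icosahedron: poles plus two staggered rings of 5
  zr <- 1 / sqrt(5); rr <- 2 / sqrt(5)
  upper <- t(sapply(0:4, function(k) c(rr * cos(2 * pi * k / 5), rr * sin(2 * pi * k / 5), zr)))
  lower <- t(sapply(0:4, function(k) c(rr * cos(2 * pi * (k + 0.5) / 5), rr * sin(2 * pi * (k + 0.5) / 5), -zr)))
  pts <- rbind(c(0, 0, 1), upper, lower, c(0, 0, -1))
  iu <- 2:6; il <- 7:11
  faces <- NULL
  for (k in 0:4) {
    k1 <- (k + 1) %% 5
    faces <- rbind(faces,
                   c(1, iu[k + 1], iu[k1 + 1]),                 # top cap
                   c(iu[k + 1], il[k + 1], iu[k1 + 1]),         # upper band
                   c(iu[k1 + 1], il[k + 1], il[k1 + 1]),        # lower band
                   c(12, il[k1 + 1], il[k + 1]))                # bottom cap
  }
  for (s in seq_len(subdivisions)) {
    key <- function(m) apply(m, 1, function(p) paste(sprintf("%.17g", p), collapse = ","))
    new_faces <- matrix(0L, 0, 3)
    all_pts <- pts
    idx_of <- stats::setNames(seq_len(nrow(pts)), key(pts))
    get_idx <- function(p) {
      k <- paste(sprintf("%.17g", p), collapse = ",")
      i <- unname(idx_of[k])
      if (is.na(i)) {
        all_pts <<- rbind(all_pts, p)
        i <- nrow(all_pts)
        idx_of[k] <<- i
      }
      i
    }
    for (f in seq_len(nrow(faces))) {
      v <- faces[f, ]
      a <- pts[v[1], ]; b <- pts[v[2], ]; cc <- pts[v[3], ]
      ab <- unit_vector((a + b) / 2); bc <- unit_vector((b + cc) / 2); ca <- unit_vector((cc + a) / 2)
      i_ab <- get_idx(ab); i_bc <- get_idx(bc); i_ca <- get_idx(ca)
      new_faces <- rbind(new_faces,
                         c(v[1], i_ab, i_ca), c(v[2], i_bc, i_ab),
                         c(v[3], i_ca, i_bc), c(i_ab, i_bc, i_ca))
    }
    pts <- all_pts; faces <- new_faces
  }
  # outward orientation
  for (f in seq_len(nrow(faces))) {
    tri <- pts[faces[f, ], ]
    if (sum(cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ]) * colMeans(tri)) < 0)
      faces[f, ] <- faces[f, c(1, 3, 2)]
  }
  list(points = sweep(pts * radius, 2, center, `+`), faces = faces)
}

#' Specify a synthetic subject
#'
#' @param canal_normals 6 x 3 matrix of canal-plane unit normals in the
#'   standard frame, rows RP, RA, RH, LP, LA, LH (defaults to
#'   [standard_canal_normals()]).
#' @param crus_halfwidth distance from the midline to each common-crus
#'   bifurcation A, mm.
#' @param radii canal circle radii (mm), named posterior/superior/lateral;
#'   defaults 3.0/2.8/2.4 so arc lengths decrease posterior > superior >
#'   lateral.
#' @param arc_span canal arc span, degrees.
#' @param n_points points per canal arc.
#' @param noise_sd isotropic centerline noise sd, mm (interior points only).
#' @param eyeball_radius eyeball sphere radius, mm.
#' @param eyeball_centers list with `left`/`right` 3-vectors; the default puts
#'   the eyes anterior with their lowest vertex at the level of the crus
#'   bifurcations, the right eye 0.05 mm lower so the fundus fixed point is
#'   unique.
#' @param b_coincides_d build the lateral canal arc so its non-C endpoint B
#'   coincides exactly with the posterior endpoint D.
#' @param pose rigid pose `list(R = <3x3 rotation>, t = <3-vector>)` applied
#'   to all geometry, or `NULL` for identity.
#' @param seed integer seed for the noise draws (required; the generator never
#'   touches global RNG state outside it).
#' @return an object of class `subject_spec`.
#' @export
subject_spec <- function(canal_normals = standard_canal_normals(),
                         crus_halfwidth = 33,
                         radii = c(posterior = 3.0, superior = 2.8, lateral = 2.4),
                         arc_span = 240, n_points = 120,
                         noise_sd = 0.05,
                         eyeball_radius = 12,
                         eyeball_centers = list(left = c(30, 65, 12), right = c(-30, 65, 11.95)),
                         b_coincides_d = FALSE,
                         pose = NULL, seed = 1L) {
  stopifnot(is.matrix(canal_normals), nrow(canal_normals) == 6,
            all(c("RP", "RA", "RH", "LP", "LA", "LH") %in% rownames(canal_normals)))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (any(radii <= 0) || eyeball_radius <= 0 || crus_halfwidth <= 0)
    stop("radii, eyeball_radius and crus_halfwidth must be > 0", call. = FALSE)
  if (!is.null(pose)) stopifnot(is.matrix(pose$R), length(pose$t) == 3)
  if (is.null(seed)) stop("subject_spec requires a seed", call. = FALSE)
  structure(list(canal_normals = canal_normals, crus_halfwidth = crus_halfwidth,
                 radii = radii, arc_span = arc_span, n_points = as.integer(n_points),
                 noise_sd = noise_sd, eyeball_radius = eyeball_radius,
                 eyeball_centers = eyeball_centers, b_coincides_d = b_coincides_d,
                 pose = pose, seed = as.integer(seed)),
            class = "subject_spec")
}

# In-plane unit projection of direction d onto the plane with unit normal n.
inplane <- function(d, n) unit_vector(d - sum(d * n) * n)

# Canal spec whose arc starts at `start` and bulges toward `b` (in-plane),
# with tangent sign `wsign` selecting which way around the ring the far
# endpoint lies. Endpoints sit at +/- span/2 around the bulge direction.
canal_spec_from_start <- function(start, normal, radius, bulge, wsign,
                                  arc_span = 240, n_points = 120) {
  n <- unit_vector(normal)
  b <- inplane(bulge, n)
  w <- wsign * cross3(n, b)
  h <- rad(arc_span) / 2
  center <- start - radius * (cos(h) * b - sin(h) * w)
  canal_spec(n, center = center, radius = radius, arc_span = arc_span,
             n_points = n_points, start_dir = (start - center) / radius,
             sweep = wsign)
}

# Lateral arc forced through both C and D (the B = D coincident variant):
# tilt the requested normal minimally so C-D lies in-plane, then take the
# major arc of the circle through C and D.
canal_spec_through <- function(p, q, normal, radius, n_points = 120) {
  chord <- q - p
  L <- sqrt(sum(chord^2))
  n <- unit_vector(normal - sum(normal * chord) * chord / L^2)
  r <- max(radius, 0.51 * L)
  h <- sqrt(max(r^2 - (L / 2)^2, 0))
  mid <- (p + q) / 2
  center <- mid + h * unit_vector(cross3(n, chord))
  u0 <- (p - center) / r
  # major-arc span between the two endpoints
  v1 <- (q - center) / r
  ang <- acos(clamp(sum(u0 * v1)))
  span_deg <- 360 - deg(ang)
  # choose sweep sign that reaches q the long way round
  for (s in c(1, -1)) {
    w0 <- s * cross3(n, u0)
    endp <- center + r * (cos(rad(span_deg)) * u0 + sin(rad(span_deg)) * w0)
    if (sum((endp - q)^2) < 1e-16)
      return(canal_spec(n, center = center, radius = r, arc_span = span_deg,
                        n_points = n_points, start_dir = u0, sweep = s))
  }
  stop("could not construct arc through the requested endpoints", call. = FALSE)
}

#' Generate a synthetic subject
#'
#' Emits a [centerline_set()] realizing the labyrinth graph (see module
#' header), two icosphere eyeball surfaces, and the ground truth: key points
#' A-E per side, canal normals in the standard frame and in image
#' coordinates, designed junction coordinates, per-polyline arc lengths and
#' the applied pose.
#'
#' @param spec a [subject_spec()].
#' @param subject_id identifier stored in the centerline set.
#' @return list with elements `centerlines`, `eyeballs` (list left/right) and
#'   `truth`.
#' @export
make_subject <- function(spec, subject_id = "synthetic") {
  stopifnot(inherits(spec, "subject_spec"))
  withr::with_seed(spec$seed, make_subject_impl(spec, subject_id))
}

make_subject_impl <- function(spec, subject_id) {
  polylines <- list()
  meta <- list()
  truth_sides <- list()
  for (side in c("right", "left")) {
    sgn <- if (side == "left") 1 else -1
    code <- if (side == "left") "L" else "R"
    nP <- unit_vector(spec$canal_normals[paste0(code, "P"), ])
    nS <- unit_vector(spec$canal_normals[paste0(code, "A"), ])
    nH <- unit_vector(spec$canal_normals[paste0(code, "H"), ])
    A <- c(sgn * spec$crus_halfwidth, 0, 0)
    wsgn <- c(P = 1, S = 1, H = -1) * sgn

    sp_post <- canal_spec_from_start(A, nP, spec$radii[["posterior"]], c(0, -1, 0),
                                     wsgn[["P"]], spec$arc_span, spec$n_points)
    sp_sup  <- canal_spec_from_start(A, nS, spec$radii[["superior"]], c(0, 0, 1),
                                     wsgn[["S"]], spec$arc_span, spec$n_points)
    arc_post <- make_canal_arc(sp_post, spec$noise_sd)
    arc_sup  <- make_canal_arc(sp_sup, spec$noise_sd)
    # snap shared endpoints to the canonical junction doubles (bit-identical
    # across every polyline that meets there; displacement is ~1 ulp)
    arc_post[1, ] <- A
    arc_sup[1, ] <- A
    D <- arc_post[nrow(arc_post), ]
    C <- arc_sup[nrow(arc_sup), ]
    if (spec$b_coincides_d) {
      sp_lat <- canal_spec_through(C, D, nH, spec$radii[["lateral"]], spec$n_points)
    } else {
      sp_lat <- canal_spec_from_start(C, nH, spec$radii[["lateral"]], c(sgn, 0, 0),
                                      wsgn[["H"]], spec$arc_span, spec$n_points)
    }
    arc_lat <- make_canal_arc(sp_lat, spec$noise_sd)
    arc_lat[1, ] <- C
    if (spec$b_coincides_d) arc_lat[nrow(arc_lat), ] <- D
    B <- arc_lat[nrow(arc_lat), ]

    E <- A + c(sgn * 2.3, 2.0, -3.0)
    cochlea_end <- E + c(-sgn * 2.5, 5.5, -1.5)
    link_crus <- straight_link(A, E, 6, spec$noise_sd)
    link_DE <- straight_link(D, E, 5, spec$noise_sd)
    link_CE <- straight_link(C, E, 5, spec$noise_sd)
    line_cochlea <- straight_link(E, cochlea_end, 7, spec$noise_sd)

    side_polys <- list(arc_post, arc_sup, arc_lat, link_crus, link_DE, link_CE, line_cochlea)
    side_meta <- data.frame(
      side = side,
      role = c("posterior", "superior", "lateral", "crus", "link_DE", "link_CE", "cochlea"),
      stringsAsFactors = FALSE)
    polylines <- c(polylines, side_polys)
    meta <- c(meta, list(side_meta))
    truth_sides[[side]] <- list(
      key_points = rbind(A = A, B = B, C = C, D = D, E = E),
      junctions = if (spec$b_coincides_d) rbind(A, C, D, E) else rbind(A, C, E),
      normals = rbind(posterior = nP, superior = nS,
                      lateral = unit_vector(sp_lat$true_normal)))
  }
  meta <- do.call(rbind, meta)

  eyeballs <- lapply(c(left = "left", right = "right"), function(side)
    icosphere(spec$eyeball_centers[[side]], spec$eyeball_radius, subdivisions = 2))

  # rigid pose into image coordinates
  pose <- spec$pose
  posed_polylines <- lapply(polylines, apply_pose, pose = pose)
  posed_eyeballs <- lapply(names(eyeballs), function(side) {
    m <- eyeballs[[side]]
    eyeball_surface(apply_pose(m$points, pose), side = side, faces = m$faces)
  })
  names(posed_eyeballs) <- names(eyeballs)

  truth <- list(
    sides = lapply(truth_sides, function(ts) {
      list(key_points_image = apply_pose(ts$key_points, pose),
           key_points_standard = ts$key_points,
           junctions_image = apply_pose(ts$junctions, pose),
           normals_standard = ts$normals,
           normals_image = t(apply(ts$normals, 1, apply_pose_dir, pose = pose)))
    }),
    polyline_meta = meta,
    polyline_lengths = vapply(posed_polylines, polyline_length, numeric(1)),
    n_junctions = if (spec$b_coincides_d) 8L else 6L,
    pose = pose,
    noise_sd = spec$noise_sd,
    eyeball_centers = spec$eyeball_centers,
    eyeball_radius = spec$eyeball_radius)

  list(centerlines = centerline_set(posed_polylines, subject_id = subject_id),
       eyeballs = posed_eyeballs,
       truth = truth)
}

#' Specify a synthetic cohort
#'
#' @param n_subjects number of subjects (>= 1).
#' @param population_normals 6 x 3 matrix of population mean canal normals
#'   (rows RP, RA, RH, LP, LA, LH) in the standard frame.
#' @param kappa von Mises-Fisher concentration, length 1 or 6 (per canal);
#'   default calibrated so mean angular deviations match typical adult
#'   inter-subject dispersion (about 5-7 degrees).
#' @param noise_sd centerline point noise sd, mm.
#' @param random_pose apply an independent random rigid pose per subject.
#' @param seed integer seed (required); the entire cohort is reproducible
#'   from it.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 55,
                        population_normals = standard_canal_normals(),
                        kappa = kappa_for_deviation(default_canal_dispersion()),
                        noise_sd = 0.05, random_pose = TRUE, seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (any(kappa <= 0)) stop("kappa must be > 0", call. = FALSE)
  if (length(kappa) == 1) kappa <- rep(kappa, 6)
  kappa <- stats::setNames(as.numeric(kappa), rownames(population_normals))
  structure(list(n_subjects = as.integer(n_subjects),
                 population_normals = population_normals, kappa = kappa,
                 noise_sd = noise_sd, random_pose = random_pose,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Each subject's six canal normals are drawn independently from
#' vMF(population normal, kappa); each subject receives an independent random
#' rigid pose (when `random_pose`) and noise seed, all reproducible from the
#' cohort seed.
#'
#' @param spec a [cohort_spec()].
#' @return list with `subjects` (list of [make_subject()] outputs) and
#'   `truth` (per-subject drawn normals in the standard frame).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  canals <- rownames(spec$population_normals)
  withr::with_seed(spec$seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_subjects)
    subjects <- vector("list", spec$n_subjects)
    drawn <- vector("list", spec$n_subjects)
    for (i in seq_len(spec$n_subjects)) {
      normals <- t(vapply(canals, function(cn)
        as.numeric(rvmf(1, spec$population_normals[cn, ], spec$kappa[[cn]])),
        numeric(3)))
      rownames(normals) <- canals
      pose <- if (spec$random_pose)
        list(R = random_rotation(), t = stats::runif(3, -50, 50)) else NULL
      sspec <- subject_spec(canal_normals = normals, noise_sd = spec$noise_sd,
                            pose = pose, seed = sub_seeds[i])
      subjects[[i]] <- make_subject(sspec, subject_id = sprintf("sim%03d", i))
      drawn[[i]] <- normals
    }
    list(subjects = subjects,
         truth = list(normals_standard = drawn,
                      population_normals = spec$population_normals,
                      kappa = spec$kappa))
  })
}
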