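test_that("plane_from_points follows the sign convention and rejects collinear input", {
  pl <- plane_from_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(pl$normal, c(0, 0, 1))
  # any vertex order yields the same oriented plane
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    pts <- list(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))[perm]
    expect_equal(plane_from_points(pts[[1]], pts[[2]], pts[[3]])$normal, c(0, 0, 1))
  }
  expect_error(plane_from_points(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "collinear")
  # vertical plane: tie-break gives positive second component
  expect_equal(plane_from_points(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1))$normal, c(0, 1, 0))
})

test_that("signed_distance matches the direct formula and an optimization oracle", {
  pl <- plane3d(c(0, 0, 0), c(0, 0, 1))
  expect_equal(signed_distance(pl, c(0, 0, 5)), 5)
  expect_equal(signed_distance(pl, c(3, -2, 0)), 0)
  withr::with_seed(2, {
    for (i in 1:5) {
      p0 <- rnorm(3, sd = 10); n <- random_unit(); q <- rnorm(3, sd = 10)
      pl <- plane3d(p0, n)
      d <- signed_distance(pl, q)
      # orthogonal projection consistency: q - d n lies on the plane
      expect_lt(abs(signed_distance(pl, q - d * n)), 1e-12)
      # oracle: minimize ||q - x|| over x in the plane (2D parameterization)
      ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u <- ref - sum(ref * n) * n; u <- u / sqrt(sum(u^2))
      w <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3], n[1] * u[2] - n[2] * u[1])
      f <- function(ab) sum((q - (p0 + ab[1] * u + ab[2] * w))^2)
      opt <- stats::optim(c(0, 0), f, method = "BFGS", control = list(reltol = 1e-15))
      expect_equal(sqrt(opt$value), abs(d), tolerance = 1e-8)
    }
  })
})

test_that("fundus iteration finds the inferior tangent plane of spherical eyeballs", {
  crus_l <- c(33, 0, 0); crus_r <- c(-33, 0, 0)
  mk_eye <- function(center, side) {
    m <- icosphere(center, 12, subdivisions = 2)
    eyeball_surface(m$points, side = side, faces = m$faces)
  }
  eyes <- list(mk_eye(c(30, 65, 12), "left"), mk_eye(c(-30, 65, 11.95), "right"))
  fp <- fundus_point(eyes, crus_l, crus_r)
  expect_true(fp$converged)
  expect_identical(fp$side, "right")   # the lower eye supplies the fundus point
  # analytic tangency: plane through the x-axis touching the right sphere from
  # below; tangent point = center - r * unit normal of that plane
  cr <- c(-30, 65, 11.95); r <- 12
  # plane contains x-axis: normal (0, sin a, cos a); tangency: distance from
  # center equals r -> 65 sin a + 11.95 cos a = r (inferior solution)
  g <- function(a) 65 * sin(a) + 11.95 * cos(a) - r
  a <- uniroot(g, c(-0.2, 0.2), tol = 1e-14)$root
  n_an <- c(0, -sin(a), cos(a))  # superior-oriented normal, tilted about x
  tangent <- cr - r * n_an
  edge <- 12 * 1.0515 / 4 * 1.1   # icosahedron edge / 2 subdivisions, slack
  expect_lt(sqrt(sum((fp$point - tangent)^2)), edge)
  expect_lt(angle_deg(fp$plane$normal, n_an), 1.5)
  # inferior excursion is monotone non-decreasing across iterations
  expect_true(all(diff(fp$inferior_trace) >= -1e-12))
  # an already-horizontal configuration converges immediately
  eyes2 <- list(mk_eye(c(30, 65, 12), "left"), mk_eye(c(-30, 65, 12.4), "right"))
  fp2 <- fundus_point(eyes2, crus_l, crus_r)
  expect_identical(fp2$iterations, 1L)
  # a rigidly moved copy selects the same vertex index (with a superior hint)
  pose <- withr::with_seed(12, random_pose())
  eyes_p <- lapply(eyes, function(e)
    eyeball_surface(pose_points(e$points, pose), side = e$side, faces = e$faces))
  hint <- as.numeric(pose$R %*% c(0, 0, 1))
  fp_p <- fundus_point(eyes_p, pose_points(rbind(crus_l), pose)[1, ],
                       pose_points(rbind(crus_r), pose)[1, ], superior_hint = hint)
  expect_identical(fp_p$index, fp$index)
})

test_that("build_frame constructs the documented axis conventions", {
  pl <- plane3d(c(0, 0, -10), c(0, 0, 1))
  fr <- build_frame(crus_left = c(40, 0, 0), crus_right = c(-40, 0, 0), pl)
  expect_equal(fr$axes[, "X"], c(1, 0, 0), ignore_attr = TRUE)
  expect_equal(fr$axes[, "Z"], c(0, 0, 1), ignore_attr = TRUE)
  expect_equal(fr$axes[, "Y"], c(0, 1, 0), ignore_attr = TRUE)
  expect_equal(fr$origin, c(0, 0, 0))
  ras <- build_frame(c(40, 0, 0), c(-40, 0, 0), pl, convention = "ras")
  expect_equal(ras$axes[, "X"], c(-1, 0, 0), ignore_attr = TRUE)
  expect_equal(ras$axes[, "Y"], c(0, -1, 0), ignore_attr = TRUE)
  # axes orthonormal for arbitrary valid input
  withr::with_seed(3, {
    for (i in 1:10) {
      n <- random_unit()
      cl <- rnorm(3, sd = 30); cr <- cl + 60 * random_unit()
      x <- (cl - cr) / sqrt(sum((cl - cr)^2))
      if (abs(sum(x * n)) > 0.95) next   # skip near-parallel draws
      fr <- build_frame(cl, cr, plane3d(rnorm(3), n))
      expect_lt(max(abs(crossprod(fr$axes) - diag(3))), 1e-10)
    }
  })
  expect_error(build_frame(c(0.4, 0, 0), c(0, 0, 0), pl), "separation")
  expect_error(build_frame(c(0, 0, 40), c(0, 0, -40), pl), "parallel")
})

test_that("to_frame/from_frame are inverse and behave on points vs directions", {
  pl <- plane3d(c(0, 0, 0), c(0.1, -0.2, 1))
  fr <- build_frame(c(35, 2, 1), c(-33, -1, 0), pl)
  expect_equal(to_frame(fr$origin, fr), c(0, 0, 0))
  withr::with_seed(4, {
    pts <- matrix(rnorm(30, sd = 20), 10, 3)
    expect_equal(from_frame(to_frame(pts, fr), fr), pts, tolerance = 1e-12)
    v <- random_unit()
    vf <- to_frame(v, fr, is_direction = TRUE)
    expect_equal(sqrt(sum(vf^2)), 1, tolerance = 1e-12)  # directions keep length
    expect_equal(from_frame(vf, fr, is_direction = TRUE), v, tolerance = 1e-12)
  })
  id <- structure(list(origin = c(0, 0, 0), axes = diag(3), convention = "las"),
                  class = "head_frame")
  expect_equal(to_frame(c(1, 2, 3), id), c(1, 2, 3))
})

test_that("in-frame geometry is invariant under rigid motion of the whole subject", {
  sub0 <- make_subject(subject_spec(seed = 18))
  res0 <- analyze_subject(sub0$centerlines, sub0$eyeballs)
  withr::with_seed(19, poses <- replicate(3, random_pose(), simplify = FALSE))
  for (pose in poses) {
    sub1 <- make_subject(subject_spec(seed = 18, pose = pose))
    res1 <- analyze_subject(sub1$centerlines, sub1$eyeballs)
    a0 <- attitude_table(res0$attitudes); a1 <- attitude_table(res1$attitudes)
    key <- function(a) paste(a$side, a$canal)
    a1 <- a1[match(key(a0), key(a1)), ]
    for (i in 1:6)
      expect_lt(angle_deg(as.numeric(a0[i, c("nx", "ny", "nz")]),
                          as.numeric(a1[i, c("nx", "ny", "nz")])), 0.01)
    for (side in c("left", "right"))
      expect_lt(max(abs(to_frame(res0$key_points[[side]], res0$frame) -
                        to_frame(res1$key_points[[side]], res1$frame))), 1e-6)
  }
})
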