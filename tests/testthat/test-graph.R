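test_that("junctions require at least three welded polyline incidences", {
  p <- c(1, 2, 3)
  three <- centerline_set(list(rbind(c(0, 0, 0), p),
                               rbind(c(5, 0, 0), p),
                               rbind(c(0, 5, 0), p)))
  j <- find_junctions(three)
  expect_equal(nrow(j), 1)
  expect_equal(j$multiplicity, 3L)
  expect_equal(as.numeric(j[1, 1:3]), p)
  two <- centerline_set(list(rbind(c(0, 0, 0), p), rbind(c(5, 0, 0), p)))
  expect_equal(nrow(find_junctions(two)), 0)
  expect_error(find_junctions(three, weld_tol = -1), "weld_tol")
})

test_that("junctions closer than min_separation merge", {
  p <- c(0, 0, 0); q <- c(0.4, 0, 0)
  cs <- centerline_set(list(rbind(c(-5, 0, 0), p), rbind(c(0, -5, 0), p), rbind(c(0, 0, -5), p),
                            rbind(c(5, 5, 0), q), rbind(c(5, 0, 5), q), rbind(c(5, -5, 0), q)))
  expect_equal(nrow(find_junctions(cs, min_separation = 1.0)), 1)
  expect_equal(nrow(find_junctions(cs, min_separation = 0.1)), 2)
})

test_that("junctions touching only short spurious segments are pruned", {
  p <- c(0, 0, 0)
  tiny <- lapply(list(c(0.8, 0, 0), c(0, 0.8, 0), c(0, 0, 0.8)),
                 function(q) rbind(q, p))
  long <- rbind(c(10, 10, 10), c(5, 5, 5), c(5, 5, -5))
  cs <- centerline_set(c(tiny, list(long)))
  j <- find_junctions(cs)
  expect_equal(nrow(j), 1)   # the tiny crossing is a raw junction
  segs <- extract_segments(cs, j)
  expect_equal(nrow(canalplane:::prune_junctions(j, segs, min_arc = 2.0)), 0)
  expect_equal(nrow(canalplane:::prune_junctions(j, segs, min_arc = 0.5)), 1)
})

test_that("polylines split at interior junctions; lengths are preserved exactly", {
  origin <- c(0, 0, 0)
  through <- rbind(c(-4, 0, 0), c(-2, 0, 0), origin, c(2, 0, 0), c(4, 0, 0))
  enders <- list(rbind(c(0, 5, 0), origin), rbind(c(0, 0, 5), origin), rbind(c(0, -5, 0), origin))
  cs <- centerline_set(c(list(through), enders))
  j <- find_junctions(cs)
  expect_equal(nrow(j), 1)
  segs <- extract_segments(cs, j)
  from_through <- Filter(function(s) s$polyline == 1, segs)
  expect_length(from_through, 2)
  expect_equal(sum(vapply(from_through, `[[`, 1, "arc_length")), 8)  # split preserves length
  # straight 10 mm polyline with no junctions stays one segment of exact length
  straight <- centerline_set(list(rbind(c(0, 0, 0), c(3, 0, 0), c(10, 0, 0))))
  s <- extract_segments(straight, find_junctions(straight))
  expect_length(s, 1)
  expect_identical(s[[1]]$arc_length, 10)
})

test_that("synthetic subject segments match the generator's designed lengths", {
  sub <- make_subject(subject_spec(seed = 14))
  j <- find_junctions(sub$centerlines)
  segs <- extract_segments(sub$centerlines, j)
  expect_length(segs, length(sub$centerlines$polylines))  # junctions only at endpoints
  expect_equal(vapply(segs, `[[`, 1, "arc_length"),
               unname(sub$truth$polyline_lengths), tolerance = 1e-12)
})

test_that("side splitting separates the two labyrinths and names them by eyeball proximity", {
  sub <- make_subject(subject_spec(seed = 15, pose = list(R = random_rotation(), t = c(10, -20, 5))))
  segs <- extract_segments(sub$centerlines, find_junctions(sub$centerlines))
  segs <- split_sides(segs, sub$eyeballs)
  sides <- vapply(segs, `[[`, "", "side")
  expect_setequal(unique(sides), c("left", "right"))
  expect_equal(sum(sides == "left"), 7)
  meta_sides <- sub$truth$polyline_meta$side
  expect_identical(sides, meta_sides[vapply(segs, `[[`, 1L, "polyline")])
})

test_that("position rules label rings directly: rearmost/uppermost/outermost", {
  mk <- function(normal, center, radius)
    list(path = circle_points(normal, center, radius, n = 60, span_deg = 240),
         arc_length = radius * 240 * pi / 180,
         endpoints = NULL, polyline = NA, side = "left")
  segs <- list(mk(c(0, 0.3, 0.954), c(33, -6, 1), 3.0),    # rearmost midpoint
               mk(c(-0.7, 0.6, 0.33), c(33, -1, 6), 2.8),  # uppermost
               mk(c(0, -0.3, 0.954), c(39, -1, 1), 2.4))   # outermost
  for (i in seq_along(segs)) {
    segs[[i]]$endpoints <- rbind(segs[[i]]$path[1, ], segs[[i]]$path[nrow(segs[[i]]$path), ])
    segs[[i]]$arc_length <- canalplane:::polyline_length(segs[[i]]$path)
  }
  canals <- identify_canals(segs)
  labels <- vapply(canals, `[[`, "", "canal")
  expect_identical(labels, c("posterior", "superior", "lateral"))
  expect_length(attr(canals, "warnings"), 0)
  # size-order conflict: lateral ring bigger than posterior -> position wins, warning raised
  segs_conflict <- segs
  segs_conflict[[3]] <- mk(c(0, -0.3, 0.954), c(39, -1, 1), 3.5)
  segs_conflict[[3]]$endpoints <- rbind(segs_conflict[[3]]$path[1, ],
                                        segs_conflict[[3]]$path[nrow(segs_conflict[[3]]$path), ])
  canals2 <- identify_canals(segs_conflict)
  expect_identical(vapply(canals2, `[[`, "", "canal"),
                   c("posterior", "superior", "lateral"))
  expect_match(attr(canals2, "warnings"), "violate posterior > superior > lateral")
  # fewer than 3 ring candidates is an identification error
  expect_error(identify_canals(segs[1:2]), "ring candidates")
})

test_that("key points A-E match ground truth exactly on default subjects", {
  sub <- make_subject(subject_spec(seed = 16))
  res <- analyze_subject(sub$centerlines, sub$eyeballs)
  for (side in c("left", "right"))
    expect_equal(res$key_points[[side]],
                 sub$truth$sides[[side]]$key_points_image, tolerance = 1e-12)
})

test_that("junctions, labels and key points are invariant to polyline order and direction", {
  sub <- make_subject(subject_spec(seed = 17))
  res0 <- analyze_subject(sub$centerlines, sub$eyeballs)
  withr::with_seed(99, {
    perm <- sample(length(sub$centerlines$polylines))
    polys <- sub$centerlines$polylines[perm]
    flip <- sample(c(TRUE, FALSE), length(polys), replace = TRUE)
    polys[flip] <- lapply(polys[flip], function(m) m[nrow(m):1, , drop = FALSE])
  })
  shuffled <- centerline_set(polys, subject_id = "shuffled")
  res1 <- analyze_subject(shuffled, sub$eyeballs)
  expect_equal(nrow(res1$junctions), nrow(res0$junctions))
  for (side in c("left", "right"))
    expect_equal(res1$key_points[[side]], res0$key_points[[side]], tolerance = 1e-9)
  lab0 <- sort(paste(vapply(res0$canals, `[[`, "", "side"), vapply(res0$canals, `[[`, "", "canal")))
  lab1 <- sort(paste(vapply(res1$canals, `[[`, "", "side"), vapply(res1$canals, `[[`, "", "canal")))
  expect_identical(lab1, lab0)
})

test_that("posterior and superior arcs sharing no endpoint is a topology error", {
  mk <- function(normal, center, radius, side = "left") {
    path <- circle_points(normal, center, radius, n = 60, span_deg = 240)
    list(path = path, arc_length = canalplane:::polyline_length(path),
         endpoints = rbind(path[1, ], path[nrow(path), ]), polyline = NA, side = side)
  }
  segs <- list(mk(c(0, 0.3, 0.954), c(33, -6, 1), 3.0),
               mk(c(-0.7, 0.6, 0.33), c(33, -1, 6), 2.8),
               mk(c(0, -0.3, 0.954), c(39, -1, 1), 2.4))
  canals <- identify_canals(segs)
  expect_error(identify_key_points(canals, segs), "share no endpoint")
})
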