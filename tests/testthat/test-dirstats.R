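test_that("vector mean is the normalized componentwise sum", {
  v <- c(0.2, -0.4, 0.89); v <- v / sqrt(sum(v^2))
  expect_equal(vector_mean(rbind(v, v, v)), v)
  expect_equal(vector_mean(rbind(c(1, 0, 0), c(0, 1, 0))),
               c(sqrt(2) / 2, sqrt(2) / 2, 0))
  withr::with_seed(1, {
    m <- rvmf(100, c(0, 0.6, 0.8), 50)
    # independent summation oracle: explicit componentwise loop
    s <- c(0, 0, 0)
    for (i in seq_len(nrow(m))) s <- s + m[i, ]
    expect_equal(vector_mean(m), s / sqrt(sum(s^2)), tolerance = 1e-14)
    # order and duplication invariance
    expect_equal(vector_mean(m[sample(100), ]), vector_mean(m))
    expect_equal(vector_mean(rbind(m, m)), vector_mean(m))
  })
  expect_error(vector_mean(rbind(c(0, 0, 1), c(0, 0, -1))), "resultant")
})

test_that("angle mean averages each direction angle and reports its cosines", {
  v <- c(-0.651, 0.702, 0.287) / sqrt(sum(c(-0.651, 0.702, 0.287)^2))
  am <- angle_mean(rbind(v, v, v))
  expect_equal(unname(am$mean_deg), unname(direction_angles(v, unit_tol = 1e-9)))
  expect_equal(unname(am$sd_deg), c(0, 0, 0))
  am2 <- angle_mean(rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(unname(am2$mean_deg), c(45, 45, 90))
  expect_equal(am2$cosine, c(sqrt(2) / 2, sqrt(2) / 2, 0))
  withr::with_seed(2, {
    m <- rvmf(40, c(0.3, -0.3, 0.9), 80)
    am3 <- angle_mean(m)
    # independently coded per-component arccos-average oracle
    for (j in 1:3) {
      angs <- 180 / pi * acos(m[, j])
      expect_equal(unname(am3$mean_deg[j]), mean(angs), tolerance = 1e-12)
      expect_equal(unname(am3$sd_deg[j]), stats::sd(angs), tolerance = 1e-12)
    }
  })
  expect_error(angle_mean(rbind(c(1, 0, 0))), "n >= 2")
})

test_that("deviation range summarizes angles to the mean direction", {
  v <- c(0, 0, 1)
  expect_equal(deviation_range(rbind(v, v, v), v), c(mean_deg = 0, sd_deg = 0))
  tilt <- function(a) c(sin(a * pi / 180), 0, cos(a * pi / 180))
  expect_equal(deviation_range(rbind(tilt(10), tilt(-10)), v),
               c(mean_deg = 10, sd_deg = 0), tolerance = 1e-12)
  expect_error(deviation_range(rbind(v), v), "n >= 2")
})

test_that("the vector mean beats random directions on mean angular deviation", {
  withr::with_seed(3, {
    m <- rvmf(60, c(0.2, 0.5, 0.84), 120)
    vm <- vector_mean(m)
    base <- deviation_range(m, vm)[["mean_deg"]]
    for (i in 1:1000) {
      r <- random_unit()
      expect_lte(base, deviation_range(m, r)[["mean_deg"]] + 1e-9)
    }
  })
})

test_that("vMF calibration puts simulated deviation ranges in the observed regime", {
  withr::with_seed(4, {
    k <- kappa_for_deviation(6.9)
    m <- rvmf(55, c(0, -0.3, 0.954) / sqrt(sum(c(0, -0.3, 0.954)^2)), k)
    dev <- deviation_range(m, vector_mean(m))
    expect_equal(dev[["mean_deg"]], 6.9, tolerance = 1 / 6.9)  # within 1 degree
  })
})

test_that("method difference is the angle between the two mean normals", {
  v <- c(0.1, 0.3, 0.95); v <- v / sqrt(sum(v^2))
  expect_equal(method_difference(v, v), 0)
  expect_equal(method_difference(v, -v), 180)
  withr::with_seed(5, {
    tight <- rvmf(55, v, 1e4)
    md <- method_difference(vector_mean(tight), angle_mean(tight)$unit)
    expect_lt(md, 0.1)
    tighter <- rvmf(55, v, 1e6)
    expect_lt(method_difference(vector_mean(tighter), angle_mean(tighter)$unit), 0.01)
  })
})

test_that("angle-mean cosine norm approaches 1 as dispersion vanishes", {
  withr::with_seed(6, {
    norms <- vapply(c(10, 1e2, 1e3, 1e4), function(k)
      sqrt(sum(angle_mean(rvmf(200, c(0.4, 0.4, 0.825), k))$cosine^2)), numeric(1))
    expect_true(all(diff(norms) > 0))   # monotone toward 1
    expect_lt(abs(norms[4] - 1), 1e-3)
    expect_true(all(norms < 1 + 1e-12))
  })
})

test_that("summarize_cohort aggregates per canal and handles edge cases", {
  pop <- standard_canal_normals()
  mk_rows <- function(codes, n) do.call(rbind, lapply(codes, function(code) {
    m <- matrix(pop[code, ], n, 3, byrow = TRUE)
    data.frame(side = ifelse(substr(code, 1, 1) == "L", "left", "right"),
               canal = unname(c(P = "posterior", A = "superior", H = "lateral")[substr(code, 2, 2)]),
               nx = m[, 1], ny = m[, 2], nz = m[, 3])
  }))
  # identical subjects: summary equals the subject, zero deviations
  s <- summarize_cohort(mk_rows(rownames(pop), 4))
  for (code in rownames(pop)) {
    expect_equal(s$groups[[code]]$vector_mean, unname(pop[code, ]), tolerance = 1e-12)
    expect_equal(s$groups[[code]]$deviation_mean_deg, 0, tolerance = 1e-6)
    expect_equal(s$groups[[code]]$method_difference_deg, 0, tolerance = 1e-6)
  }
  # missing groups are warned about and omitted
  s2 <- summarize_cohort(mk_rows(c("RP", "RA"), 3))
  expect_length(s2$groups, 2)
  expect_true(any(grepl("omitted", s2$warnings)))
  # n = 1: means defined, sds flagged undefined
  s3 <- summarize_cohort(mk_rows("LP", 1))
  expect_equal(s3$groups$LP$vector_mean, unname(pop["LP", ]))
  expect_true(is.na(s3$groups$LP$deviation_sd_deg))
  expect_true(any(grepl("n = 1", s3$warnings)))
})

test_that("sphere scatter export writes checkable point and arrow coordinates", {
  normals <- data.frame(canal = rep(c("RP", "RA", "RH", "LP", "LA", "LH"), each = 2),
                        nx = 0, ny = 0, nz = 1)
  means <- data.frame(canal = c("RP", "RA", "RH", "LP", "LA", "LH"), nx = 0, ny = 0, nz = 1)
  path <- withr::local_tempfile(fileext = ".png")
  out <- export_sphere_scatter(normals, means, radius = 100, path = path)
  doc <- jsonlite::fromJSON(out$json, simplifyVector = FALSE)
  expect_length(doc$points, nrow(normals))
  expect_length(doc$arrows, 6)
  expect_equal(doc$points[[1]]$z, 100)      # unit z maps to the display radius
  single <- export_sphere_scatter(data.frame(canal = "RP", nx = 0, ny = 0, nz = 1),
                                  path = withr::local_tempfile(fileext = ".png"))
  dd <- jsonlite::fromJSON(single$json, simplifyVector = FALSE)
  expect_equal(c(dd$points[[1]]$x, dd$points[[1]]$y, dd$points[[1]]$z), c(0, 0, 100))
})
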