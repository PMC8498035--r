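# Shared helpers: small geometric fixtures and independent oracles.

# atan2 form is accurate down to the smallest angles (acos loses precision
# near parallel vectors)
angle_deg <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  180 / pi * atan2(sqrt(sum(cr^2)), sum(a * b))
}

# angle ignoring normal sign (planes are unsigned)
axis_angle_deg <- function(a, b) min(angle_deg(a, b), angle_deg(a, -b))

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# points on a circle of given normal/center/radius (exact, noise-free)
circle_points <- function(normal, center = c(0, 0, 0), radius = 1,
                          n = 50, span_deg = 360) {
  normal <- normal / sqrt(sum(normal^2))
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * normal) * normal; u <- u / sqrt(sum(u^2))
  w <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  th <- seq(0, span_deg * pi / 180, length.out = n)
  t(sapply(th, function(a) center + radius * (cos(a) * u + sin(a) * w)))
}

# Independent orthogonal-fit oracle: exhaustive search over sphere directions
# (2 degree grid) minimizing the perpendicular residual sum of squares,
# refined locally with Nelder-Mead. Never calls the package's fit.
grid_search_normal <- function(points) {
  centered <- sweep(points, 2, colMeans(points))
  az <- seq(0, 358, by = 2) * pi / 180
  el <- seq(-88, 88, by = 2) * pi / 180
  grid <- expand.grid(az = az, el = el)
  N <- rbind(cos(grid$el) * cos(grid$az), cos(grid$el) * sin(grid$az), sin(grid$el))
  rss <- colSums((centered %*% N)^2)
  best <- which.min(rss)
  f <- function(p) {
    n <- c(cos(p[2]) * cos(p[1]), cos(p[2]) * sin(p[1]), sin(p[2]))
    sum((centered %*% n)^2)
  }
  opt <- stats::optim(c(grid$az[best], grid$el[best]), f,
                      control = list(reltol = 1e-14, maxit = 2000))
  p <- opt$par
  c(cos(p[2]) * cos(p[1]), cos(p[2]) * sin(p[1]), sin(p[2]))
}

random_pose <- function() list(R = random_rotation(), t = stats::runif(3, -50, 50))

pose_points <- function(pts, pose) sweep(pts %*% t(pose$R), 2, pose$t, `+`)
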