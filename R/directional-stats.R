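# Cohort-level directional statistics of canal plane normals.
#
# Two summaries are computed per canal: the vector mean (normalized sum of
# the unit normals — the proper mean direction) and the traditional angle
# mean (arithmetic mean of each direction angle, whose cosines form a
# generally non-unit vector). The angle between the two summarizes how much
# the traditional method deviates; it vanishes as the sample concentrates.

as_normal_matrix <- function(normals) {
  m <- if (is.matrix(normals)) normals else do.call(rbind, normals)
  m <- as_point_matrix(m, "normals")
  norms <- sqrt(rowSums(m^2))
  if (any(abs(norms - 1) > 1e-6))
    stop("all normals must be unit vectors", call. = FALSE)
  m
}

#' Mean direction of unit normals (vector method)
#'
#' Normalized componentwise sum of the input unit vectors.
#'
#' @param normals n x 3 matrix (or list) of unit vectors, n >= 1.
#' @return unit 3-vector.
#' @export
vector_mean <- function(normals) {
  m <- as_normal_matrix(normals)
  s <- colSums(m)
  if (sqrt(sum(s^2)) <= 1e-9)
    stop("mean direction undefined: resultant length is (near) zero", call. = FALSE)
  unit_vector(s)
}

#' Mean direction angles (traditional angle method)
#'
#' Per axis, the arithmetic mean and sample standard deviation (n - 1
#' denominator) of the arccosines of the components, in degrees; the cosines
#' of the mean angles form the angle-method vector, returned both as-is
#' (generally non-unit) and unit-normalized.
#'
#' @param normals n x 3 matrix (or list) of unit vectors, n >= 2.
#' @return list with `mean_deg`, `sd_deg` (length-3, sagittal/coronal/
#'   horizontal), `cosine` (the non-unit vector of cosines) and `unit` (its
#'   normalized copy).
#' @export
angle_mean <- function(normals) {
  m <- as_normal_matrix(normals)
  if (nrow(m) < 2) stop("angle_mean needs n >= 2 for a standard deviation", call. = FALSE)
  ang <- deg(acos(clamp(m)))
  mean_deg <- colMeans(ang)
  sd_deg <- apply(ang, 2, stats::sd)
  cosine <- cos(rad(mean_deg))
  nms <- c("sagittal", "coronal", "horizontal")
  list(mean_deg = stats::setNames(mean_deg, nms),
       sd_deg = stats::setNames(sd_deg, nms),
       cosine = cosine, unit = unit_vector(cosine))
}

#' Angular deviation range about a mean direction
#'
#' Angles between each unit normal and the mean direction, summarized as
#' sample mean and standard deviation (degrees).
#'
#' @param normals n x 3 matrix (or list) of unit vectors, n >= 2.
#' @param mean unit 3-vector (typically the [vector_mean()]).
#' @return named vector `c(mean_deg, sd_deg)`.
#' @export
deviation_range <- function(normals, mean) {
  m <- as_normal_matrix(normals)
  if (nrow(m) < 2) stop("deviation_range needs n >= 2", call. = FALSE)
  mean <- as.numeric(mean)
  if (abs(sqrt(sum(mean^2)) - 1) > 1e-6) stop("mean must be a unit vector", call. = FALSE)
  dots <- as.numeric(m %*% mean)
  if (any(abs(dots) > 1 + 1e-9)) stop("dot products outside [-1, 1]", call. = FALSE)
  a <- deg(acos(clamp(dots)))
  c(mean_deg = mean(a), sd_deg = stats::sd(a))
}

#' Angle between the vector-method and angle-method mean normals
#'
#' @param v_vec unit vector from [vector_mean()].
#' @param v_ang_unit unit-normalized cosine vector from [angle_mean()].
#' @return angle in degrees.
#' @export
method_difference <- function(v_vec, v_ang_unit) {
  deg(acos(clamp(sum(unit_vector(v_vec) * unit_vector(v_ang_unit)))))
}

canal_code <- function(side, canal) {
  paste0(ifelse(side == "left", "L", "R"),
         c(posterior = "P", superior = "A", lateral = "H")[canal])
}

#' Summarize a cohort of canal attitudes
#'
#' Groups attitudes by side and canal and applies [vector_mean()],
#' [angle_mean()], [deviation_range()] (against the vector mean) and
#' [method_difference()] per group. Groups of size 1 get defined means with
#' standard deviations flagged as `NA`; expected groups with no attitudes
#' are listed in a completeness warning and omitted.
#'
#' @param attitudes data.frame with columns `side`, `canal`, `nx`, `ny`,
#'   `nz` (unit normals in the head frame), one row per subject-canal; see
#'   [attitude_table()].
#' @return an object of class `cohort_summary`: `groups` (per canal-code
#'   list of statistics), `table` (long data.frame), `warnings`.
#' @export
summarize_cohort <- function(attitudes) {
  stopifnot(is.data.frame(attitudes),
            all(c("side", "canal", "nx", "ny", "nz") %in% names(attitudes)))
  codes <- c("RP", "RA", "RH", "LP", "LA", "LH")
  attitudes$code <- canal_code(attitudes$side, attitudes$canal)
  warnings_out <- character(0)
  groups <- list()
  for (code in codes) {
    rows <- attitudes[attitudes$code == code, , drop = FALSE]
    if (nrow(rows) == 0) {
      warnings_out <- c(warnings_out, sprintf("no attitudes for canal %s; omitted", code))
      next
    }
    m <- as.matrix(rows[, c("nx", "ny", "nz")])
    vm <- vector_mean(m)
    if (nrow(m) >= 2) {
      am <- angle_mean(m)
      dev <- deviation_range(m, vm)
      md <- method_difference(vm, am$unit)
    } else {
      warnings_out <- c(warnings_out, sprintf("canal %s has n = 1; standard deviations undefined", code))
      nms <- c("sagittal", "coronal", "horizontal")
      am <- list(mean_deg = direction_angles(vm, unit_tol = 1e-6),
                 sd_deg = stats::setNames(rep(NA_real_, 3), nms),
                 cosine = vm, unit = vm)
      dev <- c(mean_deg = 0, sd_deg = NA_real_)
      md <- 0
    }
    groups[[code]] <- list(
      canal = code, n = nrow(m),
      vector_mean = vm,
      vector_angles = direction_angles(vm, unit_tol = 1e-6),
      angle_mean_deg = am$mean_deg, angle_sd_deg = am$sd_deg,
      angle_cosine = am$cosine, angle_unit = am$unit,
      deviation_mean_deg = unname(dev["mean_deg"]),
      deviation_sd_deg = unname(dev["sd_deg"]),
      method_difference_deg = md)
  }
  if (length(groups) == 0) stop("no canal groups to summarize", call. = FALSE)
  tab <- do.call(rbind, lapply(groups, function(g) {
    rbind(
      data.frame(canal = g$canal, method = "vector",
                 sagittal_deg = g$vector_angles[["sagittal"]],
                 coronal_deg = g$vector_angles[["coronal"]],
                 horizontal_deg = g$vector_angles[["horizontal"]],
                 deviation_mean_deg = g$deviation_mean_deg,
                 deviation_sd_deg = g$deviation_sd_deg,
                 method_difference_deg = g$method_difference_deg,
                 n = g$n),
      data.frame(canal = g$canal, method = "angle",
                 sagittal_deg = g$angle_mean_deg[["sagittal"]],
                 coronal_deg = g$angle_mean_deg[["coronal"]],
                 horizontal_deg = g$angle_mean_deg[["horizontal"]],
                 deviation_mean_deg = NA_real_,
                 deviation_sd_deg = NA_real_,
                 method_difference_deg = g$method_difference_deg,
                 n = g$n))
  }))
  rownames(tab) <- NULL
  structure(list(groups = groups, table = tab, warnings = warnings_out),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d canal groups\n", length(x$groups)))
  vt <- x$table[x$table$method == "vector", ]
  for (i in seq_len(nrow(vt)))
    cat(sprintf("  %s (n=%d): sagittal %6.2f  coronal %6.2f  horizontal %6.2f  deviation %.2f +/- %s  method diff %.4f deg\n",
                vt$canal[i], vt$n[i], vt$sagittal_deg[i], vt$coronal_deg[i],
                vt$horizontal_deg[i], vt$deviation_mean_deg[i],
                ifelse(is.na(vt$deviation_sd_deg[i]), "NA", sprintf("%.2f", vt$deviation_sd_deg[i])),
                vt$method_difference_deg[i]))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
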