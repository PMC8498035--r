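# Result tables and the normal-vector sphere scatter export.

#' Collect canal attitudes into a long table
#'
#' @param attitude_lists list of per-subject attitude lists (each a list of
#'   [canal_attitude()] results), optionally named by subject.
#' @return data.frame with columns subject_id, side, canal, nx, ny, nz,
#'   sagittal_deg, coronal_deg, horizontal_deg, fit_rms.
#' @export
attitude_table <- function(attitude_lists) {
  if (length(attitude_lists) > 0 && !is.null(attitude_lists[[1]]$canal))
    attitude_lists <- list(attitude_lists)  # a single subject's list
  ids <- names(attitude_lists)
  if (is.null(ids)) ids <- sprintf("subject%03d", seq_along(attitude_lists))
  rows <- list()
  for (i in seq_along(attitude_lists)) for (a in attitude_lists[[i]]) {
    rows[[length(rows) + 1]] <- data.frame(
      subject_id = ids[i], side = a$side, canal = a$canal,
      nx = a$normal[1], ny = a$normal[2], nz = a$normal[3],
      sagittal_deg = a$angles[["sagittal"]],
      coronal_deg = a$angles[["coronal"]],
      horizontal_deg = a$angles[["horizontal"]],
      fit_rms = a$fit_rms)
  }
  do.call(rbind, rows)
}

#' Write a cohort summary as CSV (and a full-precision JSON mirror)
#'
#' One row per canal and method (vector, angle) with columns canal,
#' sagittal_deg, coronal_deg, horizontal_deg, deviation_mean_deg,
#' deviation_sd_deg, method. Angles are rounded to 2 decimals at write time
#' only; the JSON mirror keeps full precision.
#'
#' @param summary a [summarize_cohort()] result.
#' @param path output CSV path.
#' @param json also write `<path, .csv -> .json>` with full precision.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path, json = TRUE) {
  stopifnot(inherits(summary, "cohort_summary"))
  if (length(summary$groups) < 1) stop("summary is empty", call. = FALSE)
  tab <- summary$table[, c("canal", "sagittal_deg", "coronal_deg", "horizontal_deg",
                           "deviation_mean_deg", "deviation_sd_deg", "method")]
  tab <- tab[order(match(tab$method, c("vector", "angle"))), ]
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = 2)
  tryCatch(utils::write.csv(tab, path, row.names = FALSE, quote = FALSE),
           error = function(e) stop(sprintf("cannot write summary to '%s': %s",
                                            path, conditionMessage(e)), call. = FALSE))
  if (json) {
    jpath <- sub("\\.csv$", ".json", path)
    if (identical(jpath, path)) jpath <- paste0(path, ".json")
    jsonlite::write_json(summary$groups, jpath, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Export the normal-vector sphere scatter
#'
#' Scales each unit normal to a display sphere (radius 100 by default),
#' colors points by canal and draws the mean normals as arrows; writes a PNG
#' and a JSON companion with the exact point and arrow coordinates for
#' headless checking.
#'
#' @param normals data.frame with columns `canal` (group label) and `nx`,
#'   `ny`, `nz` unit-normal components.
#' @param means optional data.frame with the same columns, one row per group.
#' @param radius display sphere radius.
#' @param path output PNG path; the JSON companion replaces the extension
#'   with `.json`.
#' @return invisible list with `png` and `json` paths (`png` is `NA` if no
#'   graphics device is available).
#' @export
export_sphere_scatter <- function(normals, means = NULL, radius = 100, path) {
  stopifnot(is.data.frame(normals), nrow(normals) >= 1,
            all(c("canal", "nx", "ny", "nz") %in% names(normals)))
  jpath <- sub("\\.[A-Za-z]+$", ".json", path)
  if (identical(jpath, path)) jpath <- paste0(path, ".json")
  payload <- list(
    radius = radius,
    points = lapply(seq_len(nrow(normals)), function(i) list(
      canal = normals$canal[i],
      x = radius * normals$nx[i], y = radius * normals$ny[i], z = radius * normals$nz[i])),
    arrows = if (is.null(means)) list() else lapply(seq_len(nrow(means)), function(i) list(
      canal = means$canal[i],
      x = radius * means$nx[i], y = radius * means$ny[i], z = radius * means$nz[i])))
  jsonlite::write_json(payload, jpath, digits = NA, auto_unbox = TRUE)
  png_path <- tryCatch({
    grDevices::png(path, width = 1200, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    groups <- sort(unique(normals$canal))
    cols <- stats::setNames(grDevices::hcl.colors(max(3, length(groups)), "Dark 3")[seq_along(groups)], groups)
    graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    panels <- list(c(1, 2, "vertical view (x-y)"), c(1, 3, "back view (x-z)"))
    comp <- cbind(normals$nx, normals$ny, normals$nz) * radius
    mcomp <- if (is.null(means)) NULL else cbind(means$nx, means$ny, means$nz) * radius
    for (p in panels) {
      i <- as.integer(p[1]); j <- as.integer(p[2])
      graphics::plot(comp[, i], comp[, j], col = cols[normals$canal], pch = 16,
                     xlim = c(-radius, radius), ylim = c(-radius, radius),
                     xlab = c("x", "y", "z")[i], ylab = c("x", "y", "z")[j],
                     main = p[3], asp = 1)
      if (!is.null(mcomp)) {
        vis <- sqrt(mcomp[, i]^2 + mcomp[, j]^2) > 1e-6 * radius  # skip arrows seen end-on
        if (any(vis))
          graphics::arrows(0, 0, mcomp[vis, i], mcomp[vis, j],
                           col = cols[means$canal[vis]], lwd = 2, length = 0.1)
      }
    }
    graphics::legend("topright", legend = groups, col = cols[groups], pch = 16, cex = 0.8)
    path
  }, error = function(e) {
    warning(sprintf("could not render PNG (%s); JSON companion written", conditionMessage(e)))
    NA_character_
  })
  invisible(list(png = png_path, json = jpath))
}
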