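# Centerline polyline I/O.
#
# Native on-disk format is a small JSON dialect:
#   {"subject_id": "...", "units": "mm", "polylines": [[[x,y,z], ...], ...]}
# Coordinates are written with 17 significant digits so that a write/read
# round trip reproduces every double bit-for-bit. Junction coordinates shared
# by several polylines must be numerically identical across them; the graph
# stage relies on that (with a small weld tolerance as a guard).
#
# A best-effort reader for VTK XML PolyData (.vtp, ascii-encoded) is provided
# for interoperability with centerline-extraction tools.

#' Construct a centerline set
#'
#' A centerline set holds one subject's inner-ear centerline model as a list of
#' ordered 3D polylines in millimetres (image/scanner coordinates).
#'
#' @param polylines list of n x 3 numeric matrices (or lists of length-3
#'   points), each with at least 2 points and no zero-length steps.
#' @param subject_id character identifier.
#' @return an object of class `centerline_set`.
#' @export
centerline_set <- function(polylines, subject_id = "subject") {
  if (length(polylines) < 1) stop("centerline set needs at least one polyline", call. = FALSE)
  polylines <- lapply(seq_along(polylines), function(i) {
    m <- as_point_matrix(polylines[[i]], sprintf("polyline %d", i))
    validate_polyline(m, i)
    m
  })
  structure(list(subject_id = as.character(subject_id),
                 units = "mm",
                 polylines = polylines),
            class = "centerline_set")
}

validate_polyline <- function(m, i = NA) {
  lab <- if (is.na(i)) "polyline" else sprintf("polyline %d", i)
  if (nrow(m) < 2) stop(sprintf("%s has fewer than 2 points", lab), call. = FALSE)
  if (!all(is.finite(m))) stop(sprintf("%s contains non-finite coordinates", lab), call. = FALSE)
  steps <- sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))
  if (any(steps == 0))
    stop(sprintf("%s has coincident consecutive points (zero-length step at index %d)",
                 lab, which(steps == 0)[1]), call. = FALSE)
  invisible(m)
}

#' @export
print.centerline_set <- function(x, ...) {
  npts <- sum(vapply(x$polylines, nrow, 1L))
  cat(sprintf("<centerline_set> subject '%s': %d polylines, %d points (mm)\n",
              x$subject_id, length(x$polylines), npts))
  invisible(x)
}

#' Read a centerline set from disk
#'
#' @param path file path.
#' @param format `"json"` (native dialect) or `"vtp"` (VTK XML PolyData,
#'   ascii-encoded arrays only). Guessed from the file extension by default.
#' @return a [centerline_set()].
#' @export
read_centerlines <- function(path, format = c("auto", "json", "vtp")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vtp$", path, ignore.case = TRUE)) "vtp" else "json"
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  switch(format,
         json = read_centerlines_json(path),
         vtp  = read_centerlines_vtp(path))
}

read_centerlines_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop(sprintf("malformed centerline JSON '%s': %s",
                                                   path, conditionMessage(e)), call. = FALSE))
  if (is.null(doc$polylines)) stop(sprintf("'%s': missing 'polylines' element", path), call. = FALSE)
  if (!is.null(doc$units) && !identical(doc$units, "mm"))
    stop(sprintf("'%s': units must be 'mm', got '%s'", path, doc$units), call. = FALSE)
  centerline_set(doc$polylines,
                 subject_id = if (is.null(doc$subject_id)) "subject" else doc$subject_id)
}

read_centerlines_vtp <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop(sprintf("malformed VTP file '%s': %s",
                                                   path, conditionMessage(e)), call. = FALSE))
  pts_node <- xml2::xml_find_first(doc, ".//Piece/Points/DataArray")
  if (is.na(pts_node)) stop(sprintf("'%s': no <Points><DataArray> element", path), call. = FALSE)
  if (!identical(xml2::xml_attr(pts_node, "format"), "ascii"))
    stop(sprintf("'%s': only ascii-format VTP DataArrays are supported", path), call. = FALSE)
  coords <- scan(text = xml2::xml_text(pts_node), quiet = TRUE)
  pts <- matrix(coords, ncol = 3, byrow = TRUE)
  conn_node <- xml2::xml_find_first(doc, ".//Piece/Lines/DataArray[@Name='connectivity']")
  off_node  <- xml2::xml_find_first(doc, ".//Piece/Lines/DataArray[@Name='offsets']")
  if (is.na(conn_node) || is.na(off_node))
    stop(sprintf("'%s': missing <Lines> connectivity/offsets arrays", path), call. = FALSE)
  conn <- as.integer(scan(text = xml2::xml_text(conn_node), quiet = TRUE))
  offs <- as.integer(scan(text = xml2::xml_text(off_node), quiet = TRUE))
  starts <- c(1L, head(offs, -1L) + 1L)
  polylines <- lapply(seq_along(offs), function(i) {
    idx <- conn[starts[i]:offs[i]] + 1L  # VTK indices are 0-based
    pts[idx, , drop = FALSE]
  })
  subject_id <- sub("\\.vtp$", "", basename(path), ignore.case = TRUE)
  centerline_set(polylines, subject_id = subject_id)
}

#' Write a centerline set to the native JSON dialect
#'
#' Coordinates are serialized with 17 significant digits, so
#' `read_centerlines(write_centerlines(x, p))` reproduces `x` exactly.
#'
#' @param centerlines a [centerline_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_centerlines <- function(centerlines, path) {
  stopifnot(inherits(centerlines, "centerline_set"))
  doc <- list(subject_id = jsonlite::unbox(centerlines$subject_id),
              units = jsonlite::unbox("mm"),
              polylines = lapply(centerlines$polylines, function(m)
                lapply(seq_len(nrow(m)), function(i) m[i, ])))
  writeLines(jsonlite::toJSON(doc, digits = I(17)), path)
  invisible(path)
}
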