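# Eyeball surface I/O: STL (binary and ascii) meshes and plain xyz point
# clouds. The frame stage only needs the vertex cloud; faces are kept when
# available so meshes can be re-exported.

#' Construct an eyeball surface
#'
#' @param points n x 3 numeric matrix of vertices (mm).
#' @param side `"left"` or `"right"`.
#' @param faces optional m x 3 integer matrix of 1-based triangle indices.
#' @return an object of class `eyeball_surface`.
#' @export
eyeball_surface <- function(points, side = c("left", "right"), faces = NULL) {
  side <- match.arg(side)
  points <- as_point_matrix(points, "eyeball points")
  if (!all(is.finite(points))) stop("eyeball surface contains non-finite coordinates", call. = FALSE)
  if (nrow(points) < 4) stop("eyeball surface needs at least 4 points", call. = FALSE)
  # non-coplanarity: the centered cloud must have full rank 3
  s <- svd(scale(points, scale = FALSE), nu = 0, nv = 0)$d
  if (s[3] <= 1e-9 * max(s[1], 1))
    stop("eyeball points are (nearly) coplanar; a surface is required", call. = FALSE)
  if (!is.null(faces)) {
    faces <- matrix(as.integer(faces), ncol = 3)
    if (any(faces < 1L) || any(faces > nrow(points)))
      stop("face indices out of range", call. = FALSE)
  }
  structure(list(side = side, points = points, faces = faces),
            class = "eyeball_surface")
}

#' @export
print.eyeball_surface <- function(x, ...) {
  cat(sprintf("<eyeball_surface> side %s: %d vertices%s\n", x$side, nrow(x$points),
              if (is.null(x$faces)) "" else sprintf(", %d faces", nrow(x$faces))))
  invisible(x)
}

# Weld duplicated vertices (within 1e-9 mm) and remap faces.
weld_vertices <- function(points, faces = NULL, tol = 1e-9) {
  key <- apply(round(points / tol), 1, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])
  welded <- points[first, , drop = FALSE]
  if (!is.null(faces)) {
    new_index <- cumsum(first)
    faces <- matrix(new_index[map][faces], ncol = 3)
  }
  list(points = welded, faces = faces)
}

#' Read an eyeball surface from STL or xyz
#'
#' STL vertices duplicated across facets are welded (tolerance 1e-9 mm), so
#' binary and ascii encodings of the same mesh yield identical point sets.
#'
#' @param path file path.
#' @param side `"left"` or `"right"`.
#' @param format `"stl"` (dialect auto-detected) or `"xyz"`; guessed from the
#'   extension by default.
#' @return an [eyeball_surface()].
#' @export
read_eyeball <- function(path, side = c("left", "right"), format = c("auto", "stl", "xyz")) {
  side <- match.arg(side)
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (file.size(path) == 0) stop(sprintf("empty file: %s", path), call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.xyz$|\\.txt$", path, ignore.case = TRUE)) "xyz" else "stl"
  if (format == "xyz") {
    pts <- as.matrix(utils::read.table(path, col.names = c("x", "y", "z")))
    return(eyeball_surface(pts, side = side))
  }
  mesh <- if (is_ascii_stl(path)) read_stl_ascii(path) else read_stl_binary(path)
  w <- weld_vertices(mesh$points, mesh$faces)
  message(sprintf("read_eyeball: %d raw vertices welded to %d unique points (%s)",
                  nrow(mesh$points), nrow(w$points), basename(path)))
  eyeball_surface(w$points, side = side, faces = w$faces)
}

# An STL file is binary iff its size matches 84 + 50 * facet_count; ascii
# files start with "solid" but so may binary headers, hence the size check.
is_ascii_stl <- function(path) {
  size <- file.size(path)
  if (size < 84) return(TRUE)
  con <- file(path, "rb"); on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  !is.na(n) && size != 84 + 50 * n
}

# STL stores float32; ascii coordinates are quantized to float32 on read so
# both dialects of the same mesh yield bit-identical point sets.
float32_quantize <- function(x) {
  r <- writeBin(as.vector(x), raw(), size = 4, endian = "little")
  matrix(readBin(r, "numeric", n = length(x), size = 4, endian = "little"),
         nrow = nrow(x), ncol = ncol(x))
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0 || length(vlines) %% 3 != 0)
    stop(sprintf("'%s': no valid 'vertex' records (ascii STL)", path), call. = FALSE)
  coords <- scan(text = sub("^\\s*vertex\\s+", "", vlines), quiet = TRUE)
  pts <- float32_quantize(matrix(coords, ncol = 3, byrow = TRUE))
  list(points = pts, faces = matrix(seq_len(nrow(pts)), ncol = 3, byrow = TRUE))
}

read_stl_binary <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (is.na(n) || n < 1) stop(sprintf("'%s': invalid binary STL facet count", path), call. = FALSE)
  pts <- matrix(0, 3 * n, 3)
  for (i in seq_len(n)) {
    vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
    invisible(readBin(con, "raw", 2))  # attribute byte count
    if (length(vals) < 12) stop(sprintf("'%s': truncated binary STL at facet %d", path, i), call. = FALSE)
    pts[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  list(points = pts, faces = matrix(seq_len(3 * n), ncol = 3, byrow = TRUE))
}

#' Write an eyeball surface as STL
#'
#' @param eyeball an [eyeball_surface()] with faces.
#' @param path output path.
#' @param binary write the binary dialect (default) or ascii.
#' @return `path`, invisibly.
#' @export
write_eyeball_stl <- function(eyeball, path, binary = TRUE) {
  stopifnot(inherits(eyeball, "eyeball_surface"))
  if (is.null(eyeball$faces)) stop("cannot write STL without faces", call. = FALSE)
  pts <- eyeball$points; faces <- eyeball$faces
  facet_normal <- function(tri) {
    n <- cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    len <- sqrt(sum(n^2))
    if (len < 1e-300) c(0, 0, 0) else n / len
  }
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(faces)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(faces))) {
      tri <- pts[faces[i, ], , drop = FALSE]
      writeBin(c(facet_normal(tri), t(tri)), con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("solid eyeball", con)
    for (i in seq_len(nrow(faces))) {
      tri <- pts[faces[i, ], , drop = FALSE]
      nrm <- facet_normal(tri)
      writeLines(sprintf("  facet normal %.9e %.9e %.9e", nrm[1], nrm[2], nrm[3]), con)
      writeLines("    outer loop", con)
      for (j in 1:3)
        writeLines(sprintf("      vertex %.9e %.9e %.9e", tri[j, 1], tri[j, 2], tri[j, 3]), con)
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid eyeball", con)
  }
  invisible(path)
}
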