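# Subject-level analysis and the end-to-end pipeline
# (simulate -> identify -> frame -> fit -> summarize -> plot).

#' Pipeline parameters
#'
#' @param weld_tol junction welding tolerance, mm.
#' @param min_junction_separation junctions closer than this are merged, mm.
#' @param min_arc segments shorter than this are ignored when pruning
#'   junctions, mm.
#' @param min_ring_length minimum arc length of a canal-ring candidate, mm.
#' @param n_out spline resample count per canal arc.
#' @param max_iter fundus fixed-point iteration cap.
#' @param convention head-frame axis convention, `"las"` or `"ras"`.
#' @return a validated list of class `pipeline_params`.
#' @export
pipeline_params <- function(weld_tol = 1e-6, min_junction_separation = 1.0,
                            min_arc = 2.0, min_ring_length = 8.0,
                            n_out = 200, max_iter = 100,
                            convention = c("las", "ras")) {
  convention <- match.arg(convention)
  vals <- c(weld_tol = weld_tol, min_junction_separation = min_junction_separation,
            min_arc = min_arc, min_ring_length = min_ring_length,
            n_out = n_out, max_iter = max_iter)
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  if (identical(weld_tol, 0)) bad <- setdiff(bad, "weld_tol")  # 0 is a legal weld_tol
  if (length(bad))
    stop(sprintf("invalid pipeline parameters (must be positive): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  structure(c(as.list(vals), list(convention = convention)),
            class = "pipeline_params")
}

#' Analyze one subject: identify, frame, fit
#'
#' Runs the full per-subject chain: junction detection, segment extraction,
#' side splitting, a topological first pass locating the common-crus
#' bifurcations (the shared endpoint of the two longest ring segments per
#' side), fundus-plane iteration and frame construction, then in-frame canal
#' identification, key points, and per-canal plane fits.
#'
#' @param centerlines a [centerline_set()].
#' @param eyeballs list of [eyeball_surface()] (left and right).
#' @param params a [pipeline_params()].
#' @return list: `frame`, `fundus`, `key_points` (per side), `canals`,
#'   `attitudes` (list of [canal_attitude()]), `junctions`, `warnings`.
#' @export
analyze_subject <- function(centerlines, eyeballs, params = pipeline_params()) {
  stopifnot(inherits(params, "pipeline_params"))
  junctions <- find_junctions(centerlines, weld_tol = params$weld_tol,
                              min_separation = params$min_junction_separation)
  segments <- extract_segments(centerlines, junctions, weld_tol = params$weld_tol)
  pruned <- prune_junctions(junctions, segments, min_arc = params$min_arc,
                            weld_tol = params$weld_tol)
  if (nrow(pruned) < nrow(junctions)) {
    junctions <- pruned
    segments <- extract_segments(centerlines, junctions, weld_tol = params$weld_tol)
  }
  segments <- split_sides(segments, eyeballs, weld_tol = params$weld_tol)

  # pass 1: the common-crus bifurcation A is the endpoint shared by the two
  # largest ring segments (posterior and superior canals), per side; ring
  # size is measured by fitted circle radius, which is robust to point noise
  crus <- list()
  for (side in c("left", "right")) {
    side_segs <- Filter(function(s)
      s$side == side && s$arc_length >= params$min_ring_length, segments)
    if (length(side_segs) < 2)
      stop(sprintf("no ring segments on %s side", side), call. = FALSE)
    radii <- vapply(side_segs, function(s) estimate_ring_radius(s$path), numeric(1))
    ord <- order(radii, decreasing = TRUE)
    s1 <- side_segs[[ord[1]]]; s2 <- side_segs[[ord[2]]]
    A <- NULL
    for (a in 1:2) for (b in 1:2)
      if (points_close(s1$endpoints[a, ], s2$endpoints[b, ], params$weld_tol))
        A <- s1$endpoints[a, ]
    if (is.null(A))
      stop(sprintf("topology error: longest ring segments share no endpoint on %s side", side),
           call. = FALSE)
    crus[[side]] <- A
  }

  # superior hint: the utricle E (far endpoint of the short link leaving A)
  # lies inferior to the crus bifurcation, so A - E points roughly superior
  # in any pose; it selects the inferior of the two tangent-plane fixed
  # points of the fundus iteration
  hint <- c(0, 0, 0)
  for (side in c("left", "right")) {
    side_segs <- Filter(function(s)
      s$side == side && s$arc_length < params$min_ring_length, segments)
    ends <- link_far_ends(crus[[side]], side_segs, numeric(0), params$weld_tol)
    if (length(ends) > 0) {
      lens <- vapply(ends, function(e) sqrt(sum((e - crus[[side]])^2)), numeric(1))
      hint <- hint + unit_vector(crus[[side]] - ends[[which.max(lens)]])
    }
  }
  superior_hint <- if (sqrt(sum(hint^2)) > 1e-6) unit_vector(hint) else NULL

  fundus <- fundus_point(eyeballs, crus$left, crus$right,
                         max_iter = params$max_iter, superior_hint = superior_hint)
  frame <- build_frame(crus$left, crus$right, fundus$plane,
                       convention = params$convention)

  # pass 2: position rules in the standard frame
  canals <- identify_canals(segments, frame = frame,
                            min_ring_length = params$min_ring_length)
  key_points <- identify_key_points(canals, segments,
                                    weld_tol = params$weld_tol, frame = frame)
  attitudes <- lapply(canals, canal_attitude, frame = frame, n_out = params$n_out)
  list(frame = frame, fundus = fundus, key_points = key_points,
       canals = canals, attitudes = attitudes, junctions = junctions,
       warnings = attr(canals, "warnings"))
}

#' Run configuration for the end-to-end pipeline
#'
#' @param out_dir output directory (created if absent).
#' @param input_dir directory of per-subject inputs
#'   (`<id>.centerlines.json`, `<id>.eye_left.stl`, `<id>.eye_right.stl`);
#'   `NULL` to simulate a cohort instead.
#' @param n_subjects cohort size when simulating.
#' @param seed integer seed (required when simulating).
#' @param noise_sd centerline noise when simulating, mm.
#' @param params a [pipeline_params()].
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(out_dir, input_dir = NULL, n_subjects = 10, seed = NULL,
                       noise_sd = 0.05, params = pipeline_params()) {
  stopifnot(inherits(params, "pipeline_params"))
  simulate <- is.null(input_dir)
  if (simulate && is.null(seed)) stop("simulate requires a seed", call. = FALSE)
  if (!simulate && !dir.exists(input_dir))
    stop(sprintf("input_dir does not exist: %s", input_dir), call. = FALSE)
  structure(list(out_dir = out_dir, input_dir = input_dir, simulate = simulate,
                 n_subjects = as.integer(n_subjects),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 noise_sd = noise_sd, params = params),
            class = "run_config")
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> identify -> frame -> fit -> summarize ->
#' plot, writing per-stage JSON/CSV artifacts and a run log under
#' `config$out_dir`. Any stage error aborts with a message naming the stage
#' and subject.
#'
#' @param config a [run_config()].
#' @return the [summarize_cohort()] result, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  subj_dir <- file.path(config$out_dir, "subjects")
  dir.create(subj_dir, showWarnings = FALSE)
  logf <- file(file.path(config$out_dir, "run.log"), "w")
  on.exit(close(logf))
  log_line(logf, "canalplane %s", as.character(utils::packageVersion("canalplane")))
  p <- config$params
  log_line(logf, "params: weld_tol=%g min_junction_separation=%g min_arc=%g min_ring_length=%g n_out=%d max_iter=%d convention=%s",
           p$weld_tol, p$min_junction_separation, p$min_arc, p$min_ring_length,
           p$n_out, p$max_iter, p$convention)

  stage <- function(name, subject, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed for subject '%s': %s", name, subject,
                   conditionMessage(e)), call. = FALSE))
  }

  subjects <- list()
  if (config$simulate) {
    log_line(logf, "stage simulate: n=%d seed=%d noise_sd=%g",
             config$n_subjects, config$seed, config$noise_sd)
    cohort <- stage("simulate", "-", make_cohort(cohort_spec(
      n_subjects = config$n_subjects, noise_sd = config$noise_sd,
      seed = config$seed)))
    for (i in seq_along(cohort$subjects)) {
      sub <- cohort$subjects[[i]]
      id <- sub$centerlines$subject_id
      write_centerlines(sub$centerlines, file.path(subj_dir, paste0(id, ".centerlines.json")))
      write_eyeball_stl(sub$eyeballs$left, file.path(subj_dir, paste0(id, ".eye_left.stl")))
      write_eyeball_stl(sub$eyeballs$right, file.path(subj_dir, paste0(id, ".eye_right.stl")))
      jsonlite::write_json(
        list(normals_standard = lapply(sub$truth$sides, `[[`, "normals_standard"),
             key_points_image = lapply(sub$truth$sides, `[[`, "key_points_image")),
        file.path(subj_dir, paste0(id, ".truth.json")), digits = NA)
      subjects[[id]] <- list(centerlines = sub$centerlines, eyeballs = sub$eyeballs)
    }
  } else {
    files <- list.files(config$input_dir, pattern = "\\.centerlines\\.json$", full.names = TRUE)
    if (length(files) == 0) stop("no *.centerlines.json inputs found", call. = FALSE)
    for (f in files) {
      id <- sub("\\.centerlines\\.json$", "", basename(f))
      cs <- stage("load", id, read_centerlines(f))
      eyes <- lapply(c(left = "left", right = "right"), function(side) {
        ep <- file.path(config$input_dir, sprintf("%s.eye_%s.stl", id, side))
        if (!file.exists(ep)) stop(sprintf("missing eyeball file %s", ep), call. = FALSE)
        suppressMessages(read_eyeball(ep, side = side))
      })
      subjects[[id]] <- list(centerlines = cs, eyeballs = eyes)
    }
    log_line(logf, "stage load: %d subjects from %s", length(subjects), config$input_dir)
  }

  all_attitudes <- list()
  for (id in names(subjects)) {
    res <- stage("analyze", id,
                 analyze_subject(subjects[[id]]$centerlines, subjects[[id]]$eyeballs, p))
    jsonlite::write_json(list(
      key_points = lapply(res$key_points, function(m) as.data.frame(cbind(point = rownames(m), as.data.frame(m)))),
      warnings = res$warnings,
      frame = list(origin = res$frame$origin, axes = res$frame$axes,
                   convention = res$frame$convention,
                   fundus_iterations = res$fundus$iterations)),
      file.path(subj_dir, paste0(id, ".anatomy.json")), digits = NA)
    all_attitudes[[id]] <- res$attitudes
    if (length(res$warnings)) log_line(logf, "subject %s warnings: %s", id,
                                       paste(res$warnings, collapse = "; "))
  }
  log_line(logf, "stage analyze: %d subjects", length(all_attitudes))

  att <- attitude_table(all_attitudes)
  utils::write.csv(within(att, {
    nx <- NULL; ny <- NULL; nz <- NULL
  }), file.path(config$out_dir, "attitudes.csv"), row.names = FALSE, quote = FALSE)
  summary <- stage("summarize", "-", summarize_cohort(att))
  write_summary(summary, file.path(config$out_dir, "summary.csv"))
  log_line(logf, "stage summarize: %d canal groups", length(summary$groups))

  att$code <- canal_code(att$side, att$canal)
  means <- do.call(rbind, lapply(summary$groups, function(g)
    data.frame(canal = g$canal, nx = g$vector_mean[1], ny = g$vector_mean[2],
               nz = g$vector_mean[3])))
  sc <- export_sphere_scatter(
    data.frame(canal = att$code, nx = att$nx, ny = att$ny, nz = att$nz),
    means = means, path = file.path(config$out_dir, "normal_sphere.png"))
  log_line(logf, "stage plot: %s", ifelse(is.na(sc$png), "JSON only", "PNG + JSON"))
  invisible(summary)
}
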