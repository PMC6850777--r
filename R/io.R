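COHORT_COLS <- c("cell_id", "strain", "first_detection_min", "fate",
                 "fate_time_min", "rls", "division_times_min")
EVENT_COLS <- c("cell_id", "cycle_index", "onset_min", "resolution_min",
                "outcome", "duration_min")
TRACE_COLS <- c("cell_id", "time_min", "compartment", "cycle_index", "signal_au")

#' Cohort, event and trace table I/O
#'
#' All tabular artifacts are plain CSV. The cohort table has one row per cell
#' with division times serialized as a `;`-joined field; the events table one
#' row per scored event; the traces table is long format with columns
#' `cell_id, time_min, compartment (mother|daughter), cycle_index, signal_au`.
#' Readers validate the schema and reject malformed rows with row numbers.
#'
#' @param cohort a [GLMCohort-class].
#' @param path file path.
#' @name table-io
NULL

#' @rdname table-io
#' @export
writeCohortCsv <- function(cohort, path) {
  rec <- cohort@records
  rec$division_times_min <- vapply(
    cohort@division_times[rec$cell_id],
    function(x) paste(sprintf("%.6f", x), collapse = ";"), character(1))
  utils::write.csv(rec[, COHORT_COLS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname table-io
#' @export
readCohortCsv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(COHORT_COLS, names(d))
  if (length(missing))
    stop("cohort CSV missing columns: ", paste(missing, collapse = ", "))
  bad <- which(!d$fate %in% FATES)
  if (length(bad))
    stop("cohort CSV: invalid fate in row(s) ", paste(bad, collapse = ", "))
  divs <- lapply(seq_len(nrow(d)), function(i) {
    s <- d$division_times_min[i]
    if (is.na(s) || !nzchar(s)) numeric(0)
    else as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  names(divs) <- d$cell_id
  nbad <- which(vapply(divs, function(x) any(is.na(x)), logical(1)))
  if (length(nbad))
    stop("cohort CSV: unparseable division times in row(s) ",
         paste(nbad, collapse = ", "))
  new("GLMCohort",
      records = d[, setdiff(COHORT_COLS, "division_times_min")],
      division_times = divs, events = emptyEventsDf(),
      superseded = emptyEventsDf(), preset_name = d$strain[1] %||% "",
      seed = NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' @rdname table-io
#' @param events events data.frame (see [callEvents()]).
#' @export
writeEventsCsv <- function(events, path) {
  utils::write.csv(events[, EVENT_COLS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname table-io
#' @export
readEventsCsv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(EVENT_COLS, names(d))
  if (length(missing))
    stop("events CSV missing columns: ", paste(missing, collapse = ", "))
  bad <- which(!d$outcome %in% OUTCOMES)
  if (length(bad))
    stop("events CSV: unknown outcome in row(s) ", paste(bad, collapse = ", "))
  corr <- d$outcome == "corrected"
  bad <- which(corr != !is.na(d$resolution_min))
  if (length(bad))
    stop("events CSV: resolution_min must be present iff corrected; row(s) ",
         paste(bad, collapse = ", "))
  d
}

#' @rdname table-io
#' @param traces a [TraceSet-class].
#' @export
writeTracesCsv <- function(traces, path) {
  rows <- list()
  for (tr in traces@traces) {
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = tr$cell_id, time_min = tr$time_min, compartment = "mother",
      cycle_index = NA_integer_, signal_au = tr$mother,
      stringsAsFactors = FALSE)
    for (sg in tr$daughter_segments)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = tr$cell_id, time_min = sg$time_min,
        compartment = "daughter", cycle_index = sg$cycle_index,
        signal_au = sg$signal, stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname table-io
#' @param sampling_interval_min expected cadence for validation.
#' @param cohort optional [GLMCohort-class] used to restore mother-death
#'   flags (a death flag is set for cells that died with a terminal-death
#'   event).
#' @export
readTracesCsv <- function(path, sampling_interval_min = 5, cohort = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRACE_COLS, names(d))
  if (length(missing))
    stop("traces CSV missing columns: ", paste(missing, collapse = ", "))
  bad <- which(!d$compartment %in% c("mother", "daughter"))
  if (length(bad))
    stop("traces CSV: unknown compartment in row(s) ", paste(bad, collapse = ", "))
  dt <- sampling_interval_min
  traces <- list()
  for (cid in unique(d$cell_id)) {
    dm <- d[d$cell_id == cid & d$compartment == "mother", ]
    dm <- dm[order(dm$time_min), ]
    if (nrow(dm) > 1 && max(abs(diff(dm$time_min) - dt)) > 1e-6)
      stop(sprintf("traces CSV: non-uniform mother time steps for cell %s", cid))
    dd <- d[d$cell_id == cid & d$compartment == "daughter", ]
    segs <- list()
    for (ci in sort(unique(dd$cycle_index))) {
      ds <- dd[dd$cycle_index == ci, ]
      ds <- ds[order(ds$time_min), ]
      segs[[length(segs) + 1L]] <- list(cycle_index = ci,
                                        time_min = ds$time_min,
                                        signal = ds$signal_au)
    }
    dflag <- NA_real_
    if (!is.null(cohort)) {
      r <- cohort@records[cohort@records$cell_id == cid, ]
      evc <- cohort@events[cohort@events$cell_id == cid, ]
      if (nrow(r) && r$fate == "died" && nrow(evc) &&
          any(evc$outcome == "terminal_death"))
        dflag <- r$fate_time_min
    }
    traces[[cid]] <- list(cell_id = cid, time_min = dm$time_min,
                          mother = dm$signal_au, daughter_segments = segs,
                          mother_death_flag_min = dflag)
  }
  new("TraceSet", sampling_interval_min = dt, traces = traces)
}

#' Image stack and calibration I/O
#'
#' Stacks are stored as multi-page 32-bit float TIFF scaled to `[0, 1]`, with
#' the scale factor in a YAML sidecar (`<path>.yaml`) so values round-trip on
#' the original intensity scale. Calibration sets are written as a TIFF pair
#' plus a provenance sidecar.
#'
#' @param stack numeric array x * y * n.
#' @param path TIFF file path.
#' @name image-io
NULL

#' @rdname image-io
#' @export
writeImageStack <- function(stack, path) {
  d <- dim(stack)
  if (length(d) == 2L) stack <- array(stack, c(d, 1L))
  scale <- max(stack, 1e-12)
  pages <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(list(scale = scale, n_frames = dim(stack)[3],
                        shape = dim(stack)[1:2]),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname image-io
#' @export
readImageStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  stack <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) stack[, , k] <- pages[[k]] * meta$scale
  stack
}

#' @rdname image-io
#' @param calib a [CalibrationSet-class].
#' @param dir output directory.
#' @param provenance named list stored in the sidecar.
#' @export
writeCalibration <- function(calib, dir, provenance = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeImageStack(array(calib@bias_map, c(dim(calib@bias_map), 1L)),
                  file.path(dir, "bias.tiff"))
  writeImageStack(array(calib@flat_correction, c(dim(calib@flat_correction), 1L)),
                  file.path(dir, "flat.tiff"))
  yaml::write_yaml(provenance, file.path(dir, "calibration.yaml"))
  invisible(dir)
}

#' @rdname image-io
#' @export
readCalibration <- function(dir) {
  bias <- readImageStack(file.path(dir, "bias.tiff"))[, , 1]
  flat <- readImageStack(file.path(dir, "flat.tiff"))[, , 1]
  new("CalibrationSet", bias_map = bias, flat_correction = flat)
}

#' Preset registry serialization
#'
#' @param presets named list of [StrainPreset-class] objects.
#' @param path YAML file path.
#' @export
writePresetYaml <- function(presets, path) {
  if (is(presets, "StrainPreset")) presets <- stats::setNames(list(presets), presets@name)
  lst <- lapply(presets, function(p) {
    sl <- methods::slotNames("StrainPreset")
    stats::setNames(lapply(sl, function(s) slot(p, s)), sl)
  })
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writePresetYaml
#' @export
readPresetYaml <- function(path) {
  lst <- yaml::read_yaml(path)
  out <- lapply(lst, function(l) {
    do.call(new, c(list("StrainPreset"),
                   lapply(l, function(x) if (is.list(x)) unlist(x) else x)))
  })
  names(out) <- vapply(out, function(p) p@name, character(1))
  out
}
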