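#' Accessors for cohort and trace containers
#'
#' @param object a [GLMCohort-class] or [TraceSet-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cohortRecords", function(object) standardGeneric("cohortRecords"))
#' @rdname accessors
#' @export
setMethod("cohortRecords", "GLMCohort", function(object) object@records)

#' @rdname accessors
#' @export
setGeneric("cohortEvents", function(object) standardGeneric("cohortEvents"))
#' @rdname accessors
#' @export
setMethod("cohortEvents", "GLMCohort", function(object) object@events)

#' @rdname accessors
#' @export
setGeneric("supersededEvents", function(object) standardGeneric("supersededEvents"))
#' @rdname accessors
#' @export
setMethod("supersededEvents", "GLMCohort", function(object) object@superseded)

#' @rdname accessors
#' @export
setGeneric("divisionTimes", function(object) standardGeneric("divisionTimes"))
#' @rdname accessors
#' @export
setMethod("divisionTimes", "GLMCohort", function(object) object@division_times)

#' @rdname accessors
#' @export
setGeneric("traceList", function(object) standardGeneric("traceList"))
#' @rdname accessors
#' @export
setMethod("traceList", "TraceSet", function(object) object@traces)

#' @rdname accessors
#' @export
setGeneric("samplingInterval", function(object) standardGeneric("samplingInterval"))
#' @rdname accessors
#' @export
setMethod("samplingInterval", "TraceSet", function(object) object@sampling_interval_min)

#' @rdname accessors
#' @export
setGeneric("biasMap", function(object) standardGeneric("biasMap"))
#' @rdname accessors
#' @export
setMethod("biasMap", "CalibrationSet", function(object) object@bias_map)

#' @rdname accessors
#' @export
setGeneric("flatCorrection", function(object) standardGeneric("flatCorrection"))
#' @rdname accessors
#' @export
setMethod("flatCorrection", "CalibrationSet", function(object) object@flat_correction)

setMethod("show", "StrainPreset", function(object) {
  cat("StrainPreset:", object@name, "\n")
  cat(sprintf("  lifespan: Gompertz(modal %.1f, shape %.3f) x %.2f\n",
              object@lifespan_modal, object@lifespan_shape, object@lifespan_scale))
  cat(sprintf("  GLM hazard: young %.3f, late ramp %s\n", object@h_young,
              paste(format(object@late_ramp), collapse = " ")))
  cat(sprintf("  arrest: lognormal(median %g min, sdlog %g); cytokinesis %g/h, death %g/h\n",
              object@duration_median_min, object@duration_sdlog,
              object@lambda_cytokinesis, object@terminal_death_hazard))
  cat(sprintf("  trace: noise CV %g, bleach %g/frame, leak (%g, %g)\n",
              object@trace_noise_cv, object@bleach_per_frame,
              object@leak_range[1], object@leak_range[2]))
})

setMethod("show", "GLMCohort", function(object) {
  rec <- object@records
  cat(sprintf("GLMCohort of %d cells (preset '%s', seed %s)\n", nrow(rec),
              object@preset_name, object@seed))
  cat("  fates:", paste(sprintf("%s=%d", names(table(rec$fate)),
                                as.integer(table(rec$fate))), collapse = ", "), "\n")
  cat(sprintf("  events: %d scored (%d superseded transients)\n",
              nrow(object@events), nrow(object@superseded)))
  if (nrow(object@events))
    cat("  outcomes:", paste(sprintf("%s=%d", names(table(object@events$outcome)),
                                     as.integer(table(object@events$outcome))),
                             collapse = ", "), "\n")
})

setMethod("show", "TraceSet", function(object) {
  n <- length(object@traces)
  nf <- sum(vapply(object@traces, function(t) length(t$time_min), integer(1)))
  cat(sprintf("TraceSet: %d cells, %d mother frames at %g-min cadence\n",
              n, nf, object@sampling_interval_min))
})

setMethod("show", "CalibrationSet", function(object) {
  cat(sprintf("CalibrationSet: %d x %d; bias mean %.2f AU, flat range [%.3f, %.3f]\n",
              nrow(object@bias_map), ncol(object@bias_map),
              mean(object@bias_map), min(object@flat_correction),
              max(object@flat_correction)))
})
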