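#' @import methods
NULL

FATES <- c("died", "senesced", "censored_lost", "censored_end")
OUTCOMES <- c("corrected", "terminal_cytokinesis", "terminal_death")

#' Generative parameters for one genotype
#'
#' A `StrainPreset` bundles every parameter of the phenomenological cohort
#' generator for one genotype: the replicative-lifespan law, the age-dependent
#' genome-level missegregation (GLM) hazard, the competing resolution laws
#' (retrograde correction vs. cytokinesis vs. mother death), censoring, and the
#' trace model (cycle shape, noise, bleaching).
#'
#' The hazard is frailty-style: it conditions on the cell's baseline death age
#' `L` drawn from the lifespan law. Divisions more than five before `L` use
#' `h_young`; the last five divisions (ages `L-4 .. L`) use `late_ramp`, which
#' produces the death-aligned rise in event probability seen in aged cohorts.
#'
#' @slot name genotype label.
#' @slot lifespan_modal modal lifespan of the Gompertz law, in divisions.
#' @slot lifespan_shape Gompertz shape parameter (per division).
#' @slot lifespan_scale multiplier applied to the drawn lifespan.
#' @slot h_young per-division GLM probability far from death.
#' @slot late_ramp length-5 vector of per-division GLM probabilities for the
#'   last five divisions before baseline death.
#' @slot duration_median_min median of the log-normal arrest-duration law (min).
#' @slot duration_sdlog sigma of the log arrest duration.
#' @slot lambda_cytokinesis hazard of daughter separation during arrest (per h).
#' @slot terminal_death_hazard hazard of mother death during arrest (per h).
#' @slot censor_hazard per-division probability of trap loss.
#' @slot cycle_minutes baseline cell-cycle duration (min).
#' @slot cycle_slowdown fractional per-division late-life cycle lengthening.
#' @slot trace_noise_cv coefficient of variation of multiplicative trace noise.
#' @slot bleach_per_frame fractional signal loss per acquired frame.
#' @slot leak_range interval in (0, 0.5) for the residual mother fraction of
#'   the 2N signal during a GLM.
#' @slot multi_event_prob probability that a GLM cycle contains an earlier,
#'   superseded transient event.
#' @export
setClass("StrainPreset",
  representation(
    name = "character",
    lifespan_modal = "numeric",
    lifespan_shape = "numeric",
    lifespan_scale = "numeric",
    h_young = "numeric",
    late_ramp = "numeric",
    duration_median_min = "numeric",
    duration_sdlog = "numeric",
    lambda_cytokinesis = "numeric",
    terminal_death_hazard = "numeric",
    censor_hazard = "numeric",
    cycle_minutes = "numeric",
    cycle_slowdown = "numeric",
    trace_noise_cv = "numeric",
    bleach_per_frame = "numeric",
    leak_range = "numeric",
    multi_event_prob = "numeric"
  )
)

setValidity("StrainPreset", function(object) {
  msgs <- character(0)
  chkProb <- function(x, nm, n = 1L) {
    if (length(slot(object, x)) != n)
      msgs <<- c(msgs, sprintf("%s must have length %d", nm, n))
    else if (any(!is.finite(slot(object, x))) ||
             any(slot(object, x) < 0) || any(slot(object, x) > 1))
      msgs <<- c(msgs, sprintf("%s must lie in [0, 1]", nm))
  }
  chkPos <- function(x, nm) {
    if (length(slot(object, x)) != 1L || !is.finite(slot(object, x)) ||
        slot(object, x) <= 0)
      msgs <<- c(msgs, sprintf("%s must be a positive scalar", nm))
  }
  chkNonneg <- function(x, nm) {
    if (length(slot(object, x)) != 1L || !is.finite(slot(object, x)) ||
        slot(object, x) < 0)
      msgs <<- c(msgs, sprintf("%s must be a nonnegative scalar", nm))
  }
  if (length(object@name) != 1L || !nzchar(object@name))
    msgs <- c(msgs, "name must be a nonempty string")
  chkPos("lifespan_modal", "lifespan_modal")
  chkPos("lifespan_shape", "lifespan_shape")
  chkPos("lifespan_scale", "lifespan_scale")
  chkProb("h_young", "h_young")
  chkProb("late_ramp", "late_ramp", 5L)
  chkPos("duration_median_min", "duration_median_min")
  chkPos("duration_sdlog", "duration_sdlog")
  chkNonneg("lambda_cytokinesis", "lambda_cytokinesis")
  chkNonneg("terminal_death_hazard", "terminal_death_hazard")
  chkProb("censor_hazard", "censor_hazard")
  chkPos("cycle_minutes", "cycle_minutes")
  chkNonneg("cycle_slowdown", "cycle_slowdown")
  chkNonneg("trace_noise_cv", "trace_noise_cv")
  chkProb("bleach_per_frame", "bleach_per_frame")
  if (length(object@leak_range) != 2L || any(!is.finite(object@leak_range)) ||
      object@leak_range[1] <= 0 || object@leak_range[2] >= 0.5 ||
      object@leak_range[1] > object@leak_range[2])
    msgs <- c(msgs, "leak_range must be an ordered interval inside (0, 0.5)")
  chkProb("multi_event_prob", "multi_event_prob")
  if (length(msgs)) msgs else TRUE
})

#' Cohort of mother cells with scored GLM events
#'
#' Container for one simulated (or called) cohort: one row per mother cell in
#' `records`, per-cell division times, and one row per scored GLM event in
#' `events`. Ground-truth cohorts from [simulateCohort()] additionally carry
#' superseded (earlier, final-event-rule-removed) events in `superseded`.
#'
#' @slot records data.frame with columns `cell_id`, `strain`,
#'   `first_detection_min`, `fate` (died / senesced / censored_lost /
#'   censored_end), `fate_time_min`, `rls`.
#' @slot division_times named list (by `cell_id`) of strictly increasing
#'   division times in minutes; `rls == lengths(division_times)`.
#' @slot events data.frame with columns `cell_id`, `cycle_index`, `onset_min`,
#'   `resolution_min` (NA unless corrected), `outcome`, `duration_min`
#'   (NA unless corrected). At most one event per (cell, cycle).
#' @slot superseded data.frame with the same columns holding transient events
#'   removed by the final-event rule (empty unless generated).
#' @slot preset_name label of the generating preset ("" if unknown).
#' @slot seed integer seed used by the generator (NA if unknown).
#' @export
setClass("GLMCohort",
  representation(
    records = "data.frame",
    division_times = "list",
    events = "data.frame",
    superseded = "data.frame",
    preset_name = "character",
    seed = "integer"
  )
)

emptyEventsDf <- function() {
  data.frame(cell_id = character(0), cycle_index = integer(0),
             onset_min = numeric(0), resolution_min = numeric(0),
             outcome = character(0), duration_min = numeric(0),
             stringsAsFactors = FALSE)
}

setValidity("GLMCohort", function(object) {
  msgs <- character(0)
  rec <- object@records
  need <- c("cell_id", "strain", "first_detection_min", "fate",
            "fate_time_min", "rls")
  if (!all(need %in% names(rec)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(rec$cell_id))
    msgs <- c(msgs, "cell_id must be unique")
  if (!all(rec$fate %in% FATES))
    msgs <- c(msgs, sprintf("fate must be one of %s", paste(FATES, collapse = ", ")))
  if (!setequal(names(object@division_times), rec$cell_id))
    msgs <- c(msgs, "division_times must be named by cell_id")
  else {
    dt <- object@division_times[rec$cell_id]
    if (!all(lengths(dt) == rec$rls))
      msgs <- c(msgs, "rls must equal the number of division times")
    bad <- vapply(dt, function(x) length(x) > 1 && any(diff(x) <= 0), logical(1))
    if (any(bad))
      msgs <- c(msgs, "division times must be strictly increasing")
    last <- vapply(dt, function(x) if (length(x)) max(x) else -Inf, numeric(1))
    if (any(rec$fate_time_min < last - 1e-5))
      msgs <- c(msgs, "fate_time_min must be >= last division time")
  }
  ev <- object@events
  evneed <- names(emptyEventsDf())
  if (!all(evneed %in% names(ev)))
    msgs <- c(msgs, paste("events must have columns:", paste(evneed, collapse = ", ")))
  else if (nrow(ev)) {
    if (!all(ev$cell_id %in% rec$cell_id))
      msgs <- c(msgs, "events reference unknown cell_id")
    if (anyDuplicated(ev[, c("cell_id", "cycle_index")]))
      msgs <- c(msgs, "at most one scored event per (cell_id, cycle_index)")
    if (!all(ev$outcome %in% OUTCOMES))
      msgs <- c(msgs, "unknown event outcome")
    corr <- ev$outcome == "corrected"
    if (any(corr != !is.na(ev$resolution_min)) ||
        any(corr != !is.na(ev$duration_min)))
      msgs <- c(msgs, "resolution/duration present iff outcome is corrected")
    if (any(ev$duration_min[corr] <= 0))
      msgs <- c(msgs, "corrected durations must be > 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' Mother/daughter fluorescence trace pairs
#'
#' Uniformly sampled mother histone-signal series plus per-cycle daughter
#' segments for a set of cells. Each element of `traces` is a list with
#' `cell_id`, `time_min` (uniform grid), `mother` (signal, AU),
#' `daughter_segments` (list of lists with `cycle_index`, `time_min`,
#' `signal`), and `mother_death_flag_min` (NA unless the mother died).
#'
#' @slot sampling_interval_min sampling cadence in minutes (default 5).
#' @slot traces named list of per-cell trace pairs.
#' @export
setClass("TraceSet",
  representation(sampling_interval_min = "numeric", traces = "list")
)

setValidity("TraceSet", function(object) {
  msgs <- character(0)
  dt <- object@sampling_interval_min
  if (length(dt) != 1L || !is.finite(dt) || dt <= 0)
    return("sampling_interval_min must be a positive scalar")
  for (tr in object@traces) {
    if (length(tr$time_min) != length(tr$mother)) {
      msgs <- c(msgs, sprintf("%s: time and mother series differ in length", tr$cell_id))
      next
    }
    if (length(tr$time_min) > 1 &&
        max(abs(diff(tr$time_min) - dt)) > 1e-6)
      msgs <- c(msgs, sprintf("%s: mother series not uniformly sampled", tr$cell_id))
    if (any(tr$mother < 0))
      msgs <- c(msgs, sprintf("%s: negative mother signal", tr$cell_id))
    segs <- tr$daughter_segments
    if (length(segs) > 1) {
      iv <- t(vapply(segs, function(s) range(s$time_min), numeric(2)))
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (any(iv[-1, 1] < iv[-nrow(iv), 2] - 1e-9))
        msgs <- c(msgs, sprintf("%s: daughter segments overlap in time", tr$cell_id))
    }
  }
  if (length(msgs)) unique(msgs) else TRUE
})

#' Camera bias and flat-field correction maps
#'
#' @slot bias_map per-pixel camera offset (AU), estimated from dark frames.
#' @slot flat_correction per-pixel multiplicative correction factor,
#'   normalized to mean 1 over the image.
#' @export
setClass("CalibrationSet",
  representation(bias_map = "matrix", flat_correction = "matrix")
)

setValidity("CalibrationSet", function(object) {
  if (!identical(dim(object@bias_map), dim(object@flat_correction)))
    return("bias_map and flat_correction must have identical shape")
  if (abs(mean(object@flat_correction) - 1) > 1e-6)
    return("flat_correction must have mean 1 (within 1e-6)")
  TRUE
})

#' Event-caller thresholds
#'
#' @slot glm_retention_threshold maximum mother post-drop fraction of the
#'   pre-drop 2N level for a GLM call (strictly below normal anaphase ~0.5).
#' @slot min_persist_frames frames the low state must persist.
#' @slot derivative_z z-score threshold on windowed slopes for correction
#'   detection, relative to the trace's plateau noise floor.
#' @slot correction_window_frames window defining "simultaneous" opposite
#'   mother/daughter slopes.
#' @slot recovery_fraction fraction of the 1N level the mother must regain to
#'   confirm a correction.
#' @export
setClass("CallerParams",
  representation(
    glm_retention_threshold = "numeric",
    min_persist_frames = "integer",
    derivative_z = "numeric",
    correction_window_frames = "integer",
    recovery_fraction = "numeric"
  )
)

setValidity("CallerParams", function(object) {
  msgs <- character(0)
  if (object@glm_retention_threshold <= 0 || object@glm_retention_threshold >= 0.5)
    msgs <- c(msgs, "glm_retention_threshold must lie in (0, 0.5)")
  if (object@min_persist_frames < 1L)
    msgs <- c(msgs, "min_persist_frames must be >= 1")
  if (object@correction_window_frames < 2L)
    msgs <- c(msgs, "correction_window_frames must be >= 2")
  if (object@recovery_fraction <= 0 || object@recovery_fraction > 1)
    msgs <- c(msgs, "recovery_fraction must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Cell-cycle segmentation of a mother trace
#'
#' @slot cell_id cell identifier.
#' @slot boundaries strictly increasing frame indices; cycle `k` spans frames
#'   `boundaries[k] .. boundaries[k+1] - 1`.
#' @slot ref_2n per-cycle pre-mitotic (2N) reference level (AU).
#' @slot ref_1n per-cycle post-mitotic (1N) reference level (AU).
#' @export
setClass("CycleSegmentation",
  representation(cell_id = "character", boundaries = "integer",
                 ref_2n = "numeric", ref_1n = "numeric")
)

setValidity("CycleSegmentation", function(object) {
  msgs <- character(0)
  if (is.unsorted(object@boundaries, strictly = TRUE))
    msgs <- c(msgs, "boundaries must be strictly increasing")
  ncyc <- max(length(object@boundaries) - 1L, 0L)
  if (length(object@ref_2n) != ncyc || length(object@ref_1n) != ncyc)
    msgs <- c(msgs, "need one 2N/1N reference pair per cycle")
  if (any(object@ref_2n <= object@ref_1n))
    msgs <- c(msgs, "2N reference must exceed 1N reference in every cycle")
  if (length(msgs)) msgs else TRUE
})

#' Per-cell fluorescence quantification parameters
#'
#' @slot top_fraction fraction of brightest pixels averaged (default 0.02).
#' @slot dilation_radius disk radius in pixels for grayscale dilation.
#' @slot min_mask_pixels minimum admissible cell-mask size.
#' @export
setClass("QuantParams",
  representation(top_fraction = "numeric", dilation_radius = "integer",
                 min_mask_pixels = "integer")
)

setValidity("QuantParams", function(object) {
  msgs <- character(0)
  if (object@top_fraction <= 0 || object@top_fraction >= 1)
    msgs <- c(msgs, "top_fraction must lie in (0, 1)")
  if (object@dilation_radius < 1L)
    msgs <- c(msgs, "dilation_radius must be >= 1")
  if (object@min_mask_pixels < 1L)
    msgs <- c(msgs, "min_mask_pixels must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Bootstrap configuration
#'
#' `nonoverlap_p05` intervals are 83.4% percentile intervals: for two bars with
#' comparable variance, non-overlap of such intervals corresponds to a
#' two-group test at approximately p = 0.05. `percentile95` gives plain 95%
#' percentile intervals.
#'
#' @slot n_boot number of resamples (>= 100).
#' @slot level_mode `"nonoverlap_p05"` or `"percentile95"`.
#' @slot seed integer seed for the resampling stream.
#' @export
setClass("BootstrapConfig",
  representation(n_boot = "integer", level_mode = "character", seed = "integer")
)

setValidity("BootstrapConfig", function(object) {
  msgs <- character(0)
  if (object@n_boot < 100L)
    msgs <- c(msgs, "n_boot must be >= 100")
  if (!object@level_mode %in% c("nonoverlap_p05", "percentile95"))
    msgs <- c(msgs, "level_mode must be nonoverlap_p05 or percentile95")
  if (length(msgs)) msgs else TRUE
})
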