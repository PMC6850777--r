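smooth3 <- function(x) if (length(x) >= 3) stats::runmed(x, 3) else x

#' Segment a mother trace into cell cycles
#'
#' In annotated mode the cycle boundaries follow the supplied division times
#' (nearest frame). In unannotated mode boundaries are found from the signal
#' alone: a sustained drop of the smoothed mother signal into the 1N band
#' (0.35-0.65 of the running plateau) marks an anaphase, while a drop below
#' 0.35 marks a GLM arrest whose boundary is instead placed where the
#' recovery settles near 1N; arrests that recover all the way back to the 2N
#' plateau (superseded transients) produce no boundary. Per cycle, the 2N
#' reference is the median of the plateau frames (smoothed signal within 80%
#' of the cycle maximum) and the 1N reference the median of the first frames.
#'
#' @param trace one trace-pair list (an element of [TraceSet-class] `traces`).
#' @param annotations optional numeric vector of division times (minutes).
#' @param sampling_interval_min frame cadence (minutes).
#' @return A [CycleSegmentation-class].
#' @export
segmentCycles <- function(trace, annotations = NULL, sampling_interval_min = 5) {
  m <- trace$mother
  tt <- trace$time_min
  n <- length(m)
  dt <- sampling_interval_min
  if (!is.null(annotations)) {
    bf <- round((annotations - tt[1]) / dt) + 1
    bf <- bf[bf > 1 & bf <= n]
    bounds <- as.integer(c(1L, bf, n + 1L))
    bounds <- unique(bounds)
  } else {
    if (n < 2 * 10)
      stop("trace shorter than two cycles; unannotated segmentation needs more data")
    sm <- smooth3(m)
    bounds <- 1L
    cur_max <- sm[1]
    i <- 2L
    while (i <= n) {
      if (sm[i] < 0.35 * cur_max) {
        # GLM arrest: skip to recovery settle point (if any)
        pre2n <- cur_max
        j <- i
        while (j <= n && sm[j] < 0.42 * pre2n) j <- j + 1L
        if (j > n) break                       # terminal arrest: no boundary
        while (j < n && sm[j + 1] > sm[j] * 1.03) j <- j + 1L
        if (sm[j] <= 0.72 * pre2n) {           # settled near 1N: division
          bounds <- c(bounds, j)
          cur_max <- sm[j]
        } else {                               # recovered to 2N: transient
          cur_max <- pre2n
        }
        i <- j + 1L
      } else if (sm[i] <= 0.65 * cur_max &&
                 (i == n || sm[min(i + 1L, n)] <= 0.70 * cur_max)) {
        bounds <- c(bounds, i)                 # normal anaphase into 1N band
        cur_max <- sm[i]
        i <- i + 1L
      } else {
        cur_max <- max(cur_max, sm[i])
        i <- i + 1L
      }
    }
    bounds <- as.integer(unique(c(bounds, n + 1L)))
  }
  ncyc <- length(bounds) - 1L
  ref2 <- ref1 <- numeric(ncyc)
  for (k in seq_len(ncyc)) {
    idx <- bounds[k]:(bounds[k + 1] - 1L)
    sm <- smooth3(m[idx])
    mx <- max(sm)
    ref2[k] <- stats::median(m[idx][sm >= 0.8 * mx])
    ref1[k] <- stats::median(m[idx][seq_len(min(3L, length(idx)))])
    if (ref1[k] >= 0.8 * ref2[k])
      ref1[k] <- ref2[k] / 2   # flat cycle (arrest tail): no 1N plateau seen
  }
  new("CycleSegmentation", cell_id = trace$cell_id, boundaries = bounds,
      ref_2n = ref2, ref_1n = ref1)
}

daughterSegmentAt <- function(trace, t_onset) {
  for (sg in trace$daughter_segments)
    if (t_onset >= sg$time_min[1] - 1e-9 &&
        t_onset <= sg$time_min[length(sg$time_min)] + 1e-9)
      return(sg)
  NULL
}

#' Call GLM onsets on a segmented trace
#'
#' A GLM is called at the first frame of a run where the mother signal falls
#' below `glm_retention_threshold` times the cycle's 2N reference and stays
#' there for at least `min_persist_frames`, provided the daughter gains at
#' least half of the mother's lost signal concurrently. Normal anaphase
#' (retention ~ 0.5) never crosses the threshold. When several candidate runs
#' occur in one cycle only the final one is retained.
#'
#' @param trace one trace-pair list.
#' @param seg a [CycleSegmentation-class] for this trace.
#' @param params a [CallerParams-class].
#' @return data.frame of onsets: `cell_id`, `cycle_index`, `onset_min`,
#'   `onset_frame` (empty if no events).
#' @export
callGlms <- function(trace, seg, params = callerParams()) {
  validObject(params)
  m <- trace$mother
  tt <- trace$time_min
  bounds <- seg@boundaries
  out <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    idx <- bounds[k]:(bounds[k + 1] - 1L)
    thr <- params@glm_retention_threshold * seg@ref_2n[k]
    below <- m[idx] < thr
    if (!any(below)) next
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cand <- which(r$values & r$lengths >= params@min_persist_frames)
    if (!length(cand)) next
    for (ci in rev(cand)) {                 # final event first
      of <- idx[starts[ci]]
      sgd <- daughterSegmentAt(trace, tt[of])
      if (is.null(sgd)) next
      pre_i <- which(sgd$time_min < tt[of] - 1e-9)
      pre <- if (length(pre_i)) sgd$signal[max(pre_i)] else 0
      win <- sgd$time_min >= tt[of] - 1e-9 &
             sgd$time_min <= tt[of] + 2 * (tt[2] - tt[1]) + 1e-9
      if (!any(win)) next
      gain <- max(sgd$signal[win]) - pre
      lost <- seg@ref_2n[k] - m[of]
      if (gain >= 0.5 * lost) {
        # the threshold crossing happened between frames of-1 and of: report
        # the interval midpoint to avoid a half-frame late bias
        out[[length(out) + 1L]] <- data.frame(
          cell_id = trace$cell_id, cycle_index = k,
          onset_min = tt[of] - (tt[2] - tt[1]) / 2,
          onset_frame = of, stringsAsFactors = FALSE)
        break                               # <= 1 event per cycle
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(cell_id = character(0), cycle_index = integer(0),
               onset_min = numeric(0), onset_frame = integer(0))
}

# median absolute successive difference over frames satisfying `sel`,
# counting only differences between adjacent selected frames
plateauNoiseFloor <- function(x, sel = rep(TRUE, length(x))) {
  if (length(x) < 3) return(0)
  d <- diff(x)
  keep <- sel[-length(sel)] & sel[-1]
  if (!any(keep)) return(0)
  stats::median(abs(d[keep]))
}

# pooled relative noise floor: per cycle, successive differences between
# adjacent 2N-plateau frames divided by that cycle's 2N reference
relativeNoiseFloor <- function(m, seg) {
  pool <- numeric(0)
  b <- seg@boundaries
  for (k in seq_along(seg@ref_2n)) {
    idx <- b[k]:(b[k + 1] - 1L)
    x <- m[idx]
    sel <- x > 0.9 * seg@ref_2n[k]
    if (sum(sel) < 2) next
    d <- diff(x)
    keep <- sel[-length(sel)] & sel[-1]
    pool <- c(pool, d[keep] / seg@ref_2n[k])
  }
  if (length(pool) < 3) 0 else stats::median(abs(pool))
}

#' Detect the correction (resolution) of a called GLM
#'
#' The resolution is the first frame after onset where, over a
#' `correction_window_frames` window, the daughter signal falls and the mother
#' signal rises simultaneously, each by more than `derivative_z` times the
#' trace's plateau noise floor (median absolute successive difference), and
#' the mother subsequently regains at least `recovery_fraction` of its 1N
#' level. Returns `NA` when no such frame exists before the trace/segment end
#' (terminal events, or a mother rise without a simultaneous daughter fall).
#'
#' @param onset_frame frame index of the called onset.
#' @param cycle_index cycle of the called onset.
#' @param trace one trace-pair list.
#' @param seg the trace's [CycleSegmentation-class].
#' @param params a [CallerParams-class].
#' @return resolution time in minutes, or `NA_real_`.
#' @export
detectCorrection <- function(onset_frame, cycle_index, trace, seg,
                             params = callerParams()) {
  m <- trace$mother
  tt <- trace$time_min
  w <- params@correction_window_frames
  bounds <- seg@boundaries
  cyc_end <- bounds[cycle_index + 1L] - 1L
  sgd <- daughterSegmentAt(trace, tt[onset_frame])
  if (is.null(sgd)) return(NA_real_)
  dsig <- sgd$signal
  dtim <- sgd$time_min
  # trace noise is multiplicative: pool plateau successive differences from
  # every cycle, each normalized by its own 2N reference (so photobleaching
  # does not inflate the floor), then rescale to the local signal level
  sig_rel <- relativeNoiseFloor(m, seg)
  sig_m <- sig_rel * seg@ref_2n[cycle_index]
  arr <- dsig[dtim >= tt[onset_frame] - 1e-9]
  sig_d <- sig_rel * stats::median(arr)
  # restored-1N target: the next cycle's G1 level when available (it tracks
  # photobleaching across long arrests better than the pre-arrest reference)
  ref1 <- if (cycle_index + 1L <= length(seg@ref_1n) &&
              seg@ref_1n[cycle_index + 1L] < seg@ref_2n[cycle_index])
    seg@ref_1n[cycle_index + 1L] else seg@ref_1n[cycle_index]
  for (i in (onset_frame + 1L):max(onset_frame + 1L, cyc_end - 1L)) {
    mi2 <- min(i + w - 1L, length(m))
    if (mi2 <= i) break
    di <- match(TRUE, abs(dtim - tt[i]) < 1e-6)
    if (is.na(di)) next
    di2 <- min(di + w - 1L, length(dsig))
    if (di2 <= di) break
    rise <- m[mi2] - m[i]
    fall <- dsig[di2] - dsig[di]
    if (rise > params@derivative_z * sig_m &&
        fall < -params@derivative_z * sig_d) {
      # the restored 1N level may only be reached at the division boundary
      # closing the cycle, so allow the look-ahead to cross it by two frames
      tail_max <- max(m[i:min(cyc_end + 2L, length(m))])
      if (tail_max >= params@recovery_fraction * ref1) {
        # refine to the frame inside the window where the rise begins; the
        # true resolution lies between frames j and j+1, so report the
        # midpoint (mirrors the onset convention)
        j <- i
        while (j < mi2 && m[j + 1L] - m[j] <= params@derivative_z * sig_m / 2)
          j <- j + 1L
        return(tt[j] + (tt[2] - tt[1]) / 2)
      }
    }
  }
  NA_real_
}

#' Classify a called GLM's outcome
#'
#' `corrected` when a resolution was detected; `terminal_death` when the
#' mother death flag precedes any resolution; otherwise `terminal_cytokinesis`
#' when the daughter segment ends (washout) without restoration.
#'
#' @param resolution_min resolution time or `NA` (from [detectCorrection()]).
#' @param onset_min called onset time.
#' @param trace one trace-pair list.
#' @return one of `"corrected"`, `"terminal_cytokinesis"`, `"terminal_death"`.
#' @export
classifyOutcome <- function(resolution_min, onset_min, trace) {
  if (!is.na(resolution_min)) return("corrected")
  dflag <- trace$mother_death_flag_min
  if (!is.na(dflag) && dflag >= onset_min) return("terminal_death")
  "terminal_cytokinesis"
}

#' Durations of corrected events
#'
#' Terminal events are excluded; a corrected event without a resolution time
#' is a consistency error.
#'
#' @param events data.frame with `onset_min`, `resolution_min`, `outcome`.
#' @return data.frame of corrected events with a `duration_min` column.
#' @export
measureDurations <- function(events) {
  corr <- events[events$outcome == "corrected", , drop = FALSE]
  if (any(is.na(corr$resolution_min)))
    stop("corrected event lacking resolution time")
  corr$duration_min <- corr$resolution_min - corr$onset_min
  corr
}

#' Run the full event caller over a trace set
#'
#' Segments every trace (using division-time annotations when a cohort is
#' supplied), calls onsets, detects corrections, classifies outcomes and
#' measures durations.
#'
#' @param traces a [TraceSet-class].
#' @param cohort optional [GLMCohort-class] supplying division-time
#'   annotations (its events are ignored).
#' @param params a [CallerParams-class].
#' @return events data.frame with columns `cell_id`, `cycle_index`,
#'   `onset_min`, `resolution_min`, `outcome`, `duration_min`.
#' @examples
#' p <- strainPreset(trace_noise_cv = 0, bleach_per_frame = 0)
#' coh <- simulateCohort(p, 20, seed = 2)
#' tr <- synthesizeTraces(coh, p, seed = 2)
#' called <- callEvents(tr, coh)
#' @export
callEvents <- function(traces, cohort = NULL, params = callerParams()) {
  dt <- traces@sampling_interval_min
  out <- list()
  for (tr in traces@traces) {
    ann <- if (!is.null(cohort)) cohort@division_times[[tr$cell_id]] else NULL
    sg <- segmentCycles(tr, annotations = ann, sampling_interval_min = dt)
    on <- callGlms(tr, sg, params)
    if (!nrow(on)) next
    for (j in seq_len(nrow(on))) {
      res <- detectCorrection(on$onset_frame[j], on$cycle_index[j], tr, sg, params)
      outc <- classifyOutcome(res, on$onset_min[j], tr)
      out[[length(out) + 1L]] <- data.frame(
        cell_id = on$cell_id[j], cycle_index = on$cycle_index[j],
        onset_min = on$onset_min[j],
        resolution_min = if (outc == "corrected") res else NA_real_,
        outcome = outc,
        duration_min = if (outc == "corrected") res - on$onset_min[j] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else emptyEventsDf()
}
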