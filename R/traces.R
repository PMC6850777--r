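BASE_1N <- 100  # AU; the 2N plateau is 2 * BASE_1N

# Piecewise-linear signal model: segments is a data.frame with t0, t1, v0, v1;
# sampled at arbitrary times with left-continuous steps at segment joins.
evalSegments <- function(segments, times) {
  idx <- findInterval(times, segments$t0)
  idx[idx < 1L] <- 1L
  t0 <- segments$t0[idx]; t1 <- segments$t1[idx]
  len <- t1 - t0
  frac <- ifelse(len > 0, pmin(pmax((times - t0) / ifelse(len > 0, len, 1), 0), 1), 0)
  segments$v0[idx] + frac * (segments$v1[idx] - segments$v0[idx])
}

seg <- function(t0, t1, v0, v1 = v0) data.frame(t0 = t0, t1 = t1, v0 = v0, v1 = v1)

#' Synthesize mother/daughter fluorescence traces for a cohort
#'
#' Encodes the histone-reporter cycle shape: the mother signal sits at a 1N
#' baseline through G1, rises linearly to 2N during S-phase, holds a 2N
#' plateau, and drops back to 1N at anaphase when the daughter receives its 1N
#' share. In a GLM cycle the anaphase-time transfer instead sends the majority
#' of the signal to the daughter: the mother drops to `leak * 2N` (leak drawn
#' uniformly from the preset's `leak_range`) with the complement appearing in
#' the daughter segment. A correction returns the mother to 1N while the
#' daughter simultaneously falls to 1N over the 10-15 min separating the
#' ground-truth resolution time from the recorded division time; terminal
#' events end the daughter segment (washout) without restoration. Multiplicative
#' Gaussian noise (`trace_noise_cv`) and exponential photobleaching
#' (`bleach_per_frame`, applied by absolute frame index) are applied last, so
#' with both set to zero the summed mother+daughter signal is exactly conserved
#' across any GLM transfer and its correction.
#'
#' @param cohort a [GLMCohort-class] from [simulateCohort()] (ground-truth
#'   events and superseded transients are both rendered).
#' @param preset the generating [StrainPreset-class].
#' @param seed integer seed (leak fractions and noise).
#' @return A [TraceSet-class] sampled at 5-minute cadence.
#' @examples
#' coh <- simulateCohort(strainPreset(trace_noise_cv = 0), 5, seed = 1)
#' ts <- synthesizeTraces(coh, strainPreset(trace_noise_cv = 0), seed = 1)
#' @export
synthesizeTraces <- function(cohort, preset, seed, sampling_interval_min = 5) {
  validObject(cohort)
  rec <- cohort@records
  ev <- cohort@events
  bad <- setdiff(ev$cell_id, rec$cell_id)
  if (length(bad))
    stop("events reference unknown cells: ", paste(unique(bad), collapse = ", "))
  over <- ev$cell_id[ev$cycle_index > rec$rls[match(ev$cell_id, rec$cell_id)] + 1L]
  if (length(over))
    stop("events reference cycles beyond the record: ",
         paste(unique(over), collapse = ", "))
  set.seed(as.integer(seed))
  dt <- sampling_interval_min

  traces <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    r <- rec[i, ]
    cid <- r$cell_id
    divs <- cohort@division_times[[cid]]
    cev <- ev[ev$cell_id == cid, , drop = FALSE]
    csup <- cohort@superseded[cohort@superseded$cell_id == cid, , drop = FALSE]
    t0 <- r$first_detection_min
    t_end <- r$fate_time_min
    # cycle a spans [start_a, end_a]; the last (possibly incomplete) cycle ends
    # at fate_time for arrested / censored / dying cells
    starts <- c(t0, divs)
    ends <- c(divs, t_end)
    if (ends[length(ends)] <= starts[length(starts)] + 1e-9) {
      starts <- starts[-length(starts)]
      ends <- ends[-length(ends)]
    }
    # a terminal cytokinesis leaves the mother arrested at the leak level: the
    # event cycle extends to the end of observation, daughter washes out at
    # the separation time
    tc <- cev[cev$outcome == "terminal_cytokinesis", , drop = FALSE]
    tc_washout <- NA_real_
    if (nrow(tc)) {
      at <- tc$cycle_index[1]
      tc_washout <- divs[at]
      starts <- starts[seq_len(at)]
      ends <- ends[seq_len(at)]
      ends[at] <- t_end
    }

    msegs <- list(); dsegl <- list()
    for (a in seq_along(starts)) {
      s <- starts[a]; e <- ends[a]
      D <- preset@cycle_minutes * (1 + preset@cycle_slowdown)^(a - 1)
      ea <- cev[cev$cycle_index == a, , drop = FALSE]
      sa <- csup[csup$cycle_index == a, , drop = FALSE]
      completed <- a <= length(divs)
      onset <- if (nrow(ea)) ea$onset_min else NA_real_
      g1_end <- min(s + 0.25 * D, e)
      s_end <- min(s + 0.55 * D, e)
      bud <- g1_end
      cyc_m <- list(seg(s, g1_end, BASE_1N),
                    seg(g1_end, s_end, BASE_1N, 2 * BASE_1N))
      dseg <- NULL
      if (nrow(ea) == 0) {
        # normal cycle (or event-free incomplete final cycle)
        if (completed) {
          cyc_m <- c(cyc_m, list(seg(s_end, e, 2 * BASE_1N)))
          dseg <- list(list(cycle_index = a, t0 = bud, t1 = e,
                            segs = seg(bud, e, 0)))
        } else {
          # senescent / censored tail: frozen at current phase value
          cyc_m <- c(cyc_m, list(seg(s_end, e, 2 * BASE_1N)))
          if (e > bud + 1e-9)
            dseg <- list(list(cycle_index = a, t0 = bud, t1 = e,
                              segs = seg(bud, e, 0)))
        }
      } else {
        leak <- stats::runif(1, preset@leak_range[1], preset@leak_range[2])
        pre <- list(seg(s_end, onset, 2 * BASE_1N))
        dpre <- seg(bud, onset, 0)
        if (nrow(sa)) {
          leak_s <- stats::runif(1, preset@leak_range[1], preset@leak_range[2])
          o1 <- sa$onset_min; r1 <- sa$resolution_min
          pre <- list(seg(s_end, o1, 2 * BASE_1N),
                      seg(o1, r1, leak_s * 2 * BASE_1N),
                      seg(r1, r1 + 10, leak_s * 2 * BASE_1N, 2 * BASE_1N),
                      seg(r1 + 10, onset, 2 * BASE_1N))
          dpre <- rbind(seg(bud, o1, 0),
                        seg(o1, r1, (1 - leak_s) * 2 * BASE_1N),
                        seg(r1, r1 + 10, (1 - leak_s) * 2 * BASE_1N, 0),
                        seg(r1 + 10, onset, 0))
        }
        if (ea$outcome == "corrected") {
          res <- ea$resolution_min
          cyc_m <- c(cyc_m, pre,
                     list(seg(onset, res, leak * 2 * BASE_1N),
                          seg(res, e, leak * 2 * BASE_1N, BASE_1N)))
          dseg <- list(list(cycle_index = a, t0 = bud, t1 = e,
                            segs = rbind(dpre,
                                         seg(onset, res, (1 - leak) * 2 * BASE_1N),
                                         seg(res, e, (1 - leak) * 2 * BASE_1N,
                                             BASE_1N))))
        } else {
          # terminal: mother stays at leak level; daughter washes out at the
          # separation time (cytokinesis) or holds until mother death
          wash <- if (ea$outcome == "terminal_cytokinesis") tc_washout else e
          cyc_m <- c(cyc_m, pre, list(seg(onset, e, leak * 2 * BASE_1N)))
          dseg <- list(list(cycle_index = a, t0 = bud, t1 = wash,
                            segs = rbind(dpre,
                                         seg(onset, wash, (1 - leak) * 2 * BASE_1N))))
        }
      }
      msegs <- c(msegs, cyc_m)
      dsegl <- c(dsegl, dseg)
    }
    mseg_df <- do.call(rbind, msegs)
    mseg_df <- mseg_df[mseg_df$t1 > mseg_df$t0 + 1e-9, , drop = FALSE]

    times <- seq(t0, t_end, by = dt)
    mother <- evalSegments(mseg_df, times)
    dsegs_out <- list()
    for (dsg in dsegl) {
      ti <- times[times >= dsg$t0 - 1e-9 & times <= dsg$t1 + 1e-9]
      if (!length(ti)) next
      sig <- evalSegments(dsg$segs, ti)
      dsegs_out[[length(dsegs_out) + 1L]] <-
        list(cycle_index = dsg$cycle_index, time_min = ti, signal = sig)
    }

    applyNB <- function(x, t) {
      y <- x * (1 - preset@bleach_per_frame)^(round(t / dt))
      if (preset@trace_noise_cv > 0)
        y <- y * (1 + preset@trace_noise_cv * stats::rnorm(length(y)))
      pmax(y, 0)
    }
    mother <- applyNB(mother, times)
    dsegs_out <- lapply(dsegs_out, function(sgm) {
      sgm$signal <- applyNB(sgm$signal, sgm$time_min); sgm
    })
    traces[[i]] <- list(
      cell_id = cid, time_min = times, mother = mother,
      daughter_segments = dsegs_out,
      mother_death_flag_min = if (r$fate == "died" &&
                                  nrow(cev) &&
                                  any(cev$outcome == "terminal_death"))
        r$fate_time_min else NA_real_)
    names(traces)[i] <- cid
  }
  new("TraceSet", sampling_interval_min = dt, traces = traces)
}
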