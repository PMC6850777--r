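#' Simulate a cohort of aging mother cells with ground-truth GLM events
#'
#' Draws, for each mother cell, a baseline replicative lifespan `L` from the
#' preset's Gompertz law and then walks the cell division by division. Each
#' division carries a GLM probability `h(a; L)`: `h_young` while more than five
#' divisions remain before `L`, and the corresponding `late_ramp` entry over
#' the last five divisions. When a GLM fires, a log-normal correction time
#' competes with exponential cytokinesis and mother-death clocks: the event is
#' corrected if correction wins, otherwise it is terminal and truncates the
#' lifespan at that cycle (cytokinesis counts the separated daughter as the
#' final division; mother death does not). Cells are right-censored by
#' per-division trap loss (`censor_hazard`) and by the 72 h end of run.
#'
#' With probability `multi_event_prob` a GLM cycle additionally contains an
#' earlier transient event. Scored `events` contain only the final event per
#' cycle; the transient ones are kept in the `superseded` slot so that the
#' caller's final-event rule can be exercised against them.
#'
#' Identical `(preset, n_cells, seed)` triples reproduce identical cohorts.
#'
#' @param preset a [StrainPreset-class].
#' @param n_cells number of mother cells (>= 1).
#' @param seed integer seed.
#' @return A [GLMCohort-class] with ground-truth events.
#' @examples
#' coh <- simulateCohort(strainPreset(), 50, seed = 1)
#' mean(cohortRecords(coh)$rls)
#' @export
simulateCohort <- function(preset, n_cells, seed) {
  validObject(preset)
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1)
    stop("n_cells must be >= 1")
  n_cells <- as.integer(n_cells)
  set.seed(as.integer(seed))

  run_end <- 72 * 60
  dt_ramp_sup <- 10          # recovery ramp of a superseded transient (min)
  plateau_after_sup <- 10    # 2N dwell between transient recovery and final onset

  lam_c <- preset@lambda_cytokinesis / 60
  lam_d <- preset@terminal_death_hazard / 60
  grate <- preset@lifespan_shape * exp(-preset@lifespan_shape * preset@lifespan_modal)

  recs <- vector("list", n_cells)
  divl <- vector("list", n_cells)
  evl <- list(); supl <- list()
  slug <- gsub("[^A-Za-z0-9]+", "", preset@name)

  for (i in seq_len(n_cells)) {
    cid <- sprintf("%s_c%05d", slug, i)
    first_det <- min(stats::rexp(1, 1 / 40), 300)
    L <- max(1L, as.integer(round(
      flexsurv::rgompertz(1, preset@lifespan_shape, grate) * preset@lifespan_scale)))
    t <- first_det
    divs <- numeric(0)
    fate <- NA_character_; fate_time <- NA_real_; rls <- NA_integer_
    a <- 0L
    repeat {
      a <- a + 1L
      D <- preset@cycle_minutes * (1 + preset@cycle_slowdown)^(a - 1)
      if (t + D > run_end) {
        # an arrested cycle may itself overrun the nominal end of run; the
        # observation window then closes at the last completed division
        fate <- "censored_end"; fate_time <- max(run_end, t); rls <- a - 1L
        break
      }
      if (stats::runif(1) < preset@censor_hazard) {
        fate <- "censored_lost"; fate_time <- t + stats::runif(1) * D
        rls <- a - 1L; break
      }
      h <- if (a <= L - 5L) preset@h_young else preset@late_ramp[a - L + 5L]
      if (stats::runif(1) < h) {
        onset <- t + D
        if (stats::runif(1) < preset@multi_event_prob) {
          Tsup <- min(stats::rlnorm(1, log(preset@duration_median_min),
                                    preset@duration_sdlog), 45)
          supl[[length(supl) + 1L]] <- data.frame(
            cell_id = cid, cycle_index = a, onset_min = onset,
            resolution_min = onset + Tsup, outcome = "corrected",
            duration_min = Tsup, stringsAsFactors = FALSE)
          onset <- onset + Tsup + dt_ramp_sup + plateau_after_sup
        }
        Tr <- stats::rlnorm(1, log(preset@duration_median_min), preset@duration_sdlog)
        Tc <- if (lam_c > 0) stats::rexp(1, lam_c) else Inf
        Td <- if (lam_d > 0) stats::rexp(1, lam_d) else Inf
        if (Tr < Tc && Tr < Td) {
          res <- onset + Tr
          ramp <- stats::runif(1, 10, 15)
          t <- res + ramp
          divs <- c(divs, t)
          evl[[length(evl) + 1L]] <- data.frame(
            cell_id = cid, cycle_index = a, onset_min = onset,
            resolution_min = res, outcome = "corrected", duration_min = Tr,
            stringsAsFactors = FALSE)
          if (a >= L) {  # terminal-age division completed; baseline arrest next
            fate <- if (stats::runif(1) < 0.6) "died" else "senesced"
            fate_time <- max(t, min(t + preset@cycle_minutes *
                                      (1 + preset@cycle_slowdown)^a, run_end))
            rls <- a; break
          }
        } else if (Tc < Td) {
          sep <- onset + Tc
          divs <- c(divs, sep)
          evl[[length(evl) + 1L]] <- data.frame(
            cell_id = cid, cycle_index = a, onset_min = onset,
            resolution_min = NA_real_, outcome = "terminal_cytokinesis",
            duration_min = NA_real_, stringsAsFactors = FALSE)
          fate <- "senesced"; fate_time <- max(sep, min(sep + 60, run_end))
          rls <- a; break
        } else {
          evl[[length(evl) + 1L]] <- data.frame(
            cell_id = cid, cycle_index = a, onset_min = onset,
            resolution_min = NA_real_, outcome = "terminal_death",
            duration_min = NA_real_, stringsAsFactors = FALSE)
          fate <- "died"; fate_time <- onset + Td
          rls <- a - 1L; break
        }
      } else {
        t <- t + D
        divs <- c(divs, t)
        if (a >= L) {
          fate <- if (stats::runif(1) < 0.6) "died" else "senesced"
          fate_time <- min(t + preset@cycle_minutes *
                             (1 + preset@cycle_slowdown)^a, run_end)
          rls <- a; break
        }
      }
    }
    recs[[i]] <- data.frame(
      cell_id = cid, strain = preset@name, first_detection_min = first_det,
      fate = fate, fate_time_min = fate_time, rls = rls,
      stringsAsFactors = FALSE)
    divl[[i]] <- divs
    names(divl)[i] <- cid
  }

  records <- do.call(rbind, recs)
  events <- if (length(evl)) do.call(rbind, evl) else emptyEventsDf()
  superseded <- if (length(supl)) do.call(rbind, supl) else emptyEventsDf()
  new("GLMCohort", records = records, division_times = divl,
      events = events, superseded = superseded,
      preset_name = preset@name, seed = as.integer(seed))
}
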