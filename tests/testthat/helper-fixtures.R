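# Shared fixtures, built once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small wild-type cohorts with traces at two noise levels
wtCohort <- function(cv = 0.05, n = 120, seed = 11) {
  key <- sprintf("wt_%g_%d_%d", cv, n, seed)
  fixture(key, function() {
    p <- strainPreset(trace_noise_cv = cv)
    coh <- simulateCohort(p, n, seed = seed)
    list(preset = p, cohort = coh,
         traces = synthesizeTraces(coh, p, seed = seed + 1))
  })
}

calledEvents <- function(cv = 0.05, n = 120, seed = 11) {
  key <- sprintf("called_%g_%d_%d", cv, n, seed)
  fixture(key, function() {
    fx <- wtCohort(cv, n, seed)
    callEvents(fx$traces, fx$cohort)
  })
}

withEvents <- function(cohort, events) {
  new("GLMCohort", records = cohortRecords(cohort),
      division_times = divisionTimes(cohort), events = events,
      superseded = yeastGLM:::emptyEventsDf(),
      preset_name = cohort@preset_name, seed = cohort@seed)
}

# hand-built toy cohort: A (rls 3, event at age 2, died), B (rls 2, none,
# died), C (censored after age 2, event at age 1)
toyCohort <- function() {
  rec <- data.frame(
    cell_id = c("A", "B", "C"), strain = "toy",
    first_detection_min = 0,
    fate = c("died", "died", "censored_lost"),
    fate_time_min = c(300, 200, 210), rls = c(3L, 2L, 2L),
    stringsAsFactors = FALSE)
  divs <- list(A = c(90, 180, 270), B = c(90, 180), C = c(90, 180))
  ev <- data.frame(
    cell_id = c("A", "C"), cycle_index = c(2L, 1L),
    onset_min = c(150, 60), resolution_min = c(170, 80),
    outcome = "corrected", duration_min = c(20, 20),
    stringsAsFactors = FALSE)
  new("GLMCohort", records = rec, division_times = divs, events = ev,
      superseded = yeastGLM:::emptyEventsDf(), preset_name = "toy",
      seed = 0L)
}

# F1 of called events against ground truth, matching on (cell, cycle)
eventF1 <- function(called, truth) {
  key <- function(d) paste(d$cell_id, d$cycle_index)
  tp <- sum(key(called) %in% key(truth))
  prec <- if (nrow(called)) tp / nrow(called) else 1
  rec <- if (nrow(truth)) tp / nrow(truth) else 1
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}
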