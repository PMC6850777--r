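test_that("inclusion filter keeps cells detected within the cutoff, boundary included", {
  coh <- toyCohort()
  coh@records$first_detection_min <- c(200, 180, 0)
  f <- filterFirstHours(coh)
  expect_identical(cohortRecords(f)$cell_id, c("B", "C"))
  coh@records$first_detection_min <- rep(0, 3)
  expect_identical(cohortRecords(filterFirstHours(coh)), cohortRecords(coh))
})

test_that("birth-aligned event curve follows the censoring convention by hand count", {
  curve <- glmProbabilityByAge(toyCohort(), "birth")
  expect_equal(curve$p, c(1 / 3, 1 / 3, 0))
  expect_equal(curve$n_at_risk, c(3L, 3L, 1L))
  expect_equal(curve$sem, sqrt(curve$p * (1 - curve$p) / curve$n_at_risk))
  noev <- withEvents(toyCohort(), yeastGLM:::emptyEventsDf())
  expect_true(all(glmProbabilityByAge(noev, "birth")$p == 0))
})

test_that("death alignment restricts to dead cells and shows the late-life rise", {
  curve <- glmProbabilityByAge(toyCohort(), "death")
  # only A and B die; A's event at age 2 is 2 divisions before death (rls 3)
  expect_equal(curve$n_at_risk[1], 2L)
  expect_equal(curve$p[2], 1 / 2)
  coh <- wtCohort(cv = 0.05, n = 300, seed = 41)$cohort
  dcurve <- glmProbabilityByAge(coh, "death")
  expect_gt(dcurve$p[dcurve$divisions_before_death == 1],
            dcurve$p[dcurve$divisions_before_death == 10])
})

test_that("Cochran Q reproduces the hand-derived toy exactly", {
  X <- rbind(c(1, 1, 0), c(1, 0, 0), c(1, 1, 1), c(0, 0, 0))
  out <- cochranQ(X)
  expect_equal(out$Q, 3.0)
  expect_identical(out$df, 2L)
  expect_equal(out$p_value, 0.2231302, tolerance = 1e-6)
  # identical columns for every subject give Q = 0, p = 1
  same <- matrix(rep(c(1, 1, 0, 1), 3), ncol = 3)
  expect_equal(cochranQ(same)$Q, 0)
  expect_equal(cochranQ(same)$p_value, 1)
  # row permutation invariance
  expect_equal(cochranQ(X[c(3, 1, 4, 2), ])$Q, 3.0)
})

test_that("Cochran Q trend flags the wild-type age ramp", {
  coh <- wtCohort(cv = 0.05, n = 300, seed = 41)$cohort
  out <- cochranQTrend(coh, age_bins = c(0, 8, 16, 24, 32))
  expect_lt(out$p_value, 0.05)
  expect_error(cochranQTrend(toyCohort()), "complete-case")
})

test_that("KM equals empirical survival with no censoring; censored cells enter the risk set", {
  coh <- toyCohort()
  coh@records$fate <- c("died", "died", "died")
  fit <- kmSurvival(coh)
  # deaths at divisions (2, 2, 3): empirical survival 1/3 after 2, 0 after 3
  expect_equal(fit$time, c(2, 3))
  expect_equal(fit$surv, c(1 / 3, 0))
  expect_equal(restrictedMeanRLS(fit), mean(c(3, 2, 2)))
  # excluding late-biased censoring shifts the mean down
  coh2 <- wtCohort(cv = 0.05, n = 300, seed = 41)$cohort
  m_incl <- restrictedMeanRLS(kmSurvival(coh2, include_censored = TRUE))
  m_excl <- restrictedMeanRLS(kmSurvival(coh2, include_censored = FALSE))
  expect_gt(m_incl, m_excl - 1e-9)
})

test_that("log-rank matches the hand-computed toy and degenerate cases", {
  mkcoh <- function(times, ids) {
    rec <- data.frame(cell_id = ids, strain = "t", first_detection_min = 0,
                      fate = "died", fate_time_min = times * 100,
                      rls = as.integer(times), stringsAsFactors = FALSE)
    divs <- lapply(times, function(t) seq_len(t) * 90)
    names(divs) <- ids
    new("GLMCohort", records = rec, division_times = divs,
        events = yeastGLM:::emptyEventsDf(),
        superseded = yeastGLM:::emptyEventsDf(), preset_name = "t", seed = 0L)
  }
  A <- mkcoh(c(1, 2), c("a1", "a2"))
  B <- mkcoh(c(3, 4), c("b1", "b2"))
  out <- logrankTest(A, B)
  expect_equal(out$chisq, 2.88, tolerance = 0.01)
  expect_equal(logrankTest(A, A)$chisq, 0, tolerance = 1e-12)
  Bc <- B; Bc@records$fate <- "censored_lost"
  expect_error(logrankTest(A, Bc), "zero deaths")
})

test_that("bootstrap intervals behave: degenerate width, binomial width, 1/sqrt(n) shrink", {
  mk <- function(n, p = 0.25, seed = 1) {
    set.seed(seed)
    rec <- data.frame(cell_id = sprintf("c%04d", 1:n), strain = "t",
                      first_detection_min = 0, fate = "died",
                      fate_time_min = 100,
                      rls = 1L + as.integer(runif(n) < p),
                      stringsAsFactors = FALSE)
    divs <- lapply(rec$rls, function(r) seq_len(r) * 40)
    names(divs) <- rec$cell_id
    new("GLMCohort", records = rec, division_times = divs,
        events = yeastGLM:::emptyEventsDf(),
        superseded = yeastGLM:::emptyEventsDf(), preset_name = "t", seed = 0L)
  }
  prop2 <- function(rec, ev) mean(rec$rls == 2L)
  # all cells identical: zero-width interval
  same <- mk(50, p = 0)
  ci0 <- bootstrapCI(same, prop2, bootstrapConfig(200, seed = 1))
  expect_equal(ci0$lower, ci0$upper)
  # percentile95 width close to the analytic binomial interval width
  coh <- mk(400, p = 0.25, seed = 2)
  phat <- prop2(coh@records, NULL)
  ci <- bootstrapCI(coh, prop2, bootstrapConfig(2000, "percentile95", seed = 3))
  analytic <- 2 * qnorm(0.975) * sqrt(phat * (1 - phat) / 400)
  expect_lt(abs((ci$upper - ci$lower) - analytic) / analytic, 0.2)
  # reproducibility and ~2x shrink per 4x n
  ci_b <- bootstrapCI(coh, prop2, bootstrapConfig(2000, "percentile95", seed = 3))
  expect_identical(ci, ci_b)
  w <- vapply(c(100, 400, 1600), function(n) {
    ci <- bootstrapCI(mk(n, 0.25, seed = n), prop2,
                      bootstrapConfig(500, seed = 5))
    ci$upper - ci$lower
  }, numeric(1))
  expect_equal(w[1] / w[2], 2, tolerance = 0.35)
  expect_equal(w[2] / w[3], 2, tolerance = 0.35)
})

test_that("Spearman event-vs-remaining-lifespan matches the hand-ranked toy", {
  rec <- data.frame(cell_id = c("a", "b", "c", "d"), strain = "t",
                    first_detection_min = 0, fate = "died",
                    fate_time_min = 1000, rls = c(3L, 4L, 5L, 6L),
                    stringsAsFactors = FALSE)
  divs <- lapply(rec$rls, function(r) seq_len(r) * 90)
  names(divs) <- rec$cell_id
  ev <- data.frame(cell_id = c("a", "b"), cycle_index = 2L, onset_min = 100,
                   resolution_min = 120, outcome = "corrected",
                   duration_min = 20, stringsAsFactors = FALSE)
  coh <- new("GLMCohort", records = rec, division_times = divs, events = ev,
             superseded = yeastGLM:::emptyEventsDf(), preset_name = "t",
             seed = 0L)
  # remaining lifespans at age 2: (1,2,3,4); indicators (1,1,0,0)
  expect_equal(spearmanEventVsRemaining(coh, 2), -0.894, tolerance = 1e-3)
  ev0 <- ev[0, ]
  coh0 <- withEvents(coh, ev0)
  expect_warning(r <- spearmanEventVsRemaining(coh0, 2), "constant")
  expect_true(is.na(r))
  # events predict shorter remaining lifespan in an aged cohort
  aged <- wtCohort(cv = 0.05, n = 300, seed = 41)$cohort
  la <- yeastGLM:::lastObservedAge(cohortRecords(aged), cohortEvents(aged))
  late <- as.integer(stats::quantile(la, 0.7))
  expect_lt(spearmanEventVsRemaining(aged, late), 0)
})

test_that("history dependence is detected under frailty and absent by construction otherwise", {
  # memoryless generator: conditioning on a prior event cannot matter much
  p <- strainPreset(h_young = 0.05, late_ramp = rep(0.05, 5),
                    lambda_cytokinesis = 0, terminal_death_hazard = 0,
                    censor_hazard = 0, multi_event_prob = 0)
  coh <- simulateCohort(p, 800, seed = 31)
  hd <- historyDependence(coh, bootstrapConfig(300, seed = 1))
  expect_lt(abs(hd$p_prior$estimate - hd$p_none$estimate), 0.02)
  # the frailty structure of the aging preset induces positive history dependence
  aged <- wtCohort(cv = 0.05, n = 300, seed = 41)$cohort
  hd2 <- historyDependence(aged, bootstrapConfig(300, seed = 1))
  expect_gt(hd2$p_prior$estimate, hd2$p_none$estimate)
  # toy: events only in cells with prior events
  rec <- cohortRecords(toyCohort())
  ev <- data.frame(cell_id = c("A", "A"), cycle_index = c(1L, 3L),
                   onset_min = c(50, 250), resolution_min = c(60, 260),
                   outcome = "corrected", duration_min = 10,
                   stringsAsFactors = FALSE)
  coh3 <- withEvents(toyCohort(), ev)
  hd3 <- historyDependence(coh3, bootstrapConfig(100, seed = 1))
  expect_gt(hd3$p_prior$estimate, 0)
  expect_equal(hd3$p_none$estimate, 0)
})

test_that("counterfactual lifespan gain is exact on toys", {
  coh <- toyCohort()
  # uncensored cells: A (rls 3, first event age 2 -> cf 2), B (rls 2, none)
  expect_equal(counterfactualLifespanGain(coh), 100 * (2.5 / 2 - 1))
  noev <- withEvents(coh, yeastGLM:::emptyEventsDf())
  expect_equal(counterfactualLifespanGain(noev), 0)
  # two cells rls 10, one corrected event at age 5: gain 33.3%
  rec <- data.frame(cell_id = c("x", "y"), strain = "t",
                    first_detection_min = 0, fate = "died",
                    fate_time_min = 1000, rls = 10L, stringsAsFactors = FALSE)
  divs <- list(x = seq_len(10) * 90, y = seq_len(10) * 90)
  ev <- data.frame(cell_id = "x", cycle_index = 5L, onset_min = 400,
                   resolution_min = 420, outcome = "corrected",
                   duration_min = 20, stringsAsFactors = FALSE)
  coh2 <- new("GLMCohort", records = rec, division_times = divs, events = ev,
              superseded = yeastGLM:::emptyEventsDf(), preset_name = "t",
              seed = 0L)
  expect_equal(counterfactualLifespanGain(coh2), 100 * (10 / 7.5 - 1))
})

test_that("duration-vs-age t-test matches the pooled-variance hand computation", {
  ev <- data.frame(cell_id = letters[1:6], cycle_index = c(1, 1, 1, 9, 9, 9),
                   onset_min = 0, resolution_min = c(1, 2, 3, 2, 3, 4),
                   outcome = "corrected",
                   duration_min = c(1, 2, 3, 2, 3, 4),
                   stringsAsFactors = FALSE)
  out <- durationVsAgeTest(ev)
  expect_equal(out$t, -1.2247, tolerance = 1e-4)
  expect_equal(out$df, 4)
  expect_equal(out$p_value, 0.2879, tolerance = 1e-3)
  ev$duration_min <- rep(c(1, 2, 3), 2)
  out2 <- durationVsAgeTest(ev)
  expect_equal(out2$t, 0)
  expect_equal(out2$p_value, 1)
  ev$duration_min <- 2
  expect_error(durationVsAgeTest(ev), "degenerate")
})

test_that("event-aligned averaging normalizes to 1N and recovers the correction shape", {
  fx <- wtCohort(cv = 0, n = 120, seed = 11)
  truth <- cohortEvents(fx$cohort)
  al <- alignToEvent(fx$traces, truth, min_duration_min = 30)
  # just before resolution (inside every >30-min arrest) the mother sits at
  # the leak level, well below 1N; after correction she is back near 1N
  pre <- al$mean[al$rel_time_min >= -25 & al$rel_time_min <= -10]
  post <- al$mean[al$rel_time_min >= 20]
  expect_lt(mean(pre, na.rm = TRUE), 0.6)
  expect_gt(mean(post, na.rm = TRUE), 0.85)
  # a single trace aligns to itself
  one <- truth[truth$outcome == "corrected" & truth$duration_min > 30, ][1, ]
  al1 <- alignToEvent(fx$traces, one, min_duration_min = 30)
  expect_true(all(al1$n <= 1))
  expect_error(alignToEvent(fx$traces, truth, min_duration_min = 1e6),
               "no corrected events")
})

test_that("terminal fractions are exact on toy counts", {
  # 10 deaths of which 3 terminal-GLM; 20 events of which 3 uncorrected
  rec <- data.frame(cell_id = sprintf("c%02d", 1:10), strain = "t",
                    first_detection_min = 0, fate = "died",
                    fate_time_min = 5000, rls = 30L, stringsAsFactors = FALSE)
  divs <- lapply(1:10, function(i) seq_len(30) * 80)
  names(divs) <- rec$cell_id
  ev <- data.frame(
    cell_id = rep(rec$cell_id, each = 2),
    cycle_index = rep(c(5L, 10L), 10), onset_min = 1, resolution_min = 2,
    outcome = "corrected", duration_min = 1, stringsAsFactors = FALSE)
  term <- ev$cell_id %in% rec$cell_id[1:3] & ev$cycle_index == 10L
  ev$outcome[term] <- "terminal_cytokinesis"
  ev$resolution_min[term] <- NA_real_
  ev$duration_min[term] <- NA_real_
  coh <- new("GLMCohort", records = rec, division_times = divs, events = ev,
             superseded = yeastGLM:::emptyEventsDf(), preset_name = "t",
             seed = 0L)
  out <- terminalFractionStats(coh, bootstrapConfig(100, seed = 2))
  expect_equal(out$death_fraction$estimate, 0.30)
  expect_equal(out$uncorrected_fraction$estimate, 0.15)
  allcorr <- ev; allcorr$outcome <- "corrected"
  allcorr$resolution_min <- 2; allcorr$duration_min <- 1
  out2 <- terminalFractionStats(withEvents(coh, allcorr),
                                bootstrapConfig(100, seed = 2))
  expect_equal(out2$death_fraction$estimate, 0)
  expect_equal(out2$uncorrected_fraction$estimate, 0)
})

test_that("age curve on ground truth recovers the generator hazard pointwise", {
  p <- strainPreset(h_young = 0.08, late_ramp = rep(0.08, 5),
                    lambda_cytokinesis = 0, terminal_death_hazard = 0,
                    censor_hazard = 0, multi_event_prob = 0)
  coh <- simulateCohort(p, 5000, seed = 55)
  curve <- glmProbabilityByAge(coh, "birth")
  sub <- curve[curve$n_at_risk >= 200, ]
  ci_lo <- sub$p - 1.96 * sqrt(0.08 * 0.92 / sub$n_at_risk)
  ci_hi <- sub$p + 1.96 * sqrt(0.08 * 0.92 / sub$n_at_risk)
  # pointwise 95% coverage of the true hazard, allowing a few misses
  expect_gte(mean(0.08 >= ci_lo & 0.08 <= ci_hi), 0.9)
})

test_that("statistics from called events agree with ground truth within CI overlap", {
  fx <- wtCohort(cv = 0.05, n = 120, seed = 11)
  calledCoh <- withEvents(fx$cohort, calledEvents(cv = 0.05, n = 120, seed = 11))
  cfg <- bootstrapConfig(400, seed = 3)
  tf_true <- terminalFractionStats(fx$cohort, cfg)
  tf_call <- terminalFractionStats(calledCoh, cfg)
  overlap <- function(a, b) a$lower <= b$upper && b$lower <= a$upper
  expect_true(overlap(tf_true$death_fraction, tf_call$death_fraction))
  expect_true(overlap(tf_true$uncorrected_fraction, tf_call$uncorrected_fraction))
  gain_true <- counterfactualLifespanGain(fx$cohort)
  gci <- bootstrapCI(calledCoh, function(r, e) {
    unc <- r$fate %in% c("died", "senesced")
    r <- r[unc, , drop = FALSE]
    ev <- e[e$cell_id %in% r$cell_id, , drop = FALSE]
    first <- tapply(ev$cycle_index, ev$cell_id, min)
    cf <- r$rls
    i <- match(names(first), r$cell_id)
    cf[i] <- pmin(cf[i], as.integer(first))
    100 * (mean(r$rls) / mean(cf) - 1)
  }, cfg)
  expect_gte(gain_true, gci$lower)
  expect_lte(gain_true, gci$upper)
})
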