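#' Keep cells identified early in the experiment
#'
#' Restricts a cohort to cells first detected within `cutoff_min` minutes
#' (boundary included), the standard guard ensuring that only young, healthy
#' cells enter the aging statistics.
#'
#' @param cohort a [GLMCohort-class].
#' @param cutoff_min inclusion cutoff in minutes (default 180).
#' @return the filtered [GLMCohort-class].
#' @export
filterFirstHours <- function(cohort, cutoff_min = 180) {
  keep <- cohort@records$first_detection_min <= cutoff_min
  ids <- cohort@records$cell_id[keep]
  new("GLMCohort",
      records = cohort@records[keep, , drop = FALSE],
      division_times = cohort@division_times[ids],
      events = cohort@events[cohort@events$cell_id %in% ids, , drop = FALSE],
      superseded = cohort@superseded[cohort@superseded$cell_id %in% ids, , drop = FALSE],
      preset_name = cohort@preset_name, seed = cohort@seed)
}

# last replicative age at which a cell was observed at risk: its completed
# divisions, extended by a terminal-event cycle (a terminal death occurs in
# cycle rls + 1)
lastObservedAge <- function(records, events) {
  la <- records$rls
  if (nrow(events)) {
    mx <- tapply(events$cycle_index, events$cell_id, max)
    i <- match(names(mx), records$cell_id)
    la[i] <- pmax(la[i], as.integer(mx))
  }
  la
}

#' Event probability by replicative age
#'
#' Birth alignment: at age `a` the risk set contains every cell observed for
#' at least `a` divisions, including cells censored later (a cell lost at age
#' 20 contributes up to age 19). Death alignment: the risk set is restricted
#' to cells that died or senesced, indexed by divisions before death (1 = the
#' final observed cycle). The per-age probability is events / cells at risk
#' with binomial standard errors.
#'
#' @param cohort a [GLMCohort-class].
#' @param alignment `"birth"` or `"death"`.
#' @return data.frame with `age` (or `divisions_before_death`), `p`, `sem`,
#'   `n_at_risk`, `n_events`.
#' @export
glmProbabilityByAge <- function(cohort, alignment = c("birth", "death")) {
  alignment <- match.arg(alignment)
  rec <- cohort@records
  ev <- cohort@events
  if (alignment == "birth") {
    la <- lastObservedAge(rec, ev)
    amax <- max(la, 0L)
    if (amax == 0L) stop("no observed divisions")
    ages <- seq_len(amax)
    n_risk <- vapply(ages, function(a) sum(la >= a), integer(1))
    n_ev <- vapply(ages, function(a) sum(ev$cycle_index == a), integer(1))
    keep <- n_risk > 0
    p <- n_ev[keep] / n_risk[keep]
    data.frame(age = ages[keep], p = p,
               sem = sqrt(p * (1 - p) / n_risk[keep]),
               n_at_risk = n_risk[keep], n_events = n_ev[keep])
  } else {
    dead <- rec$fate %in% c("died", "senesced")
    if (!any(dead)) stop("no dead or senesced cells for death alignment")
    recd <- rec[dead, , drop = FALSE]
    evd <- ev[ev$cell_id %in% recd$cell_id, , drop = FALSE]
    la <- lastObservedAge(recd, evd)
    # divisions before death: 1 is the final observed cycle
    dbd_ev <- la[match(evd$cell_id, recd$cell_id)] - evd$cycle_index + 1L
    dmax <- max(la)
    ds <- seq_len(dmax)
    n_risk <- vapply(ds, function(d) sum(la >= d), integer(1))
    n_ev <- vapply(ds, function(d) sum(dbd_ev == d), integer(1))
    keep <- n_risk > 0
    p <- n_ev[keep] / n_risk[keep]
    data.frame(divisions_before_death = ds[keep], p = p,
               sem = sqrt(p * (1 - p) / n_risk[keep]),
               n_at_risk = n_risk[keep], n_events = n_ev[keep])
  }
}

#' Cochran Q trend test for age-related event rates
#'
#' Bins each complete-case cell's divisions into age bins, scores each bin as
#' 1 if the cell had any GLM within it, and tests homogeneity of the bin
#' (column) totals: `Q = k(k-1) sum_j (C_j - Cbar)^2 / (k sum_i R_i - sum_i
#' R_i^2)` with `k` bins, column totals `C_j` and row totals `R_i`, referred
#' to chi-square with `k - 1` degrees of freedom. Complete cases are cells
#' observed through the last bin.
#'
#' @param cohort a [GLMCohort-class].
#' @param age_bins increasing integer break points; bin `j` covers ages
#'   `(age_bins[j], age_bins[j+1]]`. Default four equal bins over ages 1-20.
#' @return list with `Q`, `df`, `p_value`, `n_cells`.
#' @export
cochranQTrend <- function(cohort, age_bins = c(0, 5, 10, 15, 20)) {
  if (length(age_bins) < 3) stop("need at least 2 bins")
  rec <- cohort@records
  ev <- cohort@events
  la <- lastObservedAge(rec, ev)
  cc <- la >= age_bins[length(age_bins)]
  if (sum(cc) < 2) stop("fewer than 2 complete-case cells")
  ids <- rec$cell_id[cc]
  k <- length(age_bins) - 1L
  X <- matrix(0L, nrow = length(ids), ncol = k)
  evc <- ev[ev$cell_id %in% ids, , drop = FALSE]
  if (nrow(evc)) {
    bin <- findInterval(evc$cycle_index - 1L, age_bins)
    ok <- bin >= 1L & bin <= k
    for (r in which(ok))
      X[match(evc$cell_id[r], ids), bin[r]] <- 1L
  }
  out <- cochranQ(X)
  out$n_cells <- length(ids)
  out
}

#' Cochran Q statistic on a subjects-by-conditions binary matrix
#'
#' @param X 0/1 matrix, one row per subject, one column per condition.
#' @return list with `Q`, `df`, `p_value`.
#' @export
cochranQ <- function(X) {
  k <- ncol(X)
  Cj <- colSums(X)
  Ri <- rowSums(X)
  denom <- k * sum(Ri) - sum(Ri^2)
  Q <- if (denom <= 0) 0 else
    k * (k - 1) * sum((Cj - mean(Cj))^2) / denom
  list(Q = Q, df = k - 1L,
       p_value = stats::pchisq(Q, k - 1L, lower.tail = FALSE))
}

#' Kaplan-Meier replicative-lifespan curve
#'
#' Lifespan in divisions with right-censoring for cells lost before death or
#' senescence. With `include_censored = FALSE` censored cells are dropped
#' entirely (microdissection convention); with no censored cells present the
#' estimate equals the empirical survival function.
#'
#' @param cohort a [GLMCohort-class].
#' @param include_censored include censored cells as right-censored
#'   observations (default) or drop them.
#' @return a `survival::survfit` object on the divisions scale.
#' @export
kmSurvival <- function(cohort, include_censored = TRUE) {
  rec <- cohort@records
  status <- as.integer(rec$fate %in% c("died", "senesced"))
  if (!include_censored) {
    rec <- rec[status == 1L, , drop = FALSE]
    status <- rep(1L, nrow(rec))
  }
  if (!nrow(rec)) stop("no cells left for survival estimation")
  survival::survfit(survival::Surv(rec$rls, status) ~ 1)
}

#' Restricted mean replicative lifespan from a Kaplan-Meier curve
#'
#' Integrates the product-limit estimate up to the largest observed time
#' (censor-aware mean RLS).
#'
#' @param fit a `survival::survfit` object from [kmSurvival()].
#' @return scalar mean divisions.
#' @export
restrictedMeanRLS <- function(fit) {
  tt <- c(0, fit$time)
  ss <- c(1, fit$surv)
  sum(ss[-length(ss)] * diff(tt))
}

#' Log-rank comparison of two cohorts' lifespans
#'
#' @param cohortA,cohortB [GLMCohort-class] objects.
#' @param include_censored treat censored cells as right-censored (default)
#'   or drop them.
#' @return list with `chisq`, `df`, `p_value`.
#' @export
logrankTest <- function(cohortA, cohortB, include_censored = TRUE) {
  mk <- function(coh, g) {
    rec <- coh@records
    status <- as.integer(rec$fate %in% c("died", "senesced"))
    d <- data.frame(time = rec$rls, status = status, group = g)
    if (!include_censored) d <- d[d$status == 1L, , drop = FALSE]
    d
  }
  d <- rbind(mk(cohortA, "A"), mk(cohortB, "B"))
  if (any(tapply(d$status, d$group, sum) == 0))
    stop("log-rank undefined: a group has zero deaths")
  sd <- survival::survdiff(survival::Surv(time, status) ~ group, data = d)
  list(chisq = unname(sd$chisq), df = length(sd$n) - 1L,
       p_value = stats::pchisq(sd$chisq, length(sd$n) - 1L, lower.tail = FALSE))
}

#' Percentile bootstrap over cells
#'
#' Resamples whole cells (each carrying its events) with replacement and
#' returns the percentile interval of a statistic. `nonoverlap_p05` mode uses
#' 83.4% intervals, calibrated so that non-overlap of two comparable bars
#' corresponds to a two-group difference at about p = 0.05; `percentile95`
#' gives conventional 95% intervals.
#'
#' @param cohort a [GLMCohort-class].
#' @param statistic function(records, events) returning a scalar.
#' @param config a [BootstrapConfig-class].
#' @return list with `estimate`, `lower`, `upper`, `level`, `n_boot`.
#' @export
bootstrapCI <- function(cohort, statistic, config = bootstrapConfig()) {
  validObject(config)
  rec <- cohort@records
  ev <- cohort@events
  est <- statistic(rec, ev)
  set.seed(config@seed)
  n <- nrow(rec)
  ev_by_cell <- split(seq_len(nrow(ev)), ev$cell_id)
  vals <- numeric(config@n_boot)
  n_bad <- 0L
  for (b in seq_len(config@n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    r2 <- rec[idx, , drop = FALSE]
    # resampled cells get fresh ids so duplicated cells stay distinct
    lst <- ev_by_cell[r2$cell_id]
    reps <- vapply(lst, length, integer(1))
    e2 <- ev[unlist(lst, use.names = FALSE), , drop = FALSE]
    newid <- sprintf("bs%05d", seq_len(n))
    e2$cell_id <- rep(newid, reps)
    r2$cell_id <- newid
    v <- tryCatch(statistic(r2, e2), error = function(e) NA_real_)
    if (is.na(v)) n_bad <- n_bad + 1L
    vals[b] <- v
  }
  if (n_bad > 0.01 * config@n_boot)
    stop(sprintf("statistic undefined on %d of %d resamples", n_bad, config@n_boot))
  level <- if (config@level_mode == "percentile95") 0.95 else 0.834
  qs <- stats::quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  list(estimate = est, lower = qs[1], upper = qs[2], level = level,
       n_boot = config@n_boot)
}

#' Spearman correlation between a GLM at an age and remaining lifespan
#'
#' Among cells alive at `age`, correlates the binary indicator of a GLM at
#' that age with the remaining lifespan (`rls - age`) using midrank-tied
#' Spearman correlation.
#'
#' @param cohort a [GLMCohort-class].
#' @param age replicative age (divisions).
#' @return Spearman rho (`NA` with a warning if the indicator is constant).
#' @export
spearmanEventVsRemaining <- function(cohort, age) {
  rec <- cohort@records
  ev <- cohort@events
  la <- lastObservedAge(rec, ev)
  alive <- la >= age
  if (!any(alive)) stop("empty risk set at the requested age")
  ids <- rec$cell_id[alive]
  ind <- as.integer(ids %in% ev$cell_id[ev$cycle_index == age])
  remaining <- rec$rls[alive] - age
  if (length(unique(ind)) < 2) {
    warning("event indicator constant at this age; rho undefined")
    return(NA_real_)
  }
  stats::cor(ind, remaining, method = "spearman")
}

#' History dependence of GLM events
#'
#' For every division of every cell (from age 2 on), classifies the mother by
#' whether she had any GLM at an earlier age, and pools divisions to estimate
#' P(event | >= 1 prior event) and P(event | no prior event), each with a
#' bootstrap CI over cells.
#'
#' @param cohort a [GLMCohort-class].
#' @param config a [BootstrapConfig-class].
#' @return list with `p_prior`, `p_none` (each `estimate`, `lower`, `upper`),
#'   and division counts per stratum.
#' @export
historyDependence <- function(cohort, config = bootstrapConfig()) {
  tab <- function(rec, ev) {
    la <- lastObservedAge(rec, ev)
    evs <- split(ev$cycle_index, ev$cell_id)
    np <- nn <- dp <- dn <- 0
    for (i in seq_len(nrow(rec))) {
      L <- la[i]
      if (L < 2L) next
      cyc <- evs[[rec$cell_id[i]]]
      f <- if (length(cyc)) min(cyc) else Inf
      none_hi <- min(f, L)             # divisions 2..none_hi have no prior event
      dn <- dn + max(0, none_hi - 1)
      nn <- nn + sum(cyc >= 2 & cyc <= none_hi)
      if (f < L) {
        dp <- dp + (L - f)
        np <- np + sum(cyc > f & cyc <= L)
      }
    }
    c(num.prior = np, num.none = nn, den.prior = dp, den.none = dn)
  }
  full <- tab(cohort@records, cohort@events)
  pp <- function(which) {
    est <- if (full[[paste0("den.", which)]] == 0) NA_real_ else
      full[[paste0("num.", which)]] / full[[paste0("den.", which)]]
    # small cohorts can lose a stratum entirely in a resample; report the
    # point estimate with absent bounds rather than failing
    tryCatch(
      bootstrapCI(cohort, function(r, e) {
        x <- tab(r, e)
        if (x[[paste0("den.", which)]] == 0) return(NA_real_)
        x[[paste0("num.", which)]] / x[[paste0("den.", which)]]
      }, config),
      error = function(e) list(estimate = est, lower = NA_real_,
                               upper = NA_real_, level = NA_real_,
                               n_boot = config@n_boot))
  }
  list(p_prior = pp("prior"), p_none = pp("none"),
       n_divisions_prior = unname(full["den.prior"]),
       n_divisions_none = unname(full["den.none"]))
}

#' Counterfactual lifespan gain from GLM correction
#'
#' For uncensored cells, the counterfactual lifespan of a cell is its observed
#' lifespan truncated at the age of its first GLM (as if every GLM were
#' terminal). The gain is `100 * (mean observed / mean counterfactual - 1)`
#' percent: how much longer mothers live because corrections rescue them.
#'
#' @param cohort a [GLMCohort-class].
#' @return percent gain (scalar).
#' @export
counterfactualLifespanGain <- function(cohort) {
  rec <- cohort@records
  unc <- rec$fate %in% c("died", "senesced")
  rec <- rec[unc, , drop = FALSE]
  if (!nrow(rec)) stop("no uncensored cells")
  ev <- cohort@events[cohort@events$cell_id %in% rec$cell_id, , drop = FALSE]
  first <- tapply(ev$cycle_index, ev$cell_id, min)
  cf <- rec$rls
  i <- match(names(first), rec$cell_id)
  cf[i] <- pmin(cf[i], as.integer(first))
  100 * (mean(rec$rls) / mean(cf) - 1)
}

#' Test whether correction duration depends on mother age
#'
#' Splits corrected events at the cohort's median event age and compares
#' durations between the two groups with a two-tailed pooled-variance t-test.
#'
#' @param events data.frame of events with `duration_min` and `cycle_index`
#'   (corrected events only are used).
#' @return list with `t`, `df`, `p_value`, group sizes, `split_age`.
#' @export
durationVsAgeTest <- function(events) {
  corr <- events[events$outcome == "corrected", , drop = FALSE]
  med <- stats::median(corr$cycle_index)
  young <- corr$duration_min[corr$cycle_index < med]
  old <- corr$duration_min[corr$cycle_index >= med]
  if (length(young) < 2 || length(old) < 2)
    stop("need at least 2 durations per age group")
  if (stats::sd(c(young, old)) == 0) stop("degenerate variance")
  tt <- stats::t.test(young, old, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, n_young = length(young), n_old = length(old),
       split_age = med)
}

#' Average traces aligned to the correction event
#'
#' Each qualifying trace is normalized so its post-anaphase (1N) plateau is 1,
#' shifted so the resolution time is 0, and the pointwise mean and standard
#' error are taken over events with duration above `min_duration_min`.
#'
#' @param traces a [TraceSet-class].
#' @param events corrected events with `resolution_min`.
#' @param min_duration_min minimum event duration (default 30).
#' @param window_min half-width of the aligned window (default 60).
#' @return data.frame with `rel_time_min`, `mean`, `sem`, `n`.
#' @export
alignToEvent <- function(traces, events, min_duration_min = 30,
                         window_min = 60) {
  ev <- events[events$outcome == "corrected" &
               !is.na(events$resolution_min) &
               events$duration_min > min_duration_min, , drop = FALSE]
  if (!nrow(ev)) stop("no corrected events longer than the duration cutoff")
  dt <- traces@sampling_interval_min
  rel <- seq(-window_min, window_min, by = dt)
  acc <- matrix(NA_real_, nrow = nrow(ev), ncol = length(rel))
  for (j in seq_len(nrow(ev))) {
    tr <- traces@traces[[ev$cell_id[j]]]
    if (is.null(tr)) next
    sg <- segmentCycles(tr, sampling_interval_min = dt)
    one_n <- stats::median(sg@ref_1n)
    shifted <- tr$time_min - ev$resolution_min[j]
    acc[j, ] <- stats::approx(shifted, tr$mother / one_n, xout = rel,
                              rule = 1)$y
  }
  n <- colSums(!is.na(acc))
  mu <- colMeans(acc, na.rm = TRUE)
  sem <- apply(acc, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  })
  data.frame(rel_time_min = rel, mean = mu, sem = sem, n = n)
}

#' Terminal-event fractions with bootstrap intervals
#'
#' Two proportions: the fraction of uncensored deaths caused by a terminal
#' GLM, and the fraction of all scored events that were not corrected, each
#' with a [bootstrapCI()] interval.
#'
#' @param cohort a [GLMCohort-class].
#' @param config a [BootstrapConfig-class].
#' @return list with `death_fraction` and `uncorrected_fraction` CIs.
#' @export
terminalFractionStats <- function(cohort, config = bootstrapConfig()) {
  deathFrac <- function(rec, ev) {
    dead <- rec$fate %in% c("died", "senesced")
    if (!any(dead)) return(NA_real_)
    ids <- rec$cell_id[dead]
    term <- unique(ev$cell_id[ev$outcome != "corrected"])
    sum(ids %in% term) / length(ids)
  }
  uncFrac <- function(rec, ev) {
    if (!nrow(ev)) return(NA_real_)
    mean(ev$outcome != "corrected")
  }
  if (!any(cohort@records$fate %in% c("died", "senesced")))
    stop("no uncensored deaths")
  if (!nrow(cohort@events)) stop("no scored events")
  list(death_fraction = bootstrapCI(cohort, deathFrac, config),
       uncorrected_fraction = bootstrapCI(cohort, uncFrac, config))
}
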