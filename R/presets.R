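#' Construct a StrainPreset
#'
#' Defaults are the wild-type (Htb2:mCherry) preset: a young-age GLM hazard of
#' 0.015 per division rising through `late_ramp` over the last five divisions
#' before baseline death, log-normal arrest durations (median 40 min,
#' sdlog 0.9), cytokinesis competing at 0.1 h^-1 and mother death at 0.01 h^-1
#' during arrest. Under these laws the analytic probability that retrograde
#' correction wins the competing-risk race, E[exp(-(lambda_c + lambda_d) T_r)],
#' is 0.90 (see [analyticCorrectedFraction()]).
#'
#' @param name genotype label.
#' @param lifespan_modal,lifespan_shape,lifespan_scale Gompertz lifespan law:
#'   modal lifespan in divisions, shape per division, and a scale multiplier
#'   applied to the drawn lifespan.
#' @param h_young per-division GLM probability more than five divisions before
#'   baseline death.
#' @param late_ramp length-5 vector of per-division GLM probabilities for the
#'   last five divisions before baseline death.
#' @param duration_median_min,duration_sdlog log-normal arrest-duration law.
#' @param lambda_cytokinesis hazard (h^-1) of daughter separation during arrest.
#' @param terminal_death_hazard hazard (h^-1) of mother death during arrest.
#' @param censor_hazard per-division probability of trap loss.
#' @param cycle_minutes,cycle_slowdown baseline cell-cycle duration (min) and
#'   fractional per-division lengthening.
#' @param trace_noise_cv,bleach_per_frame trace noise CV and per-frame
#'   fractional bleaching.
#' @param leak_range interval in (0, 0.5) for the mother's residual fraction of
#'   the 2N signal during a GLM.
#' @param multi_event_prob probability that a GLM cycle contains an earlier,
#'   superseded transient event.
#' @return A validated [StrainPreset-class] object.
#' @examples
#' wt <- strainPreset()
#' rad9 <- getPreset("rad9d")
#' @export
strainPreset <- function(name = "wild-type",
                         lifespan_modal = 36, lifespan_shape = 0.08,
                         lifespan_scale = 1,
                         h_young = 0.015,
                         late_ramp = c(0.05, 0.10, 0.20, 0.30, 0.40),
                         duration_median_min = 40, duration_sdlog = 0.9,
                         lambda_cytokinesis = 0.1,
                         terminal_death_hazard = 0.01,
                         censor_hazard = 0.002,
                         cycle_minutes = 72, cycle_slowdown = 0.004,
                         trace_noise_cv = 0.05, bleach_per_frame = 0.001,
                         leak_range = c(0.05, 0.25),
                         multi_event_prob = 0.1) {
  new("StrainPreset", name = name,
      lifespan_modal = lifespan_modal, lifespan_shape = lifespan_shape,
      lifespan_scale = lifespan_scale,
      h_young = h_young, late_ramp = late_ramp,
      duration_median_min = duration_median_min, duration_sdlog = duration_sdlog,
      lambda_cytokinesis = lambda_cytokinesis,
      terminal_death_hazard = terminal_death_hazard,
      censor_hazard = censor_hazard,
      cycle_minutes = cycle_minutes, cycle_slowdown = cycle_slowdown,
      trace_noise_cv = trace_noise_cv, bleach_per_frame = bleach_per_frame,
      leak_range = leak_range, multi_event_prob = multi_event_prob)
}

# Genotype presets are qualitative emulations: the direction of each contrast
# follows the published genetics, the magnitudes are free parameters of this
# package. rad9d: checkpoint-compromised, flat low hazard, essentially no
# terminal events, shortened lifespan. rad52d: recombination-deficient, flat
# high hazard at all ages, longer arrests, short lifespan. tom1d/ies4d/hpc2d:
# reduced damage-induced histone loss, halved hazards, longer lifespan.
# spt21d: reduced histone transcription, raised hazards and faster
# cytokinesis. bfa1d: spindle-positioning checkpoint lost, wild-type hazards
# but arrest resolution dominated by cytokinesis (terminal-dominated).
# mad3d: spindle-assembly checkpoint dispensable, identical to wild type.
presetRegistry <- function() {
  wt <- strainPreset()
  scaleHaz <- function(p, f) {
    p@h_young <- min(1, p@h_young * f)
    p@late_ramp <- pmin(1, p@late_ramp * f)
    p
  }
  flatHaz <- function(p, h) { p@h_young <- h; p@late_ramp <- rep(h, 5); p }
  fob1 <- scaleHaz(wt, 0.7); fob1@name <- "fob1d"; fob1@lifespan_scale <- 1.3
  rad9 <- flatHaz(wt, 0.01); rad9@name <- "rad9d"
  rad9@lifespan_scale <- 0.8
  rad9@lambda_cytokinesis <- 0.001; rad9@terminal_death_hazard <- 0.0001
  rad52 <- flatHaz(wt, 0.15); rad52@name <- "rad52d"
  rad52@lifespan_scale <- 0.6; rad52@duration_median_min <- wt@duration_median_min * 1.8
  tom1 <- flatHaz(wt, 0.0075); tom1@name <- "tom1d"; tom1@lifespan_scale <- 1.2
  ies4 <- flatHaz(wt, 0.0075); ies4@name <- "ies4d"; ies4@lifespan_scale <- 1.15
  hpc2 <- flatHaz(wt, 0.0075); hpc2@name <- "hpc2d"; hpc2@lifespan_scale <- 1.2
  spt21 <- scaleHaz(wt, 1.5); spt21@name <- "spt21d"
  spt21@lambda_cytokinesis <- wt@lambda_cytokinesis * 2
  bfa1 <- wt; bfa1@name <- "bfa1d"
  bfa1@lambda_cytokinesis <- wt@lambda_cytokinesis * 10
  mad3 <- wt; mad3@name <- "mad3d"
  ps <- list(wt, fob1, rad9, rad52, tom1, ies4, hpc2, spt21, bfa1, mad3)
  names(ps) <- vapply(ps, function(p) p@name, character(1))
  ps
}

#' Named genotype presets
#'
#' @return `listPresets()` returns the preset names; `getPreset(name)` returns
#'   the corresponding [StrainPreset-class].
#' @param name preset name, one of `listPresets()`.
#' @export
listPresets <- function() names(presetRegistry())

#' @rdname listPresets
#' @export
getPreset <- function(name) {
  reg <- presetRegistry()
  if (!name %in% names(reg))
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(names(reg), collapse = ", ")), call. = FALSE)
  reg[[name]]
}

#' Analytic corrected fraction of a preset
#'
#' Probability that the retrograde-correction time beats both cytokinesis and
#' mother death during a GLM arrest, computed by numeric quadrature of
#' `E[exp(-(lambda_c + lambda_d) T_r)]` over the log-normal duration law.
#'
#' @param preset a [StrainPreset-class].
#' @return scalar probability.
#' @export
analyticCorrectedFraction <- function(preset) {
  lam <- (preset@lambda_cytokinesis + preset@terminal_death_hazard) / 60
  mu <- log(preset@duration_median_min)
  stats::integrate(function(t) exp(-lam * t) * stats::dlnorm(t, mu, preset@duration_sdlog),
                   0, Inf, rel.tol = 1e-10)$value
}

#' Construct caller parameters
#'
#' @param glm_retention_threshold maximum mother post-drop fraction of the 2N
#'   level to call a GLM; must sit below normal anaphase retention (~0.5).
#' @param min_persist_frames frames the low state must persist.
#' @param derivative_z z-score threshold on windowed slopes.
#' @param correction_window_frames window for "simultaneous" opposite slopes.
#' @param recovery_fraction fraction of 1N the mother must regain.
#' @export
callerParams <- function(glm_retention_threshold = 0.35,
                         min_persist_frames = 2L,
                         derivative_z = 3,
                         correction_window_frames = 3L,
                         recovery_fraction = 0.8) {
  new("CallerParams",
      glm_retention_threshold = glm_retention_threshold,
      min_persist_frames = as.integer(min_persist_frames),
      derivative_z = derivative_z,
      correction_window_frames = as.integer(correction_window_frames),
      recovery_fraction = recovery_fraction)
}

#' Construct quantification parameters
#' @param top_fraction fraction of brightest pixels averaged.
#' @param dilation_radius disk radius (pixels) for grayscale dilation.
#' @param min_mask_pixels minimum admissible mask size.
#' @export
quantParams <- function(top_fraction = 0.02, dilation_radius = 3L,
                        min_mask_pixels = 50L) {
  new("QuantParams", top_fraction = top_fraction,
      dilation_radius = as.integer(dilation_radius),
      min_mask_pixels = as.integer(min_mask_pixels))
}

#' Construct a bootstrap configuration
#' @param n_boot replicates (>= 100).
#' @param level_mode `"nonoverlap_p05"` (83.4% percentile interval) or
#'   `"percentile95"`.
#' @param seed integer seed.
#' @export
bootstrapConfig <- function(n_boot = 2000L, level_mode = "nonoverlap_p05",
                            seed = 1L) {
  new("BootstrapConfig", n_boot = as.integer(n_boot), level_mode = level_mode,
      seed = as.integer(seed))
}
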