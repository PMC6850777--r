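---
title: "Models and methods behind yeastGLM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind yeastGLM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yeastGLM)
```

# The phenomenon and the package's scope

During replicative aging, budding-yeast mother cells increasingly suffer
genome-level missegregations (GLMs): mitotic failures in which the majority of
the chromatin — visualized through a fluorescent histone tag — transiently
enters the daughter bud while the cell arrests before anaphase. Most events
are corrected by retrograde transport of the chromatin back to the mother;
uncorrected events are terminal, ending the replicative lifespan (RLS) either
when the daughter separates or when the mother dies. `yeastGLM` implements the
quantitative side of this biology: a calibrated synthetic cohort generator
with ground truth, microscopy calibration and per-cell fluorescence scores, an
automated event caller for mother/daughter trace pairs, and censoring-aware
cohort statistics. It does not segment or track cells in raw video, nor does
it model the underlying checkpoint biochemistry: the generator is
phenomenological by design.

# The generative model

## Lifespan and hazard

Each mother draws a baseline death age $L$ (in divisions) from a Gompertz law
— the standard parametric family for RLS data — parameterized by its modal
lifespan and shape, then multiplied by a per-genotype scale and rounded.
Division $a$ carries a GLM probability conditioned on $L$ in frailty style:

$$h(a;L) = \begin{cases} h_{\text{young}} & a \le L-5\\
\text{late\_ramp}[a-L+5] & L-4 \le a \le L\end{cases}$$

The death-conditioned ramp reproduces the sharp rise of event probability in
death-aligned coordinates without committing to a mechanism. Wild-type values
are $h_{\text{young}} = 0.015$ and ramp $(0.05, 0.10, 0.20, 0.30, 0.40)$.

## Competing resolution

A GLM arrest resolves by whichever clock fires first: a log-normal correction
time $T_r$ (median 40 min, $\sigma_{\log} = 0.9$), an exponential cytokinesis
clock at $\lambda_c = 0.1\,\mathrm{h}^{-1}$, and an exponential mother-death
clock at $\lambda_d = 0.01\,\mathrm{h}^{-1}$. The implied corrected fraction
is the quadrature integral

$$P(\text{corrected}) = E\!\left[e^{-(\lambda_c+\lambda_d) T_r}\right] =
`r round(analyticCorrectedFraction(strainPreset()), 4)`$$

computed by `analyticCorrectedFraction()` and cross-checked in the tests by
Monte Carlo. Terminal cytokinesis counts the separated daughter as the final
division and leaves the mother senescent; terminal death ends the record in
the event cycle. With probability `multi_event_prob` (default 0.1, a free
parameter — no per-cycle rate of multiple events is established) a GLM cycle
additionally contains an earlier transient event, which the scored ground
truth omits under the final-event rule but the traces render, so the caller's
final-event handling is genuinely exercised.

## Censoring and time

Cells are detected early (exponential first-detection times, mean 40 min,
capped at 5 h; the standard 3-hour inclusion filter then removes stragglers),
lost from traps with per-division probability `censor_hazard` (default 0.002),
and censored at the 72-h end of run. Cell cycles start at 72 min and lengthen
by 0.4% per division; corrected arrests extend the affected cycle by
$T_r$ plus a 10–15 min recovery ramp.

## Calibration of the wild-type preset

The hazard, duration and competing-risk constants above are fixed inputs. The
remaining free constants — the lifespan law, cycle timing and trap-loss rate —
were calibrated once, on ground truth only (before any event-caller
involvement), against three cohort-level anchors: roughly three quarters of
mothers with at least one event, roughly 90% of events corrected, and a
counterfactual lifespan gain of roughly 30%. The adopted values (modal 36,
shape 0.08, 72-min cycles, trap loss 0.002/division) give, at $n = 8000$
ground truth, penetrance 0.755–0.772, corrected fraction 0.90, and gain
26.6–28.0%. The resulting mean RLS (~29 divisions observed) is on the high
side for laboratory strains; pulling it lower costs penetrance and gain, and
the cohort-level anchors were given priority. The 72-h run cap also
truncates the longest-lived cells (about 2% of wild-type, more in long-lived
genotypes), which slightly depresses lifespan contrasts measured by
restricted means.

## Trace synthesis

The mother signal is piecewise linear per cycle on a 5-min grid: a 1N
baseline (100 AU) through G1 (25% of the cycle), a linear S-phase rise to 2N
(to 55%), a 2N plateau, and an instantaneous anaphase return to 1N. In a GLM
cycle the anaphase-time transfer instead drops the mother to
$\text{leak} \times 2N$ with $\text{leak} \sim U(0.05, 0.25)$ — strictly less
than half, since the majority of the signal enters the daughter — and the
complement appears in the daughter segment. A correction returns the mother
to 1N while the daughter falls to 1N simultaneously over the 10–15 min
recovery ramp; terminal events end the daughter segment without restoration.
Multiplicative Gaussian noise (CV 0.05) and exponential photobleaching
(0.1%/frame) are applied last; with both disabled, mother + daughter is
exactly conserved through any transfer and correction, which the tests assert
to $10^{-9}$. The defaults were chosen so that automated calling is
nontrivial but attainable.

## What the generator does and does not emulate

It emulates: 5-min sampling, S-phase doubling and anaphase halving,
age-dependent event hazards with death-aligned structure, competing
correction/cytokinesis/death resolution, superseded transients, washout and
end-of-run censoring, photobleaching, and multiplicative intensity noise. It
does not emulate: segmentation/tracking errors, focus drift, cell-shape and
crowding artifacts, correlated (non-white) noise, or mechanistic checkpoint
dynamics. Passing tests therefore demonstrate the correctness and calibration
of the pipeline on data matching these assumptions, not performance on raw
microscopy.

# The event caller

The caller automates the manual scoring rubric with explicit thresholds
(`callerParams()`):

* **Segmentation.** With division annotations, boundaries snap to the nearest
  frame. Without them, a state machine tracks the running plateau: a
  sustained drop into the 1N band (0.35–0.65 of the plateau) is an anaphase;
  a drop below 0.35 opens an arrest whose boundary is placed where the
  recovery settles near 1N, while recoveries that return to the 2N plateau
  (superseded transients) produce no boundary. Per cycle, the 2N reference is
  the median of frames within 80% of the smoothed maximum and the 1N
  reference the median of the first frames; flat arrest-tail cycles get a
  nominal 1N at half the observed level.
* **Onset calls.** A GLM is called where the mother falls below
  `glm_retention_threshold` (default 0.35) of the cycle's 2N reference for at
  least `min_persist_frames` (2), with a concurrent daughter gain of at least
  half the lost amount. 0.35 sits between normal anaphase retention (~0.5)
  and the generator's leak range (≤ 0.25), with margin for 5% CV noise.
  Multiple qualifying runs in a cycle yield only the final one. Onset times
  are reported at the midpoint of the frame interval straddling the
  threshold crossing, removing a half-frame bias.
* **Corrections.** The resolution is the first frame after onset where, over
  a 3-frame (15-min) window — the operational meaning of "simultaneous" — the
  daughter falls and the mother rises, each by more than `derivative_z` (3)
  times the trace's noise floor, with the mother subsequently regaining 80%
  of 1N. The noise floor is the pooled median absolute successive difference
  over 2N-plateau frames, normalized per cycle by its 2N reference so that
  photobleaching does not inflate it, and rescaled to the local signal level
  (noise is multiplicative). The restored-1N target uses the next cycle's G1
  level when available, again for bleaching robustness. Resolution times are
  refined to the frame where the rise begins and reported at the midpoint.
* **Outcomes and durations.** Corrected if a resolution was found; terminal
  death if the mother death flag precedes any resolution; otherwise terminal
  cytokinesis (daughter washout). Durations (resolution − onset) are defined
  for corrected events only.

Arrests shorter than `min_persist_frames` sampling intervals (about 6% of
draws from the duration law are under 10 min) are below the rubric's stated
sensitivity; event-level comparisons against ground truth are therefore made
over events at or above it. At default noise the caller reaches F1 ≥ 0.95
with outcome agreement around 97%; at zero noise, called onsets and
resolutions match ground truth within one frame.

# Statistical conventions

* **Birth vs death alignment.** Birth-aligned curves include every cell
  observed at an age, censored cells up to their last fully observed age (a
  cell lost at age 20 contributes through age 19). Death-aligned curves use
  only dead/senesced cells, indexed by divisions before death with 1 the
  final observed cycle. Both alignments are first-class outputs.
* **Cochran Q.** $Q = k(k-1)\sum_j (C_j - \bar C)^2 / (k\sum_i R_i - \sum_i
  R_i^2)$ on per-cell, per-bin any-event indicators, $\chi^2_{k-1}$ reference;
  default four bins over ages 1–20 (the choice of blocks is this package's),
  complete cases only. Type-I error is verified at 5% ± 2% on flat-hazard
  nulls.
* **Survival.** Kaplan-Meier on divisions via the `survival` package, with
  censored cells either included as right-censored or dropped
  (microdissection convention); the censor-aware mean is the restricted mean
  obtained by integrating the KM curve. Log-rank via `survival::survdiff`,
  validated against a hand-computed two-group toy ($\chi^2 = 2.88$).
* **Bootstrap.** Percentile intervals over cell-level resampling (each cell
  carries its events). Two modes are kept deliberately: plain 95% intervals,
  and 83.4% intervals calibrated so that non-overlap of two comparable bars
  corresponds to a two-group difference at about p = 0.05 — both conventions
  are in common use and they answer different questions; the package does not
  resolve them into one. The non-overlap rate is verified at 5% ± 2% under a
  two-group null.
* **Counterfactual gain.** Per uncensored cell, the counterfactual RLS is the
  observed RLS truncated at the first GLM age; the gain is
  $100(\overline{\text{rls}}/\overline{\text{rls}}_{cf} - 1)$.
* **Duration vs age.** Corrected-event durations split at the cohort's median
  event age (the grouping is this package's choice), compared by a two-tailed
  pooled-variance t-test.
* **Event-aligned averages.** Traces are normalized per cell so the 1N plateau
  is 1, shifted so the resolution is time zero, and averaged over events
  longer than 30 min.

# Numerical choices and degenerate inputs

Validity methods enforce the domain invariants (hazards in $[0,1]$, exactly
five ramp entries, leak range inside $(0, 0.5)$, strictly increasing division
times, resolution present iff corrected, at most one scored event per cycle,
flat-field mean 1 to $10^{-6}$). The flat-field correction is the inverse
dilated-median field renormalized to mean exactly 1 (the naive mean-ratio
form exceeds 1 by Jensen's inequality). Top-pixel counts round up
(`ceil(fraction * n)`, minimum one pixel); the score's median is over the
whole mask. Zero medians, empty masks, empty risk sets, zero-death log-rank
groups and degenerate variances raise explicit errors rather than returning
numbers. All generators and the bootstrap are seeded; identical seeds give
byte-identical artifacts.

# Problem sizes used in the checks

The packaged checks run the wild-type study at its native size (n = 410
cells) and use 50,000-cell cohorts for hazard-recovery asymptotics, 1000
simulations for the Cochran Q type-I calibration, 2000 two-group simulations
for the bootstrap non-overlap calibration, and 200-cell cohorts per genotype
for lifespan contrasts — sizes at which the Monte-Carlo error is comfortably
inside each check's tolerance.

# Known limitations

* The generator's genotype presets are qualitative emulations: contrast
  directions follow the published genetics, magnitudes are free parameters.
* The caller assumes traces from segmented, tracked cells at uniform cadence;
  it has no notion of tracking swaps or focus loss.
* Restricted-mean lifespans inherit a mild downward bias for long-lived
  genotypes from the 72-h end of run.
* The unannotated segmenter can misplace a boundary when a correction ramp
  and the next S-phase overlap within a frame or two; with annotations it is
  exact by construction.
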