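# yeastGLM

Single-cell analysis of **genome-level missegregation (GLM)** during budding-yeast
replicative aging.

In microfluidic lifespan devices, mother cells expressing a fluorescent histone
(e.g. Htb2:mCherry) show a stereotyped cycle: the nuclear signal doubles during
S-phase and halves at anaphase when the daughter receives its share. As mothers
age, an aberrant mode appears in which the *majority* of detectable chromatin
transiently enters the daughter bud while the cell arrests before anaphase.
Most of these GLM events are reversed by retrograde transport of the chromatin
back into the mother; the rest end the mother's replicative lifespan (RLS) when
the daughter separates (cytokinesis) or the mother dies.

`yeastGLM` packages the full quantitative workflow around this phenotype:

* **Synthetic cohorts** (`simulateCohort`, `synthesizeTraces`,
  `generateImageFixtures`): a phenomenological generator with ground-truth
  events. Per cell, a baseline lifespan `L` is drawn from a Gompertz law; each
  division carries a GLM probability `h(a; L)` (low `h_young` far from death,
  a 5-step `late_ramp` over the last five divisions); on an event, a
  log-normal correction time `T_r` competes with exponential cytokinesis and
  death clocks (rates `lambda_c`, `lambda_d`), so
  `P(corrected) = E[exp(-(lambda_c + lambda_d) T_r)]`. Mother/daughter
  fluorescence traces (5-min cadence) encode the cycle shape, the GLM
  transfer, corrections, multiplicative noise and photobleaching; image
  fixtures emulate dark frames, dye stacks and cells with known scores.
* **Image calibration and quantification** (`estimateBias`,
  `estimateFlatfield`, `correctImage`, `nucleolarAsymmetry`,
  `extractCompartmentSignal`): dark-frame bias maps, dilation/median
  flat-field correction, the top-2%/median asymmetry score, and mask-summed
  compartment traces.
* **Event calling** (`segmentCycles`, `callGlms`, `detectCorrection`,
  `classifyOutcome`, `measureDurations`, `callEvents`): an automated version
  of the manual scoring rubric — threshold-based onset calls against each
  cycle's 2N reference, simultaneous opposite mother/daughter slopes for
  corrections, washout/death for terminal classification, and a final-event
  rule when a cycle contains several drops.
* **Aging statistics** (`glmProbabilityByAge`, `cochranQTrend`, `kmSurvival`,
  `logrankTest`, `bootstrapCI`, `spearmanEventVsRemaining`,
  `historyDependence`, `counterfactualLifespanGain`, `durationVsAgeTest`,
  `alignToEvent`, `terminalFractionStats`): censoring-aware event-probability
  curves aligned from birth or death, Kaplan-Meier / log-rank lifespans,
  Cochran Q trend tests, calibrated percentile-bootstrap intervals (83.4%
  intervals whose non-overlap corresponds to p = 0.05), and the cohort-level
  summaries of penetrance, correction and counterfactual lifespan gain.
* **Orchestration** (`runConfig`, `runPipeline`, CSV/TIFF/YAML readers and
  writers, `inst/scripts/glm-pipeline.R`): deterministic, seeded end-to-end
  runs with config-hash-stamped artifacts.

## Worked example

```r
library(yeastGLM)
cfg <- runConfig(preset = "wild-type", n_cells = 100,
                 seed_cohort = 7, seed_traces = 8)
res <- runPipeline(cfg, "demo_run")
```

```
simulate: preset wild-type, n = 100, seed 7
simulate: 100 cells, 127 ground-truth events
inclusion filter (<= 180 min): 99 of 100 cells kept
traces: 99 cells at 5-min cadence
caller: 122 events called (103 corrected)
summary: penetrance 0.788, corrected 0.844, gain 26.6%
```

Reading the summary: 78.8% of the mothers experienced at least one called GLM
during their lifespan; 84.4% of called events were classified as corrected
(the preset's analytic competing-risk value is 0.90 — small cohorts scatter
around it); and the cohort's mean RLS is 26.6% higher than the counterfactual
mean obtained by truncating every cell at its first GLM, i.e. corrections buy
the average mother a quarter more lifespan. The run directory contains
`cohort.csv`, `traces.csv`, ground-truth and called events tables, and a
`summary.json` stamped with the configuration hash.

The cohort object prints as:

```
GLMCohort of 99 cells (preset 'wild-type', seed 7)
  fates: censored_end=2, censored_lost=5, died=48, senesced=44
  events: 123 scored (11 superseded transients)
  outcomes: corrected=101, terminal_cytokinesis=20, terminal_death=2
```

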