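---
title: "Quantifying CAD-prompt effects on visual search: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CAD-prompt effects on visual search: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadgaze)
```

## The problem

Concurrent-reader computer-aided detection (CAD) shows its prompts —
bounding boxes around suspected lesions — from the very start of
interpretation, and may therefore reshape how a radiologist searches a
chest radiograph, not just what they decide. Eye tracking makes that
reshaping measurable. `cadgaze` implements the full analysis pipeline for
a multi-reader crossover study of this question: every reader interprets
the same case set twice, once with boxes displayed (session 1) and once
without (session 2, after a washout), while a 60 Hz eye tracker records
gaze. Five metrics summarise each read, and a linear mixed model per
metric estimates the display effect.

## Study design and case groups

The display operating point is fixed by construction, not by an
algorithm. Lesion-positive cases are allocated to TP (box correctly on
the lesion), FN (no box), and FN+FP (box elsewhere); lesion-negative
cases to TN (no box) and FP (box present). With counts 96/12/12/48/12
the display shows a box on 96 of 120 positives (80% display sensitivity)
and no box on 48 of 60 negatives (80% display specificity).
`allocate_cases()` performs the seeded random assignment and
`display_sensitivity()` / `display_specificity()` verify the arithmetic.
Boxes use 0-based pixel coordinates with half-open extents, matching
raster indexing. The primary gaze analysis is restricted to the TP group:
only there does a correct prompt coexist with a real lesion, isolating
the prompt's effect on successful detection. The other groups exist to
keep readers from anticipating prompt correctness, and they enter the
diagnostic-performance tables only.

## The five gaze metrics

All metrics operate on raw gaze samples; no fixation-detection filter
(I-DT/I-VT) is applied, because the quantities of interest are defined
directly on the sample stream:

* **Interpretation time** — the read duration, from case onset to case
  advance. Defined by the read boundaries, so tracking dropout cannot
  shorten it.
* **Lesion dwell time** — one sampling interval (1/60 s) per valid
  sample inside the lesion area of interest (AOI): the lesion box
  expanded by a 50 px margin on every side. At the study display
  (0.233 mm pixel pitch, ~60 cm viewing distance) 50 px subtends about
  1.1 degrees — the foveal span — which is why the same constant recurs
  as AOI margin, coverage grid cell, and path buffer.
  `visual_angle(50, 0.233, 60)` reproduces the conversion.
* **Time to first fixation (TTFF)** — the timestamp of the earliest
  valid sample inside the AOI; absent if the gaze never enters it.
* **Gaze-path length** — the summed Euclidean length of the polyline
  through consecutive valid samples, in pixels. Dropout gaps are bridged
  by a straight chord with no gap cap (the longest bridged gap is logged
  per read as an audit attribute), since the metric is defined as a sum
  over the recorded trajectory and no interpolation rule is defined for
  missing samples.
* **Lung-field coverage** — the image is tiled by 50 px grid cells
  anchored at the origin; a tile belongs to the lung set when its centre
  pixel falls inside the lung mask, and a lung tile is covered when any
  of its pixels lies within 50 px of the gaze polyline. Coverage is
  covered tiles over lung tiles.

Two conventions in the coverage metric are this package's own choices,
made for determinism and cheap verification: tile membership by the
centre-pixel rule (whether boundary-straddling tiles count in the
denominator is otherwise ambiguous), and pixel-exact covered tests (a
tile is covered exactly when one of its lattice pixels is within the
buffer, so a per-pixel rasterisation oracle can confirm the efficient
geometric implementation to machine precision). AOI membership is
inclusive of the expanded boundary. All times are floating-point
seconds; frame indices are never exposed.

## Validity and pairing

A read is valid when strictly more than 50% of the expected samples
(`round(duration x 60)`) were captured — readers look at hands and UI
elements, so some loss is normal. The paired analysis set per reader is
the intersection of the two sessions' valid TP reads (listwise
deletion); diagnostic performance always uses every read. Reads whose
gaze never enters the AOI stay in the pair set and are dropped only from
the TTFF model, with the count reported in the run metadata — the
handling of never-fixated cases is a convention of this package and is
flagged in output.

## The mixed model

For each metric the model is

```
value ~ condition + (1 | case) + (1 | reader)
```

fitted by REML (`lme4`), with crossed random intercepts because every
reader reads every case. The fixed effect is the session1 − session2
contrast: positive means larger under prompt display. Inference is Wald
with a normal reference (the package reports this choice in its
metadata; likelihood-ratio or Satterthwaite conventions would differ
slightly, and with only three readers the reader variance component is
weakly identified — boundary estimates are reported as-is). Time metrics
are modelled on the natural second/pixel scale to match the additive
estimand, despite their skew; `residual_diagnostics()` surfaces the skew
(Shapiro–Wilk on conditional residuals, scale-location slope) but never
gates results.

## The synthetic study generator

The generator exists so that the entire pipeline can be exercised against
a known ground truth. It targets the metrics directly rather than
modelling oculomotor physiology — the validation surface is metric-level
recovery, not saccade realism. Per read it draws latent targets and then
constructs a sample stream that realises them:

* **Latent draws.** Each metric's target is the reader's baseline median
  plus the additive condition effect when a box is displayed, multiplied
  by a log-normal read-level factor (median 1), plus an additive
  case-level intercept shared by all six reads of a case. Baselines are
  medians because the reference summaries of such studies are reported
  as medians of skewed distributions; condition effects are additive on
  the natural scale because that is the mixed-model estimand. The case
  factor is additive on a common (across-reader median) scale rather
  than multiplicative per reader: a reader-scaled factor would be a
  reader-by-case interaction the analysis model does not contain, and
  would make the condition test conservative. Dwell and TTFF shifts
  apply only when the displayed box marks the lesion (TP); time, path
  and coverage shifts whenever any box is shown.
* **Dispersions.** The log-scale standard deviations default to 0.30
  (time), 0.35 (dwell), 0.40 (TTFF), 0.30 (path), 0.15 (coverage), with
  half of each squared dispersion assigned to the case factor
  (`rho2 = 0.5`). These are modelling choices — the reference summaries
  constrain medians and effects, not distributional form.
* **Scan-path construction.** The read lasts the drawn duration at 60 Hz.
  A lesion visit is scheduled at the drawn latency (the approach is a
  single-interval jump so first AOI entry happens at the scheduled
  sample) and dwells for the drawn time, inflated by 1/(1 − dropout) so
  the expected *measured* dwell matches the target; search fixations are
  kept off the AOI. Coverage is realised by stamping fixations over the
  lung tile grid in a per-lung serpentine order until the drawn share of
  tiles is reached, using the same geometric predicate as the metric;
  among the four scan-direction variants the generator picks the one
  whose tour passes nearest the lesion at the scheduled visit time.
  Remaining reading time lengthens fixations rather than adding travel —
  deliberately, so that interpretation time does not leak into path
  length. Within-fixation jitter amplitude is then solved from the path
  budget (expected chord length of Gaussian jitter is sigma * sqrt(pi)
  per step). Draws that cannot be realised (e.g. a long path target in a
  short read, or a coverage target whose minimum tour exceeds the path
  budget) are clamped and flagged `clamped` in the latent table.
* **Dropout and decisions.** Every emitted sample is independently
  invalid with the reader's dropout rate; invalid samples are emitted
  rather than omitted so the capture-ratio denominator is preserved.
  Session-2 decisions follow the reader's unassisted operating point;
  in session 1 the reader follows the display with probability
  `adoption`, otherwise decides unaided.

The bundled `default_generator_config()` encodes the three-reader study
conditions: baselines are the observed without-prompt session medians,
decision operating points the session-2 sensitivities/specificities,
adoption the observed total concordance rates, dropout rates 0.12, 0.08
and 0.04 (modest constant rates; see limitations), and the five
condition effects +4.9 s, +1.3 s, −1.3 s, +2076 px, +10.5 percentage
points. Images are 2560 x 1440; synthetic lung masks are two disjoint
ellipses occupying 25–29% of the frame (a portrait radiograph centred on
a widescreen display leaves the lung fields roughly a quarter of the
raster), and lesion and false-prompt boxes are 40–160 px rectangles
centred in the mask, false prompts drawn from the same size distribution
as lesions (no claim of fidelity to real CAD error geometry is made).
A false prompt must clear the lesion AOI entirely so it cannot
contaminate dwell.

## What the generator does and does not establish

Because the generator targets metrics directly, passing recovery tests
shows that the measurement and inference layers are faithful: metrics
recomputed from emitted samples match latent targets (duration exactly;
dwell and TTFF within two sampling intervals at zero dropout; path and
coverage within the stated realisation grain), and the full pipeline
recovers the configured condition effects within the study's interval
estimates. It does not show that real gaze data meet the model's
assumptions — real recordings have saccade dynamics, blinks,
calibration drift, burst-like (not independent) dropout, and per-case
validity patterns the constant dropout rate does not emulate. In
particular, the bundled configuration yields essentially complete
pairing, unlike the substantial session-2 exclusions seen with real
trackers. Geometric feasibility also binds: one bundled reader's low
path median together with a mid-range coverage median is unreachable on
this package's mask geometry (covering a tile share has a minimum tour
length), so that reader's path draws are systematically clamped and
flagged; the recovered study-level path contrast remains within its
interval estimate.

## Numerical and degenerate-input choices

Strictly-greater-than comparison at the validity threshold; capture
ratios capped at 1; a constant response short-circuits the mixed model
to the degenerate zero fit; variance components at the zero boundary are
reported unchanged; coverage of an empty recording is 0, while a mask
with no lung tiles is an error; TTFF of a never-entering read is `NA`,
never 0; box placement retries are bounded and fail loudly. Problem
sizes used in the shipped tests are chosen for fast, stable checks:
oracle equivalence on 100 random small frames, type-I error from 500
latent-level replicates at 24 cases x 3 readers (the latent fast path
exercises the inference layer; the measurement layer is validated by the
recovery tests), and a single full-scale seeded pipeline run for effect
recovery.

## A worked example

```{r example, eval = FALSE}
library(cadgaze)
res <- run_study_pipeline(default_generator_config(seed = 1))
res$analysis
tidy(res$analysis$fits$fit[[1]])
plot_condition_effects(res$analysis$fits)
```

## Known limitations

Three readers identify reader variance only weakly; adoption is a single
mixture probability, not a model of trust dynamics; no washout or order
effects are simulated (session labels map directly to conditions); the
generator's dropout is i.i.d. per sample; and the coverage/path coupling
discussed above means extreme metric combinations are realised only
approximately, with the `clamped` flag as the audit trail.
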