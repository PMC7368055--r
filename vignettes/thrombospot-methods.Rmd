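---
title: "Methods: multiparameter phenotyping of platelet–fibrin thrombus formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiparameter phenotyping of platelet–fibrin thrombus formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thrombospot)
library(dplyr)
```

## The assay and its readouts

Microspot flow assays measure thrombus formation in flowing whole blood:
recalcified blood is perfused over ~1 mm protein microspots printed on a
coverslip, and multicolour microscopy captures, every 2 minutes over an
8-minute run, a platelet membrane label, a phosphatidylserine (PS) label, a
fibrin(ogen) label, and a bright-field image. Nine kinetic readouts
summarise each run: platelet adhesion (`P1`) and PS exposure (`P2`) as
percent surface-area coverage (%SAC), thrombus coverage (`P3`), three
ordinal bright-field scores for morphology (`P4`, 0–5), aggregation (`P5`,
0–3) and contraction (`P6`, 0–3), fibrin deposition (`P7`, %SAC), a fibrin
score (`P8`, 0–3), and the shortened time to fibrin `P9 = 11 − t_fib` min,
with `t_fib = 11` (so `P9 = 0`) when no fibrin appears within the 10-minute
observation window. A complete record therefore holds 8 × 5 + 1 = 41
values. The nine microspot designs (`M1`–`M9`), the parameter definitions
and the thrombin-curve characteristics (`C1`–`C3`) are pinned in a
versioned JSON registry (`assay_registry()`), so every downstream table is
reproducible against a fixed coding. Two coding choices deserve note: score
ranges are taken as 0-based (a blank field needs a 0), and the eight
intervention classes are indexed with the fixed bit order TF = 4,
iFVIIa = 2, CTI = 1 (`condition_class()`), recorded in output metadata.

## The synthetic-data generator

No raw flow-chamber recordings ship with the package, so a generator
provides inputs with exact ground truth at two levels.

**Parameter cohorts** (`generate_parameter_cohort()`). Every coverage-type
readout follows a saturating logistic in time, anchored at zero at t = 0;
ordinal scores are tiered, rounded logistic latents; fibrin readouts are
gated by an onset time `t_fib`. The defaults encode the study conditions the
assay is known for:

* a surface reactivity ladder `M1 < M2, M3 < M4, M5 < M6 ≤ M7` in the
  platelet plateau (3–53 %SAC), with collagen-I (`M6`/`M8`/`M9`) at 50 %SAC;
* early platelet/thrombus kinetics (half-times 1.5–2.8 min) versus late,
  onset-gated fibrin: the onset floor is 4.0 min and the accumulation time
  constant 1.5 min, so fibrin accrues essentially in the second 4-minute
  interval;
* a saturating TF dose–response pulling `t_fib` from the surface baseline
  (7–10 min, or absent for weakly activating surfaces) toward the floor,
  with half-effect dose 25 pM; iFVIIa neutralises 95% of the effective TF
  dose; CTI delays the onset (1 min without TF, 2 min with TF — the
  intrinsic pathway contributes more once TF is present) and lowers the
  fibrin plateau;
* TM/APC co-coating delays the onset by 2 min and lowers the PS and fibrin
  plateaus; at low shear (150 s⁻¹) platelet deposition is reduced to 65%
  and, on weakly activating surfaces, fibrin is later and lower — the
  platelet-primed character of coagulation under flow;
* patient templates (factor XII, XI and V deficiency; factor V-Leiden with
  `tm_scale = 0`, i.e. an abolished TM response) as multiplicative/additive
  modifiers, with the control template the identity.

None of these numbers are measurements; they are plausible defaults fixed
once in `cohort_defaults()` and exposed for configuration. Between-subject
structure is a lognormal reactivity factor (SD 0.12 on the log scale)
shared across all of a subject's runs — this is what makes thrombus
signatures correlate between collagen-like surfaces for the same donor —
plus residual measurement noise (1.2 %SAC, 0.2 score units, 0.35 min on the
onset). Records represent the mean of duplicate flow runs, the standard
protocol, implemented as residual noise scaled by `1/sqrt(n_replicates)`
with a default of 2. The noiseless profile behind any run is available from
`expected_profile()` and serves as the oracle in tests (e.g. the analytic
TF dose–response is strictly decreasing).

**Image runs** (`generate_run_images()`). Platelets are rendered as discs
(radius 5–15 px) accreting toward the profile's target coverage, PS as
shrunken discs at a subset of platelet positions, fibrin as random-walk
polylines 3 px wide appearing only at/after `t_fib`, and the bright-field
proxy as an inverted composite. Noise is an illumination plane, Poisson
shot noise and Gaussian read noise on an 8-bit scale. Ground-truth masks
and exact %SAC accompany every frame; all randomness flows from one seed
and reruns are bit-identical. The default frame for tests is 256 × 256 px
(the full-sensor 1360 × 1024 geometry is supported but unnecessary for
validating the operators).

The generator emulates the kinetic and effect structure of real runs, not
their optics: no flow physics, no focal drift, no microspot boundary, no
inter-channel bleed-through. Passing tests therefore validate the analysis
operators against a controlled scene model, not segmentation performance on
real microscope data.

## Image quantification

`suppress_background()` band-passes each frame in the Fourier domain:
structures larger than `low_period_px` (default 200 px, clamped to the
frame) and noise finer than `high_period_px` (default 3 px) are removed.
Two numerical choices matter. The frame is mirror-padded before the
transform, so a non-periodic illumination gradient becomes a triangle wave
whose energy is concentrated in the removed low harmonics — without
padding, an ideal filter leaves most of a linear ramp in place. And the
pass band is an ideal 0/1 radial mask, which makes the operator exactly
idempotent; the output is mapped back to the input's gray scale by matching
mean and spread (moment matching is robust to clipped-pixel outliers, which
defeat min/max rescaling on bright-field frames).

`threshold_channel()` takes the maximum of an Otsu threshold on the
filtered frame and a floor referenced to the run's own t = 0 frame,
`mean(t0) + k·SD(t0)` with k = 3 (k = 5 for the fibrin channel, so the
threshold sits above baseline fibrinogen binding). A constant frame carries
no contrast for Otsu and falls back to the floor alone. `clean_mask()`
applies directional closing then opening with 3-px line elements, removing
speckle while preserving 3-px-wide fibres. Components are labelled with
8-connectivity; %SAC is exact (foreground ÷ total pixels). `qc_verify()`
scores the Jaccard overlap between the mask and the equally-sized
top-intensity pixel set, re-thresholds at most once with a softened floor,
and flags the run.

## Score surrogates and time to fibrin

The original ordinal scores were assigned by blinded observers against
reference images; this package substitutes automated surrogates with
explicit thresholds (`score_cutoffs()`), and marks every derived record
with `provenance = "automated_rubric"`. Area tiers (single platelet
< 80 px², small < 500, medium < 2000, large above) follow the verbal
anchors of the 0–5 morphology scale; aggregation tiers on the foreground
fraction held in aggregates; contraction on footprint shrinkage gated on
non-decreasing intensity (densification). Fibre-like objects are those with
major-axis length ≥ 20 px and elongation (major/minor axis, from image
moments) ≥ 4 — moment-based lengths stand in for skeleton lengths, which no
installed morphology stack provides. The surrogate boundaries cannot be
validated against the original visual scores without the original images;
they are calibrated only on generator scenes.

`detect_time_to_fibrin()` reports the earliest capture time at which fibrin
is present and persists at the next frame (single-frame blips are noise). A
dense fibrin mat (≥ 15 %SAC) counts as present even when merged fibres no
longer classify as elongated; an appearance at the final frame cannot be
persistence-checked and is accepted with a flag. Resolution is the 2-minute
capture grid; no sub-frame interpolation is attempted.

## Comparative analytics

Scaling is univariate: per parameter, across all surface × condition × time
cells of the comparison set supplied (subject-level rows or means — the
caller decides), values map linearly onto 0–10 with the min/max kept for
exact inversion; constant parameters map to zero and are flagged.
Subtraction heatmaps difference two scaled tables cellwise and zero every
cell inside the relevance band (centred on 0 by default, half-width one SD;
patient analyses centre the band on the control mean via
`patient_changes()`, whose retained cells satisfy |Δ| > SD exactly). The
summed scaled effect is a plain signed sum whose cell scope is an explicit
argument, because the scope defines the statistic. Interval kinetics
difference the scaled values over t = 0–4 and 4–8 min. Clustering is
Euclidean complete linkage via `stats::hclust` (lowest-index merges on
ties), cross-checked in the tests against a naive O(n³) implementation.
Group comparisons use the exact Mann–Whitney test where tie-free and small,
the tie-corrected normal approximation otherwise; all-tied data return
p = 1.

Patient integration sums (not averages) the retained deviations over all
time points and selected surfaces per parameter group — platelet (P1–P2),
thrombus (P3–P6), fibrin (P7–P9) — split by TF stratum. The TM effect pairs
runs on the TM-co-coated collagen surface (TF in the medium) with their
no-TM comparators, filters the per-cell paired differences against one SD
of the control subjects' differences, and averages over the fibrin cells;
the comparator choice is recorded in output metadata since several are
defensible. Reference ranges use the sample SD (n − 1).

## Prediction layer

Missing feature values are imputed by k-nearest neighbours (root-mean-square
distance on co-observed features, mean of the k nearest donors, lowest-index
tie-break — deterministic and idempotent). The 8-class condition prediction
replaces the original 17-program roster with eight classifier families
available in R (CART, random forest, naive Bayes, multinomial logistic,
linear and radial SVM, 1-NN, LDA); accuracies are leave-one-out, each fold
retrained from scratch with per-fold z-scoring for distance/margin-based
members and fixed per-fold seeds for stochastic ones. Published accuracies
from the original raw data are not reproducible here — the synthetic
cohorts carry their own separability — so the tests pin the calibration
points instead: chance level (≈ 1/8) at zero signal, 1.0 under clear
separation, and exact agreement with a fold-by-fold brute-force loop.
Surface comparisons are paired two-sided t-tests across the roster with
Benjamini–Hochberg adjustment. The platelet-contribution statistic for
targets P3–P9 is defined as the single-predictor R² as a percentage of the
two-predictor (P1, P2) R² — the "% of maximal prediction" — flagged
unstable when the full model explains less than 5% of variance.

## Problem sizes and limitations

The test suite and the acceptance script run on deliberately small
problems: 256 × 256 px frames, cohorts of 8–10 controls with one patient
per template, 40–50 seeded replicates for direction-recovery checks, and
24–64 runs for the LOOCV suites. These sizes give stable pass/fail
behaviour for the properties checked; they are not powered to estimate
effect sizes precisely. Known limitations: bright-field quantification on
empty fields is noise-limited (residuals up to ~2 %SAC survive cleanup at
default noise); CART and naive Bayes need several training examples per
class before leave-one-out accuracy reflects separability; and the
TM-resistance contrast for a single factor V-Leiden patient retains
subject-level noise of roughly ±0.6 scaled units, so it is assessed against
the control mean response rather than against zero.
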