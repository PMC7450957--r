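---
title: "Quantifying spider-mite feeding damage on rosette scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spider-mite feeding damage on rosette scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitedamage)
```

## The measurement problem

Spider mites empty mesophyll cells, producing diffuse chlorotic (pale
yellow to white) spots on green leaf tissue. The quantity of interest is the
total chlorotic area of a rosette in mm². Three things make this hard for
automatic methods: the damage signal is a subtle colour shift rather than a
shape; whole-rosette scans contain confounders with similar colour
(trichomes, pale young leaves, bright leaf margins, whitish petioles); and
the background, scanner brightness and contrast all shift the colour
distribution of the same tissue.

The package's pipeline measures one rosette in four stages:

1. **Rosette segmentation.** Plant pixels are those farther than a
   Euclidean RGB distance of 60 (configurable) from the background
   reference — pure white `(255,255,255)` or pure black `(0,0,0)` per the
   scan's background tag. The largest 8-connected component is kept and
   interior holes are filled, because heavily chlorotic tissue can approach
   the white reference and would otherwise punch holes in the plant mask.
   The physical calibration is taken from the scan's dpi: one pixel covers
   `(25.4 / dpi)²` mm².
2. **Damage segmentation.** The primary strategy is a probability random
   forest (default 100 trees) over a multi-scale feature stack; two simpler
   comparator strategies are provided (see below).
3. **Cluster-size filtering.** Connected components of the damage mask
   smaller than a threshold are treated as noise and removed. The
   threshold is calibrated from control rosettes: uninfested plants carry no
   real damage, so the mean size of the clusters detected on them estimates
   the scale of false detections. Removal is strict (`size < threshold`);
   a component exactly at the threshold survives.
4. **Control correction.** For each (genotype, condition, background)
   group, the mean control damage fraction `x̄_c = mean(DA_c / TA_c)` is
   fitted on the controls and each treated rosette is corrected as
   `A = DA_t − x̄_c · TA_t`. When `A ≤ 0` the rosette is recorded as
   `dropped_nonpositive` rather than deleted: attrition is itself a
   property of a method worth reporting, since a method that over-detects
   on controls loses treated samples here.

Stages 3 and 4 address different error scales: the cluster filter removes
*small, scattered* false detections (specks), the correction removes the
*systematic residual fraction* that survives filtering.

## The classifier and its features

Each pixel gets `3 + 7·S` features for `S` smoothing scales (default scales
1, 2, 4, 8 px; the bundled pipeline runs 1, 2, 4 at its working
resolution): raw R, G, B; and per scale the Gaussian-smoothed R, G, B, the
gradient magnitude, the Laplacian, and the two structure-tensor eigenvalues
of smoothed intensity. Smoothing uses separable truncated-Gaussian
convolution matrices (radius `3σ`, rows renormalised at borders), gradients
are central differences with replicated edges — every step deterministic,
so a trained classifier's predictions are reproducible bit for bit, and
serialisation via `saveRDS()` round-trips exactly.

Training labels are sparse: the rater marks a few hundred pixels per class
(`background`, `healthy`, `damaged`). Deliberately, *confounders are not a
training class* — a rater does not label trichomes — so the forest must
generalise over them, and some near-white confounders are misclassified as
damage. That is the realistic failure mode the filtering and correction
stages exist to absorb. The per-pixel uncertainty `1 − (p₁ − p₂)` (top
probability minus runner-up) ranks pixels for the active-learning loop:
labelling inside the top-uncertainty decile and retraining lowers mean
uncertainty, which the test suite asserts on synthetic scans.

Ties in the arg-max are resolved by the fixed class order background <
healthy < damaged, for determinism. Training-pixel resampling is left to
the forest's per-tree bagging rather than an explicit bootstrap stage; the
effect is equivalent and the contract simpler.

## Comparator strategies

* **Two-stage colour thresholding** (`threshold_classify()`): stage 1
  selects the rosette by a two-boundary rule on one colour plane (R, G, B,
  or H, S, I from the standard HSI decomposition with `I = mean(R,G,B)`,
  `S = 1 − min/I`); stage 2 marks damage by a second rule inside the
  selection. Simple, fast, background-invariant by construction if the
  rosette rule excludes both background colours — but it sweeps in every
  bright confounder, which the tests demonstrate.
* **Grid-average green deficiency** (`grid_classify()`): the image is tiled
  into squares of `unit_size` mm; per square overlapping the rosette the
  mean RGB over rosette pixels is taken and the square is marked when
  `g = mean(meanR, meanB) / max(meanG, 1)` exceeds a cutoff. The nine
  sensitivity levels map to a strictly decreasing cutoff ladder (0.95 down
  to 0.55), so detections are nested in sensitivity. The score and ladder
  are this package's concrete stand-in for the undocumented "lack of
  green" detectors in legacy tools; only their qualitative behaviour
  (monotone sensitivity, colour-average granularity) is claimed.
* **Manual grid emulator** (`manual_grid_emulate()`): overlays a 0.25 mm
  grid (configurable) on a damage mask and counts squares — `any-overlap`
  counts a square with ≥ 1 damaged pixel, `majority` requires > 50% damaged
  area. Overlap is computed exactly through rectangle-overlap weights, so
  fractional pixel/grid alignment needs no resampling. Any-overlap counting
  can never underestimate the pixel-exact area, and strictly overestimates
  whenever a lesion boundary crosses a grid line — the mechanism behind the
  manual standard's upward bias, asserted on random blob masks in the
  acceptance tests.

## Scanner-condition emulation

Flatbed scanner brightness/contrast units are not defined in physical
terms anywhere public; the package takes a documented stance: brightness is
an additive offset in 8-bit counts, contrast a gain
`259(C+255) / (255(259−C))` about mid-grey 128, clipped to `[0, 255]`. This
is the standard 8-bit contrast curve; it is the identity at zero and makes
"±10 brightness" mean exactly ±10 counts, which matches how stepped
lighting series are described in practice. Built-in condition tables
(`scan_condition_set()`) carry a six-condition stability set applied on
both backgrounds and a three-step brightness series per background. Both
brightness and contrast are stored explicitly per condition, as published
sources disagree on the column order of such tables.

## The synthetic generator

Because no scan corpus is distributed with the method, the generator
produces seeded scans with per-pixel ground truth (`background`, `healthy`,
`damaged`, `confounder`). What it emulates, and why:

* **Geometry**: `n_leaves` teardrop lobes with thin petiole rectangles
  radiating from a centre; overlapping leaves; scan window 2.5× the rosette
  radius. Whitish petioles reproduce the classic petiole-misclassification
  failure mode on white backgrounds.
* **Colour**: healthy green with per-leaf variation around RGB
  (75, 135, 55); chlorosis blends 75–95% toward pale yellow-white
  (245, 238, 200); trichome specks near-white; pale centres a pale green
  (170, 190, 110) distinct from chlorosis; mild Gaussian sensor noise
  (sd 2.5 counts).
* **Lesions**: elliptical blobs with perturbed boundaries, sizes log-normal
  with mean 0.25 mm² and CV 0.6, placed on healthy tissue until the target
  damage fraction of rosette pixels is reached (realised fractions land
  within ±20% of target; the tests assert this). No quantitative lesion
  morphology is claimed to match real mite feeding — the distribution is a
  documented free parameter.
* **Confounders**: specks at 3 per cm² by default, 1–9 px each; optional
  pale centre; one-pixel brightened leaf margins. Controls keep all
  confounders while carrying zero damage — this is exactly what makes the
  correction stage non-trivial and testable.

What it does **not** emulate: venation, mite bodies and webbing, specular
reflection, JPEG artefacts, colour-profile differences, multi-rosette
plates with rulers. Passing tests therefore demonstrate that the pipeline's
logic is correct and self-consistent under a controlled colour model — not
that any particular accuracy carries over to real scanner data, where
training quality and colour separation will differ.

## Numerical and design choices

* Connected components: BFS labelling in C++ with selectable 4/8
  connectivity; 8 is the default everywhere (more conservative merging of
  diagonal speck chains). The acceptance suite checks it bit-exactly
  against an independent plain-R flood fill.
* The cluster threshold is the *mean* pooled false-cluster size rounded to
  the nearest integer, pooled across genotypes by default (grouping keys
  allow per-genotype calibration if wanted).
* Percent-mode Bland–Altman differences use the pairwise mean of the two
  methods as denominator, giving values bounded in (−2, 2) for positive
  data.
* The repeatability coefficient is `1.96·sd(d)` with a chi-square interval
  on the variance — the standard definition consistent with the
  Bland–Altman framework; published tables of CRs rarely state their
  interval construction, so intervals are comparable only in method, not
  provenance.
* Lin's CCC uses population (1/n) moments (the original estimator) and a
  Fisher-z interval with Lin's large-sample standard error; the test oracle
  evaluates the moment formula independently.
* Agreement pairs lost to `dropped_nonpositive` are excluded pairwise and
  every report carries `n_pairs` and `n_excluded`.
* Child seeds for cohort replicates derive from the master seed by a fixed
  affine map modulo a prime below 2³¹, so cohorts are reproducible and
  replicates independent for practical purposes.

## Problem sizes

The bundled study cohort — also what the acceptance script runs — uses
three genotypes (damage fractions 1%, 1.5%, 5%) with eight treated and
eight control rosettes each at 150 dpi (≈ 236×236 px per scan,
~40 mm field), a six-scan training split with 300 labels per class and
scan, 100 trees, and feature scales 1, 2, 4. These sizes keep a full run
around a minute on a single core while leaving every stage's behaviour
measurable; the generator and pipeline accept larger cohorts and
resolutions (dpi ≥ 150) unchanged.

## Known limitations

* The colour model is linear RGB with additive noise; no ICC/Adobe-RGB
  profile handling. Condition emulation is per-pixel and global.
* The grid comparator's cutoff ladder is a stand-in, not a reconstruction
  of any proprietary detector.
* `split_rosettes()` orders components by bounding-box position and
  assumes non-touching rosettes; touching rosettes merge.
* Correction assumes controls and treated plants share the detection-error
  distribution (same genotype, condition, background); violating that
  assumption biases A_i in proportion to the mismatch in x̄_c.
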