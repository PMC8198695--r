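---
title: "Detecting open chromatin regions from cfDNA fragmentomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting open chromatin regions from cfDNA fragmentomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The signal model

Plasma cfDNA is released by apoptotic cells as nucleosome-protected
fragments of roughly one nucleosome (~167 bp of wrapped DNA plus
linker). Where chromatin is closed, fragments pile up on well-positioned
nucleosomes; where it is open, the DNA is degraded and few fragments
survive. Two per-base tracks capture this:

* **WPS** (window protection score): the number of fragments completely
  spanning the 120 bp window centered at a position minus the number of
  fragments with an endpoint inside that window. We take the window as
  `[x − 60, x + 60)` and count fragments, not endpoints: a fragment with
  both ends inside the window contributes −1 once. A fragment lying
  exactly on the window edge can appear in both counts and contributes
  net 0; this follows from treating the definition as two separate
  counts.
* **Coverage**: fragments overlapping each base.

Over nucleosome arrays WPS oscillates with the repeat length; in an OCR
the oscillation collapses and coverage dips. Detection is therefore
waveform pattern recognition under noise (sequencing randomness,
GC bias, mapping ambiguity), not enrichment testing.

# Processing stages and their parameters

## Tiling

The genome is processed in 20 kb tiles (`tile`), each padded by 2000 bp
(`pad`) so the WPS window, the detrend baseline and the 2000 bp feature
windows never touch a core boundary. Calls whose center falls in the pad
are discarded (the neighboring tile owns them); residual boundary
duplicates are merged when two 600 bp calls overlap by ≥ 300 bp.

## Normalization

The raw WPS baseline drifts with local coverage. We subtract a running
median (window `baseline_window` = 1001 bp, odd; several nucleosome
repeats, so it tracks drift but not the oscillation itself) and divide
by the maximum absolute deviation over the tile, mapping the waveform to
[−1, 1]. At track edges the median window is truncated rather than
extrapolated, so the baseline cannot bend toward an artificial end rule.
The downstream thresholds (0.28 peak height, 0.58 trough drop) are
defined on this unit scale. The original work does not document its
normalization; any scheme that puts the waveform on a stable unit scale
supports the same calibration procedure, which is why the thresholds are
also recoverable from data (below).

A tile whose detrended waveform is identically zero is flagged
low-signal and skipped.

## Smoothing

An order-2 Savitzky–Golay filter with a 31 bp window removes sampling
noise while preserving peak shape and width (it reproduces any locally
quadratic waveform exactly; the package tests this to 1e-9). Edges are
filled by evaluating the polynomial fitted to the first/last full
window, not by reflection, to avoid fabricating edge peaks. Windows
between 25 and 40 bp behave similarly; 31 is the published choice.

## Peak location

Local maxima are filtered in order by: height ≥ `min_height`; apex
separation ≥ `min_distance` (on conflict the higher apex survives);
width within `width_range`, measured between the interpolated crossings
of the contour at `rel_height` (default 0.5) of the peak prominence.

The published operating point (height 0.28, distance 25, width
[115, 164]) was obtained on real plasma data by sampling 2000 random
regions and taking the μ ± 3σ reliability interval of the empirical
height/width/spacing distributions. Those printed numbers are
data-derived, not universal: they encode how broad and how high
nucleosome peaks are *in that sample*, under *that* normalization. On
the package's simulated data — which has sharper fragment positioning
than real plasma — half-prominence widths are ~60 bp and the printed
band would reject every true peak. The pipeline default is therefore
`peaks = "calibrate"`: it re-runs the same μ ± 3σ procedure on the input
data (heights: μ − 3σ; widths: the central quantile band equivalent to
μ ± 3σ under normality, robust to the skew of the width distribution;
spacings: μ − 3σ for the distance floor), reporting a normality test
statistic alongside. `peak_params()` retains the published numbers for
users who want the fixed published operating point on comparable real
data.

## Troughs

A three-window scan (window `w` = 5 bp, chosen because the flat top of
most troughs spans 12–20 bp) proposes a trough wherever the middle
window's sum is strictly below both neighbors; the proposal is the
leftmost minimum of the middle window, and the scan advances by `w`.
Each proposal is then checked with the credibility rule

```
height < 0.58  AND  25 < width < 100  AND  50 < peakWidth < 220
```

with `height` the drop from the previous peak, `width` the distance from
the previous peak, and `peakWidth` the distance from the previous
trough. Three readings in this rule are ambiguous in the original
description and resolved here explicitly:

* the printed `troughWidth` line is self-referential (it would always be
  0); we read it as the distance to the *previous* trough;
* the direction of the height comparison is surprising — as printed it
  accepts *shallow* troughs. Both behaviors are available
  (`inverted = TRUE` flips it); the default follows the rule as printed,
  and the package tests assert the printed predicate verbatim;
* when no previous trough exists the `peakWidth` conjunct cannot be
  evaluated and is treated as satisfied; a proposal with no previous
  peak at all is a boundary trough and is rejected.

Because the predicate direction is unresolved, the pipeline's *feature
geometry* does not depend on it: the flanking troughs attached to each
peak are the minima of the smoothed waveform between adjacent apexes.

## Candidate calling

With a 167 bp core, a single missing nucleosome stretches the apex
spacing beyond ~200 bp; gaps > 250 bp (`min_gap`, strict) are candidate
open regions. Two weak filters follow:

* **Coverage**: the mean coverage of the central ~300 bp of the gap
  (`initial_size`; the initial OCR), normalized by the mean over the
  2000 bp neighborhood centered on the gap midpoint, must be < 0.6
  (`max_cov`). The central core is used rather than the whole
  apex-to-apex span because the span's flanks are covered by the
  fragments of the two bounding nucleosomes and would dilute the dip.
* **Flank regularity**: each side of the gap must carry ≥ 3 peaks within
  1000 bp whose consecutive spacings all lie in 120–220 bp (the band
  around the ~187 bp repeat). This rejects gaps punched into disordered
  waveform.

Calls are the gap midpoint extended to exactly 600 bp: a ~300 bp open
core plus one nucleosome (167 bp) of positional tolerance per side.
Calls overlapping annotated repeats (RepeatMasker BED) are dropped
whole — truncating them would break the fixed-size output contract.

## False-positive filtering

Each surviving candidate's 2000 bp window is summarized by 21 features:
mean and variance of peak area, apex angle, spacing, height and width
over all complete peaks in the window; mean normalized coverage of the
central 600 bp and the full window; slope and intercept of OLS coverage
trends over [0, 2000), [0, 1200) and [800, 2000) (separating the slow
symmetric OCR dip from step-like artifacts such as deletions); the unit
bisector of the central gap angle (asymmetry of the dip); and a
geometry-missingness flag. Angles require an explicit aspect ratio to be
meaningful: the x axis is scaled at 10 bp per normalized-WPS unit, fixed
in code. The enumerated feature list in the original description is
loose ("the angle bisector and vector"); the bisector encoding here
(vertex at the window center, arms to the nearest apex on each side) is
an explicit package choice, not claimed faithful.

The classifier is a 100-tree random forest (Gini splits, minimum node
size 2, `mtry = floor(sqrt(p))`, bootstrap bagging — the stock defaults
of common implementations). No random-forest package ships in the target
environment, so the forest is implemented in this package and pinned by
tests: seed-determinism, separable-case accuracy, permutation-null AUC,
and agreement of rank-statistic and trapezoid AUC to 1e-9. Training data
follow the published recipe: 800 samples split 1:1 into training and
test, 30% of training held out for validation, positives = reliably open
windows (housekeeping-gene TSS regions on real data; planted-OCR windows
in simulation), negatives = windows with abnormal waveform distortion.
Candidates with probability ≥ 0.5 (`classifier_threshold`; the original
work states no threshold) are kept.

# The simulator

`sim_config()` states a small, explicit world:

| parameter | default | rationale |
|---|---|---|
| nucleosome core | 167 bp | nucleosomal DNA length |
| linker mean / jitter | 20 / ±5 bp | ~187 bp repeat, inside the 120–220 bp regularity band |
| fragment length | N(167, 10) clipped 120–180 | mononucleosome cfDNA size selection |
| dyad jitter | sd 5 bp | well-positioned arrays |
| depth | 30× | the regime where the method is stable (≥ 20×) |
| OCR protection factor | 0.2 | strong but not total depletion |
| endpoint noise rate | 0.02 | background of uniformly placed fragments |

Planted OCRs (typically 400–600 bp, ≥ 5 kb apart) contain no dyads;
their residual fragments have uniformly random positions, so they
contribute endpoint (−1) signal without spanning protection — both
halves of the WPS signature. Per-dyad fragment counts are Poisson with
mean chosen so realized coverage matches `depth`.

Negative training windows emulate "abnormal waveform distortion":
heavily jittered positioning (dyad sd 40 bp), a shallow random central
thinning (keep 0.5–0.85), and a 5× higher noise rate. This is the
simulator's surrogate for the original work's distorted genomic regions
and is labeled as such.

**What the simulator does not emulate**: GC bias, mappability structure,
repeat-driven coverage artifacts, copy-number variation, tissue
mixtures, or sequence-level errors. A green simulation test establishes
that the pipeline recovers the stated signal model at the stated depth —
not that real-plasma headline numbers are reproduced; those require
controlled-access data.

# Numerical choices and degenerate inputs

* All coordinates are 0-based half-open (BED); BAM conversion happens at
  the import boundary; fragments = outer span of proper pairs, taken
  once from the leftmost mate, MAPQ ≥ 30 (the original work states no
  mapping filters; these are configurable conventions, not claims).
* Ties in the trough scan resolve to the leftmost minimum; plateau peaks
  take the plateau midpoint.
* Variance features use the population definition (a single peak has
  variance 0, matching the "variances are 0 iff all values equal"
  invariant).
* Constant/empty tracks: detrending returns zeros with a low-signal
  flag; a zero neighborhood mean marks a region uncallable rather than
  dividing by zero.
* Determinism: every stochastic step (simulation, calibration sampling,
  data splits, forest training) flows from an explicit seed; reruns are
  byte-identical, which the tests assert on output files.

# Known limitations

* Calibration assumes enough signal-bearing tiles to sample; sparse or
  very low-coverage inputs (< 10×) degrade peak location before
  calibration can compensate, mirroring the method's published behavior
  below 20×.
* The classifier transfers only as far as its training distribution; the
  in-package simulator regime is separable, so held-out AUC near 1 on
  synthetic labels says nothing about noisy real-world labels.
* Coverage-affecting genomic events (CNV, deletions) are only partially
  separated by the trend features; copy-number correction is out of
  scope and expected upstream.
* The Fourier-spectrum tissue-of-origin analysis associated with WPS
  signals is prior art and out of scope here.
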