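---
title: "Quantifying fluorescent protein aggregation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fluorescent protein aggregation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fociquant)
```

# Overview

`fociquant` implements the quantification layer of a live-cell protein
aggregation study: cells transfected with a fluorescently tagged,
aggregation-prone protein (here modelled on FUS-mCherry and its
ALS-causative R521C variant, co-expressed with wild-type or mistranslating
serine tRNAs) are imaged over time, and bright sub-cellular foci are
counted as aggregates. The package also covers the companion assays that
such a study uses to corroborate the imaging: dye-exclusion cytotoxicity,
SDD-AGE densitometry of aggregated protein, and tRNA-seq count analysis.

Because the measurements themselves come from live-cell experiments, the
package ships a synthetic-data generator with known ground truth for every
assay. The generator's presets encode the study's experimental conditions
and published effect sizes, so the full pipeline can be exercised — and its
parameter recovery validated — without any external data.

# The image-quantification model

## Segmentation

A frame is a single-channel intensity matrix in arbitrary units (AU). The
pipeline proceeds in three steps:

1. **Background estimation** (`estimate_background()`). Pixels at or below
   the 75th intensity percentile are taken as background; because that set
   is an upper-truncated sample, its mean and SD are corrected back to the
   untruncated values under a Gaussian background model. On an empty frame
   the estimates are unbiased; bright objects only shift the effective
   truncation point, which perturbs the estimate mildly.
2. **Cell segmentation** (`segment_cells()`). The cell mask is the set of
   8-connected components above `bg_mean + k_cell * bg_sd` (default
   `k_cell = 3`), with components below `min_cell_area_px = 20` px
   discarded. If the background is degenerate (`sd = 0`), the threshold
   falls back to `1.5 * bg_mean`.
3. **Aggregate detection** (`detect_aggregates()`). Aggregates are pixels
   within the cell mask above a stringent threshold of `k_sigma = 18`
   standard deviations above the average fluorescence per cell.

## The 18-SD threshold basis

The phrase "`k_sigma` SDs above the average fluorescence per cell" needs a
concrete statistic. We compute, for each cell component, its *diffuse*
fluorescence as the median pixel intensity of the component, and take the
mean and SD of that per-cell statistic across the cells of the frame:

> threshold = mean(per-cell medians) + k_sigma x SD(per-cell medians).

Two properties motivate this choice:

* The per-cell median is robust to the foci themselves and to the dim
  soft-edge pixels at the cell boundary, so the base statistics describe
  the diffuse fluorescence the foci must exceed.
* A naive alternative — mean and SD of all pixel intensities under the cell
  mask — is self-defeating at `k_sigma = 18`: the foci pixels inflate the
  pixel SD so strongly that `mean + 18 SD` always exceeds the foci
  intensity once foci occupy more than a fraction of a percent of the cell
  area. (Writing `f` for the foci area fraction and `m` for the
  foci-to-diffuse intensity ratio, detection requires
  `18 sqrt(f) + f + 1/m < 1`, which fails for any realistic foci load
  regardless of `m`.) That basis is still available via
  `stat_basis = "pixel"` for frames with very sparse foci.

With fewer than two cell components the cross-cell SD is undefined and the
scaled median absolute deviation of the masked pixels is used instead.
Whether the original analysis computed its statistic per frame, per
condition, or experiment-wide is not documented; per frame is the default
here (each frame's threshold is recorded in `threshold_used`).

## Median size adjustment

Thresholded areas are converted into object counts by the median size
adjustment (`calibrate_medians()`, `quantify_frame()`): cell and aggregate
component areas are pooled across *the entire experiment* — all conditions
and time points, never per condition — and their medians define the
reference object sizes. A frame's cell count is then its total cell area
divided by the median cell area, and likewise for aggregates; aggregates
per cell is the ratio of the two counts. Counts are deliberately fractional
— area-ratio counting is fractional by construction, and downstream
statistics average across replicates. This scheme is what makes the count
robust to touching cells and to merged foci: merging changes component
identity but not area.

Two further conventions: even-length area pools use the midpoint of the two
central values, and `fluorescence_per_cell` divides the
background-corrected total fluorescence over the cell mask (sum of
`pixel - bg_mean`) by the median-normalized cell count. Background
correction matters: without it the additive background biases
between-condition fluorescence ratios toward 1, and per-cell fluorescence
would not recover injected condition effects. Dividing by the
median-normalized count (rather than the raw component count) keeps the
two per-cell metrics on one consistent counting basis.

## Kinetics, fold changes and rupture events

`fold_change_at()` compares the replicate-mean metric of two conditions at
a time point, linearly interpolating between acquisitions when needed;
`plateau_level()` averages the final `window_h = 5` hours of a course
(mirroring a terminal five-hour window of the published courses);
`detect_ruptures()` calls an event wherever the metric falls by more than
`min_drop = 0.25` between consecutive frames. The drop threshold is a
design choice — saw-tooth kinetics are described qualitatively, with no
published numeric cutoff for calling a drop — and detection is ratio-based,
hence invariant under
uniform rescaling of the metric. "Start" and "end" of a course mean its
first and last acquired time points (25 h and 68.5 h post-transfection by
default).

# Companion assays

* **Cytotoxicity** (`toxicity_ratio()`, `normalize_to_control()`): the
  dye-exclusion readout is the ratio of fluorescence before detergent lysis
  (dead cells) to after lysis (all cells), in `[0, 1]` for well-formed
  wells. Condition means are normalized by the *mean* of the control
  condition (wild-type tRNA + reporter-only), not replicate-paired. Wells
  with `pre > post` are kept, with a warning, at their computed ratio —
  transparency over silent correction.
* **SDD-AGE densitometry** (`subtract_baseline()`,
  `fraction_aggregated()`): a lane profile is baseline-subtracted with a
  rolling minimum and the aggregated fraction is the trapezoidal area
  outside the monomer window divided by the total area. The monomer window
  defaults to +/- 2 estimated SDs around the tallest peak, with the SD taken
  from the half-maximum distance on the low-molecular-weight side (the side
  away from the smear). Two validity conditions matter and are why the
  preset pipeline widens both knobs: the rolling-minimum window must be
  wider than the widest true band (otherwise the baseline "eats" the broad
  smear — the preset lanes use a window of half the lane), and for a
  Gaussian monomer band a +/- 2 SD window leaks ~5% of the monomer into the
  smear, which distorts ratios of small fractions; the preset analysis uses
  +/- 3 SD since its bands are well separated. Fractions are within-lane
  quantities; no cross-lane loading normalization is applied.
* **tRNA-seq** (`pool_counts()`, `normalize_counts()`,
  `differential_abundance()`, `pool_fractions()`): transcripts produced
  from identical gene copies cannot be disambiguated by mature-tRNA
  sequencing and arrive as multi-mapped rows; these are summed into one
  pool per gene family (the default pool id strips the trailing copy
  number). Normalization divides each sample by its total and rescales by
  the mean total. Differential abundance uses a two-sided Welch t-test on
  normalized counts with fold-change flags at 1.5x and 2x; no
  multiple-testing correction is applied by default, matching the simple
  pairwise presentation the assay is reported with (a Benjamini-Hochberg
  option exists). Fold changes floor each group mean at a pseudocount of
  0.5 before the ratio: the floor handles transcripts with zero counts
  (the mutant tRNA has < 1 read on average in wild-type cells) without
  perturbing well-measured fold changes — an additive pseudocount would
  bias, e.g., 18/10 away from 1.8. Pool fractions are computed on raw mean
  counts within a condition; the mutant is itself a serine tRNA and a
  phenylalanine decoder, so those denominators include it, while the
  wild-type AGA pool excludes it. The transfection-adjusted fraction
  divides by the transfection efficiency and is flagged, not clamped, if
  it exceeds 1.

# The synthetic-data generator

`generate_frame()` renders fields of soft-edged disks (radial cosine
falloff over the outer 2 px) on Gaussian camera background. Transfected
cells carry a diffuse intensity drawn lognormally around the condition mean
(sigma_log = 0.2, multiplier mean exactly 1); untransfected cells are
invisible in the fluorescence channel and exist only in the ground-truth
sidecar. Aggregate foci are hard-edged disks of radius 1.6 px at 15x the
parent cell's diffuse intensity, placed fully inside the cell body and
non-overlapping with one another (bounded retries). `generate_timelapse()`
keeps the cell population fixed across frames, draws each frame's
per-cell foci count around a trajectory `lambda(t)`, and removes a
transfected cell (with its foci) with probability `rupture_rate` per frame
gap — rupture is modelled as disappearance, since the released
fluorescence disperses into the medium. Randomness is split into fixed
streams so the ground truth is identical whether or not pixels are
rendered, and per-frame seeds are drawn with `sample.int()` from the base
seed rather than by linear increments (linearly related seeds produced
measurably correlated frames).

What the generator does *not* emulate: realistic cell morphology, nuclei,
optics (no point-spread function), photobleaching, focus drift, shot
noise, or cell motility and division. Passing the recovery suite therefore
demonstrates that the quantification arithmetic is correct and unbiased
under the stated imaging model — not that segmentation would be robust on
real micrographs with touching, irregular cells.

## Presets and study conditions

The preset registry (`preset_names()`, `get_preset()`) encodes one
scenario per figure-level result, with the published effect sizes injected
as ground truth: reporter fluorescence per cell at 1.00 / 1.33 / 0.78 for
no-tRNA / wild-type / mutant tRNA (`fig1`); FUS production folds of 2.3
(and 2.3/2.5 for the mutant tRNA) for wild-type FUS and 2.0 (2.0/2.1) for
R521C (`fig5`); a 60% transfection efficiency (`transfection`);
aggregates-per-cell trajectories at 5x baseline declining to 4x for
wild-type tRNA and rising to 2x for the mutant (`fig6-FUS`); a 3x plateau
with rupture events for the mutant tRNA + R521C arm (`fig6-R521C`);
dye-exclusion death ratios related by the published 1.40 / 1.33 / 1.28 /
1.10 / 1.17 factors (`fig4`); aggregated fractions with a 2-fold reduction
for wild-type FUS and a 75% level for R521C (`fig7`); and count-table
means of 26 reads for the mutant tRNA, a 2000-read wild-type pool, and a
1.8-fold change in a lysine tRNA (`fig2`).

Free parameters the source does not state were fixed once, by design:

* The absolute aggregates-per-cell baseline for the no-tRNA condition is
  `lambda_0 = 0.5` foci per cell; only the fold relationships are
  published, so the presets encode those relative to this baseline.
* Absolute intensities use a bright-cell scale (diffuse intensity ~400 to
  1300 AU over background 10, noise SD 2 AU), i.e. a signal-to-noise ratio
  typical of a modern camera imaging well-expressing cells. The threshold
  crossing then falls in the flat tail of the edge profile, keeping mask
  areas — and hence per-cell quantities — effectively independent of cell
  brightness. All thresholds are computed in AU; nothing assumes integer
  quantization.
* Base death ratios in `fig4` (0.19-0.30) and aggregated fractions in
  `fig7` (0.20-0.48) are realistic assay levels chosen so the published
  ratio relations hold exactly in the injected truth.
* Field sizes and replicate counts were set by a priori power analysis
  against each recovery tolerance: 150-cell fields x 36 replicates for
  per-cell fluorescence (SE of a condition ratio ~0.5% against a 5%
  relative band); 200-cell fields x 4 replicates x 20 frames for the
  wild-type FUS course (Poisson SE of the first-time-point fold ~6%
  against a 15% band); and small 20-cell fields on a 30-minute grid (88
  frames) for the R521C course, because a single-cell rupture must be
  visible as a > 25% drop in the field's aggregates-per-cell series while
  the terminal-window plateau still averages enough counts. The rupture
  probability for the mutant-tRNA R521C arm is 0.008 per cell per frame
  (about half the population ruptures over the course), with 0.002 for the
  wild-type tRNA arm, matching the observation that ruptures occur in both
  but predominantly with the mutant.

# Numerical choices and degenerate inputs

* Connectivity is 8-connected throughout; components are labelled by
  merging diagonally touching 4-connected labels (verified exactly against
  a brute-force flood fill in the tests).
* Coordinates are row-major with R's 1-based matrix indexing; areas are
  pixel counts.
* An all-identical frame has `sd = 0` and is flagged degenerate; cell
  segmentation then uses the multiplicative fallback threshold, and
  aggregate detection with equal cell pixels finds nothing (strict
  inequality against the threshold).
* Frames with no cells report per-cell quantities as missing (`NA`), never
  zero; an experiment with no aggregate anywhere leaves the aggregate
  median undefined and all aggregate counts zero.
* Welch tests on two constant samples return p = 1 for equal means and
  p = 0 otherwise; significance stars use half-open intervals, so
  p = 0.05 is "n.s.".

# Reproducing the study-level summaries

`run_pipeline(<preset>, seed)` executes simulate → quantify → analyse for
any preset and returns recovered effect sizes next to the injected truth;
`scripts/acceptance.R` (repository root) recomputes all headline
quantities from scratch and writes them as JSON. Typical problem sizes per
run are those of the presets above; the full script completes in a few
minutes on one core.

# Known limitations

* Population-level counting only: there is no single-cell tracking, so
  per-cell aggregate trajectories and nuclear/cytoplasmic localization are
  out of scope.
* The 18-SD threshold basis is a documented interpretation of an
  under-specified rule; alternatives are exposed as configuration, and
  absolute counts (though not the fold relationships the analyses rest on)
  shift with the choice.
* The dye-exclusion and SDD-AGE stages model only the published
  arithmetic, not instrument effects (no lane warping, no saturation).
* No mechanistic aggregation model (nucleation/elongation) is fitted; the
  kinetics layer reports empirical counts only.
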