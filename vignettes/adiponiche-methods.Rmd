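---
title: "Methods: spatial niche, stress and size analysis of adipose tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial niche, stress and size analysis of adipose tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adiponiche)
```

## Scope and model

`adiponiche` implements the downstream analysis chain for imaging-based in
situ transcriptomics (Xenium-style) of human subcutaneous adipose tissue:
per-transcript quality control, three quantification geometries
(segmentation-free 50-µm bins, nucleus-proximity cells, membrane-boundary
adipocytes), control-matched gene-set stress scoring, stress zonation,
300-µm neighborhood niche detection, cell–cell colocalization, adipocyte
size–expression correlation, and the exact binomial sign test used to
summarise concordant up/down changes. Every stage is exercised on synthetic
tissue with planted ground truth, so the full chain is testable without
instrument data.

## Quantification geometries and their thresholds

All modes first discard transcripts whose decoding quality value (QV) is not
strictly greater than 35; the filter is strict because a transcript of QV
exactly 35 does not exceed the threshold.

* **Binning.** Square half-open bins of 50 µm; a bin is retained only when it
  holds strictly more than ten transcripts. The grid anchor is the minimum
  retained coordinate floored to a bin multiple, which makes the tessellation
  deterministic per sample and stable under rigid shifts of the whole field.
  Transcripts exactly on a bin's upper edge belong to the next bin.
* **Nucleus mode.** Each transcript is assigned to the single nearest nucleus
  whose geometry lies within 2 µm. "Within" is read inclusively (≤ 2.0 µm) and
  applied identically in both assignment modes; distance is zero inside a
  nucleus polygon, and ties between two equidistant nuclei break toward the
  smaller object identifier. Cells with 40 or fewer transcripts are removed.
  Counts are rescaled to 10,000 per cell and the natural-log layer is
  `log1p` of the rescaled counts.
* **Boundary mode.** Adipocytes are pixel masks from a membrane stain. Objects
  with area not strictly inside (1,000, 25,000) µm² are removed before
  assignment. A transcript inside a footprint belongs to that object; a
  transcript on a boundary is assigned to *every* object whose nearest pixel
  lies within 2 µm — multi-assignment is deliberate, because rim transcripts
  of packed adipocytes are genuinely ambiguous. Transcripts already captured
  by non-adipocyte nuclei are removed first. Expression is normalized to
  per-cell proportions, since larger objects capture more transcripts.
  The proximity search is restricted to footprint-perimeter pixels, which is
  exact for points outside the mask (an interior pixel always has a
  4-neighbor strictly closer to an outside point); the test suite verifies
  equality with an all-pixel exhaustive scan.

The original workflow's manual closing of weak membrane-stain gaps, and its
removal of contaminating fine clusters by high-resolution expression
clustering, are replaced here by (i) requiring closed masks as input and
(ii) an exclusion list of transcripts captured by non-adipocyte nuclei. This
is a simplification and is recorded in the assignment provenance.

## Gene-set stress scoring

Scores follow the control-matched scheme: genes are stratified into 25
equal-frequency bins by mean ln expression over all cells; for each target
gene, 50 control genes are drawn from its stratum (targets excluded); the
per-cell score is mean target expression minus mean pooled-control
expression. Genes with identical means share a stratum (average ranks), so a
fully degenerate matrix scores exactly zero by symmetry. When a stratum
holds fewer than 50 eligible controls — common on targeted panels with
around one hundred genes — controls are drawn with replacement and a warning
is emitted rather than silently shrinking the control set. The draw is
deterministic given a seed.

Tissue stress maps score kept 50-µm bins as pseudo-cells. The map transform
is `log1p` of the score clipped below at zero ("logged score"); the raw
(identity) transform is also available, and the choice is recorded in the
result. Clipping is a pragmatic answer to the open question of how to log a
signed score: negative control-relative scores carry little meaning on a
tissue map and are displayed as zero.

Marker positivity (e.g. p21/CDKN1A) calls a cell positive at raw count ≥ 1
by default; the threshold is exposed because "positive" is not defined
computationally in the source workflows. Per-sample fractions are compared
with two-sided Wilcoxon tests — rank-sum for independent condition pairs,
signed-rank for donor-matched pairs — under Benjamini–Hochberg adjustment.

## Zonation

Cells are binned on the 50-µm grid; each cell inherits its bin's mean score;
quartile cut points are computed over all cells pooled across conditions
(cell-level, because the reported quantity is a percentage of cells); each
state's percentage across Q1–Q4 is reported and sums to 100. Intervals are
left-closed with ties resolved downward, so an all-equal score field places
every cell in Q1 rather than scattering ties arbitrarily. Cells whose bins
fall below the resident-cell minimum are excluded and counted as an
"unzoned" remainder. Per-sample quantiles are available as an option; pooled
is the default.

## Niches

The neighborhood matrix counts, for every cell, the cells of each state
within 300 µm in the same sample (self excluded — a cell should not count
toward its own microenvironment) and converts counts to percentages. The
percentage normalization is what removes the density bias: lean fields hold
roughly twice the neighbors of obese fields because adipocytes are smaller,
and without it niche clustering would separate conditions by density rather
than composition.

Clustering builds a k-nearest-neighbor graph (k = 45) on the composition
vectors and runs Leiden community detection at resolution 0.5. The graph
degree is deliberately large relative to the local composition noise;
smaller degrees fragment smooth spatial gradients into spurious communities.
Clusters whose mean compositions lie within Jensen–Shannon distance 0.05
(base-2 logs, so the distance is bounded by 1) are merged iteratively and
each merge is logged; τ = 0 disables merging. When a batch key is given,
composition vectors are centered per sample before graph construction — a
simpler, auditable substitute for embedding-level batch correction, and a
documented divergence from the original workflow. The niche × state summary
is also reported scaled per state by its maximum across niches, which is how
composition heat maps are conventionally displayed.

Colocalization uses a 30-µm contact radius — an order below the niche
radius — and a within-sample label permutation null: z-scores and one-sided
empirical p-values per state pair. The procedure is a stated stand-in: the
source analyses report direct cell–cell colocalization without specifying
the statistic, so the permutation scheme here makes no claim of
reproduction.

## Size–expression correlation

Adipocyte area is pixel count × pixel area; centroids are pixel means.
Spearman correlations (average-rank ties; two-sided p from the
t-approximation at n ≥ 10, exact permutation below) are computed per gene
for each condition and for all conditions combined. A gene is selected when
p < 1 × 10⁻⁵ in more than one of the computed correlations, and selected
genes are ranked high-to-low by the combined-stratum correlation — the
combined column is the ranking key because it is the only stratum defined
for every gene. Constant genes are reported as undefined, never as zero, and
are never selected.

## The exact binomial sign test

The two-sided p-value follows the minimum-likelihood rule: the sum of all
outcome probabilities not exceeding the observed outcome's probability
(within a relative tie tolerance of 10⁻⁷ to stabilise floating-point
equality at the fringe). All point masses are computed as log-probabilities
and combined by log-sum-exp, so `log10_p` is exact far below the double
underflow limit (the test suite checks a case near 10⁻³⁰⁰⁰). The choice of
two-sided rule is testable: the three published sign-test anchors
(213/333, 1495/1895, 1485/1895 at p₀ = 0.5) are reproduced to two
significant figures by this rule and would not be by tail-doubling.

## The synthetic-tissue generator

The generator emulates the statistical structure of the deposited datasets
rather than their images:

* **Geometry.** Cells are discs: adipocytes with log-normal diameters
  (median 40 µm lean, 80 µm obese, 50 µm after weight loss; σ_log = 0.2,
  clamped to a plausible 15–176 µm), non-adipocytes as small discs of
  5.5 µm around a 4-µm 12-gon nucleus. Real adipocytes are irregular
  polygons; discs exercise every geometry path (containment, rim
  multi-assignment, area gating) without claiming morphological realism.
  Boundary masks are rasterized at 1 µm.
* **Density.** Total cell density scales inversely with adipocyte diameter
  (2 × 10⁻⁴ cells/µm² at 40 µm), so doubling the diameter halves the cell
  count per area. This single rule reproduces the observed roughly two-fold
  lean/obese difference in 300-µm neighbor counts.
* **Niches.** Five vertical bands (adipocyte, stem, arterial, venous,
  stress) of equal width with distinct state compositions, allocated by
  largest-remainder rounding so the planted composition is exactly the
  configured one rather than a multinomial draw — the neighborhood estimator
  is then tested against a noiseless target. Band width (1,200 µm at the
  default field) is four times the niche radius, so most cells have
  neighborhoods dominated by their own band.
* **Expression.** A 100-gene panel: five markers per state (rate 16 in the
  home state), twelve housekeeping genes, eight stress genes, and forty
  filler genes log-spaced in rate from 0.05 to 4 so that expression-matched
  control strata are populated. Counts are Poisson.
* **Stress–size coupling.** Adipocyte stress-gene rates are multiplied by a
  log-normal factor driven by a Gaussian copula on area rank with target
  Spearman ρ (default 0.5, the copula parameter r = 2 sin(πρ/6)). The
  planted coupling is recovered at ≈ 0.5 on raw stress-gene counts; after
  Poisson counting noise and per-cell proportion normalization the per-gene
  estimate attenuates to ≈ 0.40, which the recovery tests account for by
  averaging over the stress genes.
* **Noise.** Transcript positions are uniform in the cell disc (adipocytes:
  half perinuclear, half across the disc, giving the nucleus mode something
  to miss) plus Gaussian jitter of σ = 0.5 µm, so the 2-µm radius is
  meaningfully exercised. QV is a two-component mixture (high ~ N(40, 2),
  low ~ N(25, 5)) with a configurable low fraction (default 0.15), placing
  transcripts on both sides of the QV gate. Background transcripts (10⁻⁵
  per µm²) carry random genes and no source cell.

What the generator does *not* emulate: irregular cell shapes, crown-like
macrophage rings (an optional layout exists but claims no realism), segmentation
errors, spatial expression gradients within a niche, or multi-sample donor
structure. Passing the planted-recovery tests therefore demonstrates that the
machinery is correct and calibrated on data of known structure — not that
the pipeline's biological conclusions transfer to any particular real
dataset.

## Problem sizes and numerical choices

Default synthetic fields are 6,000 × 1,000 µm with ~1,200 cells (lean) and
~140,000 transcripts; planted-recovery checks use 20 seeds of this size,
and the size-correlation fixture uses 500 adipocytes of 60 µm median
diameter so the area gate does not truncate the size distribution. These
sizes were chosen so each check completes in seconds while leaving the
recovery margins well clear of their thresholds.

Numerical conventions worth knowing: assignment distances use a 10⁻¹²
absolute tolerance at radius boundaries; quantile cut points use the
standard interpolating estimator (type 7); Jensen–Shannon distances use
base-2 logs; the permutation p-value is the add-one estimator
`(1 + #{null ≥ obs}) / (1 + n_perm)`; zero-neighbor cells are flagged and
excluded from clustering rather than imputed; and an empty nucleus set
leaves all transcripts unassigned rather than erroring, while a negative
radius is always an error.

## Known limitations

* Niche detection assumes states are already assigned; no expression-space
  cell typing is bundled.
* The colocalization statistic is this package's own permutation design.
* Batch handling is per-sample centering, not embedding-level correction.
* The generator's disc geometry understates boundary ambiguity relative to
  real packed adipocytes, and its planted compositions are exact by design;
  real niche gradients are smoother.
* Wilcoxon comparisons operate on per-sample fractions and do not model
  within-sample cell-count differences.
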