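# adiponiche

Spatial niche, stress and size analysis for imaging-based in situ
transcriptomics of adipose tissue.

## The problem

Human subcutaneous adipose tissue remodels dramatically in obesity and
weight loss: adipocytes hypertrophy, macrophages infiltrate, stressed and
senescent cell states appear, and cells reorganize into recurrent
multicellular microenvironments ("niches"). Imaging-based spatial
transcriptomics (e.g. Xenium) resolves these processes at per-transcript
resolution, but the analysis chain between a raw transcript table and a
niche-level statement is long and full of geometry: quality filtering,
binning, transcript-to-cell assignment against nuclei or membrane masks,
control-matched scoring, neighborhood statistics, and exact tests on tiny
p-values. `adiponiche` packages that chain for R, for analysts who have
per-transcript coordinate tables and segmentation outputs and want audited,
reproducible implementations of each step.

## What it computes

* **Transcript QC and binning** — retain transcripts with decoding quality
  QV > 35; tessellate the field into 50-µm half-open bins, keeping bins with
  more than 10 transcripts (`load_and_filter_transcripts()`,
  `bin_transcripts()`).
* **Two assignment geometries** — nearest nucleus within 2 µm
  (single-assignment, cells kept above 40 transcripts, counts normalized to
  10,000 and `log1p`-transformed), and nearest membrane-mask pixel within
  2 µm for adipocytes gated to areas in (1,000, 25,000) µm²
  (multi-assignment on boundaries, per-cell proportion normalization)
  (`assign_to_nuclei()`, `assign_to_boundaries()`, `build_count_matrix()`).
* **Stress scores and maps** — control-matched gene-set scoring against 50
  expression-matched control genes per target on 25 expression strata
  (`score_gene_set()`), with clipped-log tissue maps over kept bins
  (`stress_map()`) and marker-positivity fractions with Wilcoxon/FDR
  comparisons (`call_positive_fraction()`).
* **Zonation** — per-bin mean stress, cell-level quartiles pooled across
  conditions, per-state composition across Q1–Q4 (`quantile_zonation()`).
* **Niches** — per-cell state composition of the 300-µm neighborhood
  (percentages, removing the lean/obese density bias), Leiden clustering on
  the composition graph with Jensen–Shannon cluster merging, and
  permutation-based cell–cell colocalization z-scores
  (`neighborhood_composition()`, `cluster_niches()`,
  `colocalization_enrichment()`).
* **Size–expression correlation** — adipocyte areas from pixel masks,
  per-gene Spearman correlation with area per condition and combined,
  selection at p < 1e-5 in more than one correlation, rank by combined
  correlation (`compute_areas()`, `gene_area_correlation()`).
* **Exact sign test** — two-sided minimum-likelihood binomial test computed
  in log space, accurate to p ~ 1e-300 and beyond in log form
  (`exact_binomial_two_sided()`), plus Benjamini–Hochberg adjustment and a
  Spearman primitive (`bh_adjust()`, `spearman_rho()`).
* **Synthetic tissue** — a generator with planted ground truth
  (condition-dependent adipocyte sizes, five spatial niches, stress–size
  coupling via a Gaussian copula, QV noise, background transcripts) so the
  whole chain is testable offline (`generate_tissue()`, `write_bundle()`).

The statistic at the core of the sign-test summaries is, for k concordant
outcomes of n with null probability p₀ = ½,

    p = Σ { P(j) : P(j) ≤ P(k) },  P(j) = C(n, j) p₀ʲ (1 − p₀)ⁿ⁻ʲ

evaluated entirely in log space with log-sum-exp.

## Worked example

```r
library(adiponiche)

# the sign test on 213 of 333 genes down-regulated after weight loss
exact_binomial_two_sided(213, 333)
#> Exact binomial test (two-sided, minlike): k = 213, n = 333, p0 = 0.5
#>   p = 3.911e-07  (log10 p = -6.4078)

# a synthetic lean tissue with five planted niches
tis <- generate_tissue(tissue_config("lean", seed = 1))
tis
#> Synthetic adipose tissue (lean): 1200 cells, 186960 transcripts (65 background)

dir <- tempfile(); write_bundle(tis, dir)
tx <- load_and_filter_transcripts(file.path(dir, "transcripts.csv"))
nrow(tx)            # 158582 of 186960 transcripts pass QV > 35
bin_transcripts(tx)
#> bin_grid: 1509 bins of 50 um (1319 kept), 100 genes

# niche detection from 300-um neighborhood compositions
cd <- data.frame(cell_id = tis$truth$cell_id, x = tis$truth$x,
                 y = tis$truth$y, state = tis$truth$state)
nm <- neighborhood_composition(cd, radius = 300)
na <- cluster_niches(nm, seed = 1)
na
#> niche_assignment: 1200 cells in 5 niches (0 merges)
round(na$summary, 1)
#>      AD  APC  ASC ECart ECven  LAM Tcell  TRM
#> N1 19.9 18.6 33.5   5.4   5.1  2.3   2.6 12.6
#> N2 14.0  5.4  5.1   7.5  34.0 11.4  14.4  8.1
#> N3 13.0 14.1  6.6  37.7   9.4  3.4   8.5  7.2
#> N4 20.5 15.6  3.0   2.3   5.7 26.2  20.5  6.2
#> N5 59.0  8.4  6.4   2.6   4.4  4.2   5.6  9.3
mclust::adjustedRandIndex(na$labels$niche, tis$truth$niche)
#> [1] 0.846
```

The five recovered communities are the planted stem (ASC-rich), venous,
arterial, stress (LAM/T-cell-rich) and adipocyte niches; the adjusted Rand
index of 0.85 against the planted labels reflects the genuine composition
gradients at band borders.

A full run of every stage (simulate → qc → assign → score → zonate →
niches → sizecorr), with per-stage manifests and resolved configuration
written next to the outputs:

```r
run_pipeline(pipeline_config(condition = "lean", seed = 1), "out_dir")
```

A thin command-line wrapper for the same entry points ships in
`inst/scripts/adiponiche.R` (subcommands `run`, `simulate`, `binom`).

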