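---
title: "Methods: building a comparable expression matrix from one-color microarray compendia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building a comparable expression matrix from one-color microarray compendia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdsnorm)
```

## The problem

Public repositories hold tens of thousands of one-color (single-channel)
microarray experiments, spread over dozens of platforms whose probe sets,
dynamic ranges and response curves all differ.  Individually the
experiments are useful; pooled into a single gene-by-experiment matrix
they support global meta-analyses such as co-expression-based prediction
of gene function.  Pooling, however, requires (i) a common gene namespace,
(ii) the removal of corrupted or pre-transformed datasets, (iii) the
taming of saturated measurements, and (iv) a normalization that makes an
intensity of, say, 500 mean the same thing in every column.  `gdsnorm`
implements that flow for GDS-formatted (SOFT) one-color datasets, together
with a statistically derived expressed/not-expressed threshold and a
neighbor-voting evaluation that quantifies what each preprocessing stage
buys.

## The intensity model

One-color intensities are approximately lognormal: unexpressed genes form
a pronounced low-intensity peak, well modeled as normal technical noise
(intensities are non-negative, so the peak is truncated at zero), while
expressed genes spread over orders of magnitude above it.  Two structural
consequences drive the pipeline:

* **Mean > median.**  A lognormal-like mixture has its mean strictly above
  its median, so the mean/median (MM) ratio of raw data must exceed 1.  A
  ratio near 1 indicates log-transformed, ratio-type or otherwise
  corrupted data.  The QC screen fails datasets with MM ratio at or below
  1.2 (the default `mm_threshold`), with zero mean, zero median, or any
  negative value.  The 1.2 cutoff rather than the theoretical 1.0 gives a
  safety margin against mixtures that are only mildly skewed; it is a
  configuration parameter.  The screen pools all values of a dataset; a
  per-sample variant is available (`per_sample = TRUE`) but off by
  default, because the dataset is the unit that is accepted or rejected.

* **A fittable noise peak.**  After normalization, the low-expression peak
  of the common reference distribution can be fitted with a normal
  distribution, and `mu + k * sigma` (default `k = 3`) gives an intensity
  above which a gene can be called expressed.

## Pipeline stages

1. **Parsing and selection** (`parse_soft()`, `select_dataset()`).  Only
   the GDS dialect of SOFT is read: one `^DATASET` block, `!dataset_*`
   attributes, one tab-delimited table with `ID_REF` and `IDENTIFIER`
   leading columns.  `^SUBSET` blocks are ignored with a warning — subset
   annotations play no role here.  Metadata matching is case-insensitive
   and whitespace-trimmed because repository capitalization varies.  A
   dataset is retained iff it is human, expression-type, single-channel
   and holds raw counts.  Negative values are *parsed*, not rejected:
   negativity is a quality problem (QC flags it), not a syntax problem.

2. **Probe mapping** (`load_gene_info()`, `map_probes()`,
   `aggregate_to_genes()`).  The `IDENTIFIER` column is resolved against
   an NCBI gene_info catalog keyed by official symbols, synonyms and
   accession-style aliases (upper-cased).  Official symbols always beat
   synonyms; residual collisions resolve to the lowest GeneID and are
   reported, so lookup is a pure function after load.  Multi-probe genes
   collapse by the **maximum** rule: probes recognising all isoforms of a
   gene hybridise at least as strongly as isoform-specific probes, so the
   per-gene maximum over non-missing probe values is the single-number
   summary; no vendor suffix parsing (`_s_at`, `I`/`A` flags) is needed.
   Unmapped probes are logged, and a platform mapping nothing at all
   raises a warning.

3. **Flooring** (`floor_outliers()`).  Scanner saturation leaves a handful
   of measurements far above the rest, which would distort both rescaling
   and the averaged reference.  Per experiment, the top
   `ceiling(0.001 * n)` non-missing values are replaced by their minimum.
   `ceiling` with a floor of one value errs toward always flooring
   something; missing values are excluded from `n`.  The operation is per
   experiment (not per dataset) because saturation is an array-level
   artifact, and because rescaling and quantile normalization are also
   columnwise.

4. **Rescaling** (`rescale()`).  Each experiment is mapped affinely onto
   0–10,000.  Rank order and ratios of differences are preserved exactly.
   A constant column is rejected (`degenerate-range`); such data cannot
   pass QC anyway.

5. **Quantile normalization** (`quantile_normalize()`).  The reference is
   the positionwise mean of the sorted columns; every value is replaced by
   the reference value at its within-column rank.  Columns with missing
   values are handled by quantile positions: a column with `n` observed
   values contributes its sorted values at positions `(i - 0.5) / n`,
   linearly interpolated onto the reference grid of `(j - 0.5) / G`
   positions (`G` genes), and maps back through the same interpolation.
   With no missing data this reduces *exactly* to the classical
   sort/average/substitute construction.  Ties receive the mean of their
   tied ranks' reference values — note that this (standard) tie rule means
   columns with many ties (e.g. a spike of zeros) match the common
   distribution exactly only away from the tied region.  One global
   reference is computed over all experiment columns jointly, and can be
   frozen to a single-column TSV so later datasets are projected onto it.

6. **Noise threshold** (`fit_noise()`, `call_expressed()`).  The model is
   fitted by default to the reference distribution when it is long enough
   to be informative (at least 1,000 values), otherwise to the pooled
   matrix values (`noise_source = "auto"`).  The algorithm:

   * Histogram the values with a Freedman–Diaconis bin width computed on
     the sub-median values (the noise-dominated half).
   * Reject (`no-noise-peak`) if the histogram is clearly dominated by a
     mode above the median — there is then no low-expression peak to
     model.  "Clearly" allows 10% sampling slack, since for pure noise the
     mode sits *at* the median.
   * Refine the peak position by fitting a quadratic to the log counts of
     the contiguous bins within half height of the peak: the log density
     of a normal peak is exactly quadratic there, so the parabola's vertex
     estimates the mode using tens of bins rather than three, which
     matters because the peak is flat and a three-point interpolation is
     noisy.  With fewer than three usable bins, the classic three-bin
     parabolic formula is used.
   * Estimate the SD from the *left* flank only, mirrored around the mode
     — the right flank is contaminated by expressed genes.  Because
     intensities cannot be negative, the left flank is itself truncated at
     zero whenever the peak sits within a few SD of zero, and the naive
     mirrored second moment is biased low (for a peak at 36 with SD 26 it
     would report roughly 18).  The estimator therefore solves the
     truncated-normal moment equation
     `m2 = sigma^2 * E[Z^2 | -mu/sigma <= Z <= 0]` for `sigma`, where `m2`
     is the observed mirrored second moment over `0 <= v <= mu`.  The
     correction factor tends to 1 as the peak moves away from zero, so the
     estimator degrades gracefully to the plain mirrored SD.
   * The threshold is `mu + k * sigma` with `k = 3` by default.  A value
     is called expressed iff it is strictly above the threshold.  The
     one-sided normal tail above 3 SD is about 0.00135, and the model
     report includes this actual tail probability alongside the
     threshold.

7. **Evaluation** (`evaluate_predictions()`).  For every annotated gene,
   its `k = 20` most Pearson-correlated genes (pairwise-complete
   experiments, minimum overlap 3; ties broken by ascending Entrez ID)
   vote on its functional categories: a category annotated to at least
   `m` neighbors (default 2) is predicted, never consulting the query's
   own annotations.  Per-gene confusion counts are pooled
   (micro-averaged), and

   * precision `P = TP / (TP + FP)`
   * recall `R = TP / (TP + FN)`
   * F-measure `F = 2PR / (P + R)`,

   with all zero-denominator cases defined as 0.  The F-measure is the
   harmonic mean; the arithmetic mean `(P + R) / 2` is also reported as
   `f_arithmetic` for reference, as the two are sometimes conflated.

## The synthetic-data generator

`sim_spec()` / `simulate_corpus()` generate SOFT corpora with the
statistical structure the pipeline assumes, so every stage is testable
offline.  Per gene and sample on an ideal (pre-platform) scale:

* unexpressed genes draw from `N(36, 26)` truncated at zero — the noise
  peak, placed at the published post-normalization parameters;
* expressed genes (default 50%) draw from a lognormal with
  `meanlog = log(500)`, `sdlog = 1`;
* module genes share a per-sample latent factor: on the log scale a
  module gene is `sqrt(rho) * L + sqrt(1 - rho) * z`, giving pairwise
  log-scale correlation `rho` (`module_cor`) — the simplest mechanism
  with a controllable correlation;
* each platform applies a response exponent (`platform_powers`, default
  drawn from [0.7, 1.3]) and a multiplicative gain
  (`platform_scale_factors`, default `10^N(0, 0.5)`).  A power warp
  multiplies both lognormal parameters, so it reproduces the observation
  that the lognormal parameters fitted to different platforms differ —
  the shape heterogeneity that rescaling cannot remove but quantile
  normalization can;
* each gene carries 1–3 probes (the extra probes attenuated, so the max
  rule recovers the full signal), plus ~2% unmappable control probes;
* per experiment, up to 0.1% of the brightest cells are multiplied by an
  outlier magnitude, emulating scanner saturation.  Saturation counts
  stay strictly below the flooring count at the same fraction, matching
  the observation that extreme measurements never exceeded the top 0.1%
  — and letting the flooring stage clip them, as it does on real arrays.

Ground-truth annotations give each module one unique category.  Non-module
genes are partitioned at random into **decoy** categories of
`decoy_category_size = 8` genes.  Decoys are statistically independent of
expression, so a perfect predictor cannot recover them; their purpose is
to make *spurious* co-expression costly, exactly as shared real GO
categories do.  With private singleton categories instead
(`decoy_category_size = 1`), the spuriously inter-correlated unexpressed
genes of unnormalized data would vote only for unpredictable singletons
and never produce a false positive, perversely rewarding the defect that
normalization removes and inverting the expected raw/scaled/normalized
ordering.

The single `seed` determines the corpus completely (the generator calls
`set.seed()` internally); identical seeds give byte-identical SOFT files.

What the generator does **not** emulate: real platform probe naming and
annotation files, GO's hierarchical structure (predictions are scored by
exact category match), array-level spatial artifacts, batch covariates
beyond per-platform gain/shape, and dataset-specific missingness patterns
(missing cells appear only where injected).  Passing tests therefore show
that the pipeline's operations have their stated statistical behavior
under a faithful caricature of one-color data — not that any particular
biological conclusion transfers to a specific real compendium.

## Validation study sizes

The test suite exercises the pipeline at deliberately desk-sized problem
scales: unit fixtures of 2–400 genes; the pre/post-normalization agreement
study on 20 datasets of 20,814 genes (the gene-space size at which the
flooring fraction corresponds to ~21 values per experiment, so the rescale
anchor is an order statistic stable enough for the R² ≥ 0.99 agreement to
be reproducible); and the stage-ordering study on 20 replicate corpora of
400 genes, 6 platforms × 12 samples with gains {1, 10, 100}, power warps
{0.5, 1.0, 1.5}, 8 planted modules of 10 genes at `module_cor = 0.45`,
scored with `k = 20, m = 3`.  The module correlation is set where recovery
is informative rather than saturated: at 0.8 every processing state
recovers every module and no ordering can show; at 0.45 the warped states
miss module pairs that normalization recovers.

## Numerical and degenerate-input decisions

* Flooring count: `max(1, ceiling(fraction * n_non_missing))`.
* Rescaling requires ≥ 2 distinct non-missing values; quantile
  normalization requires ≥ 2 non-missing values per column and accepts
  `scaled` (or, idempotently, `normalized`) input only.
* Interpolation outside the reference grid clamps to the end values
  (`rule = 2`).
* Correlation candidates need ≥ 3 pairwise-complete experiments; genes
  with fewer than `k` valid candidates are skipped and recorded.
* Neighbor ties break by ascending Entrez ID, making evaluation runs
  deterministic.
* Duplicate sample columns across datasets keep their first occurrence
  (with a message); the repository occasionally re-uses samples across
  GDS records and no principled merge exists without sample-level
  provenance.
* QC is computed on the gene-aggregated grid — the unit all downstream
  stages consume.
* The noise fit requires ≥ 1,000 values; within the pipeline a fit
  failure is a warning, not an abort, since the matrix remains useful
  without a threshold.

## Known limitations

* The maximum rule discards within-gene probe disagreement; a gene whose
  probes disagree systematically (cross-hybridisation) is summarized by
  its brightest, possibly wrong, probe.
* The global reference assumes all experiments should share one
  distribution; genuinely different designs (e.g. enriched cell
  populations) are forced onto it.
* The noise model is global.  Per-experiment thresholds (supported as a
  diagnostic by fitting per column) would track platform-specific noise
  better but lose the "one threshold for the whole matrix" property.
* Exact-match scoring understates performance relative to
  hierarchy-aware GO evaluation.
* The pipeline holds the assembled matrix in memory; corpora are
  processed dataset-by-dataset only up to assembly.
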