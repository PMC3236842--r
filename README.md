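# gdsnorm

Builds a single, directly comparable gene-by-experiment expression matrix
from heterogeneous **one-color (single-channel) microarray** datasets in
GEO's GDS SOFT format, and derives the intensity threshold above which a
gene can be called expressed.  It is written for people assembling
cross-platform expression compendia for meta-analysis — co-expression
screens, gene-function prediction, signature mining — where thousands of
experiments from dozens of platforms have to be placed on one intensity
scale.

## What it does

One-color intensities are approximately lognormal: a normal peak of
technical noise at low intensity (truncated at zero) plus expressed genes
spread over orders of magnitude.  `gdsnorm` exploits that structure in an
end-to-end pipeline:

1. **Parse & select** — read GDS SOFT files; keep human, single-channel,
   raw-count expression datasets.
2. **Map probes to Entrez Gene IDs** via an NCBI `gene_info` catalog;
   collapse multi-probe genes by the **maximum** rule (the all-isoform
   probe reports the strongest signal).
3. **Quality control** — the mean/median (MM) ratio of raw lognormal-like
   data must exceed 1; datasets with MM ratio ≤ 1.2, zero mean/median, or
   negative values are removed.
4. **Floor saturated outliers** — per experiment, the top 0.1% of values
   are replaced by their minimum.
5. **Rescale** each experiment to 0–10,000.
6. **Quantile-normalize** all experiments against one averaged reference
   distribution *D*: with *x*₍ᵢ₎ the *i*-th order statistic of a column,
   *D*ᵢ = mean over columns of *x*₍ᵢ₎, and every value is replaced by the
   reference value at its within-column rank (ties averaged; missing
   values handled by interpolating quantile positions).
7. **Fit the noise peak** — a normal *N(μ, σ²)* fitted to the
   low-expression peak of the reference; values above *μ + kσ* (default
   *k* = 3) are called **expressed**.  With the published peak parameters
   μ = 36, σ = 26 the threshold is 114.
8. **Validate by function prediction** — each gene's GO-style categories
   are predicted from its top-20 co-expressed genes by neighbor voting and
   scored by precision *P* = TP/(TP+FP), recall *R* = TP/(TP+FN) and
   F-measure *F* = 2PR/(P+R); processing stages should not decrease *F*.

A seeded simulator (`sim_spec()`, `simulate_corpus()`) generates SOFT
corpora with the assumed structure — lognormal expression, truncated
normal noise floor, per-platform gains and response-shape warps, scanner
saturation, multi-probe genes, planted co-expression modules — so the
whole pipeline is testable without downloading anything.

## Worked example

Simulate a corpus of six platforms with strongly heterogeneous gains
(1/10/100) and response shapes, then run the full pipeline and evaluate
function prediction on the raw, scaled and normalized matrices:

```r
library(gdsnorm)

spec <- sim_spec(seed = 42, module_cor = 0.45, samples_per_dataset = 12,
                 n_modules = 8, genes_per_module = 10,
                 platform_scale_factors = c(1, 10, 100),
                 platform_powers = c(0.5, 1.0, 1.5))
corpus <- simulate_corpus(spec)

cfg <- pipeline_config(datasets = corpus$datasets,
                       gene_info = corpus$gene_info,
                       annotations = corpus$annotations, eval_vote = 3)
res <- run_pipeline(cfg)
print(res)
#> <pipeline_result>
#>   funnel: files_seen=6 selected=6 qc_passed=6 experiments=72 genes=400
#>   noise: mu=6.29 sigma=3.9 threshold=18
#>   F-measure: raw=0.124 scaled=0.199 normalized=0.233
```

Reading the output: all six simulated datasets pass selection and QC
(`files_seen=6 ... qc_passed=6`), yielding a 400-gene × 72-experiment
matrix.  The noise peak of this small corpus sits at μ ≈ 6.3 with σ ≈ 3.9
on the normalized scale (the peak position is emergent — it depends on the
corpus' dynamic range), so values above 18 are called expressed here.  The
F-measure of neighbor-voting function prediction improves at each stage,
raw → scaled → normalized (0.124 → 0.199 → 0.233): rescaling removes
platform gains and quantile normalization removes the response-shape
differences that distort co-expression estimates.

Individual stages are plain functions on plain objects:

```r
print(res$qc_reports[[1]])
#> <qc_report> GDS1001: mean=15.63 median=9.162 MM=1.706 -> PASS
print(res$evaluation$normalized)
#> <eval_result> TP=80 FP=207 FN=320  P=0.279 R=0.200 F=0.233
noise_threshold(36, 26, k = 3)
#> [1] 114
```

A thin command-line front end covers the same flow
(`inst/cli/gdsnorm`, run via `Rscript`): `simulate`, `parse`, `filter`,
`qc`, and `run` subcommands with the pipeline's parameters as flags.

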