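#' Specification for a synthetic microarray corpus
#'
#' Defines every statistical property of a simulated one-color microarray
#' corpus: a normal low-intensity noise peak for unexpressed genes, a
#' lognormal expressed component, per-dataset (platform) multiplicative
#' gains and power-law response distortions, rare saturated outliers,
#' multi-probe genes, and planted co-expression modules driven by a shared
#' per-sample latent factor, each tied to a synthetic functional category.
#' One seed fully determines the corpus.
#'
#' @param n_genes Number of genes (Entrez IDs are `1001 .. 1000 + n_genes`).
#' @param probes_per_gene Integer vector of possible probe counts per gene;
#'   each gene's count is drawn uniformly from it.
#' @param n_datasets Number of datasets (platforms).
#' @param samples_per_dataset Samples (experiments) per dataset.
#' @param noise_mu,noise_sigma Normal noise-peak parameters on the ideal
#'   (pre-gain) scale; draws are truncated at 0 since intensities cannot be
#'   negative.
#' @param expressed_fraction Fraction of genes expressed above noise.
#' @param expr_meanlog,expr_sdlog Lognormal parameters of the expressed
#'   component on the ideal scale.
#' @param platform_scale_factors Per-dataset multiplicative gains
#'   (recycled); `NULL` draws `10^rnorm(n, 0, 0.5)`, platforms spanning
#'   orders of magnitude.
#' @param platform_powers Per-dataset response exponents applied as
#'   `value^power` before the gain (recycled); `NULL` draws uniformly from
#'   `[0.7, 1.3]`.  A power warp multiplies both lognormal parameters, so
#'   it models platforms whose fitted lognormal parameters differ — the
#'   distribution-shape heterogeneity that rescaling alone cannot remove
#'   but quantile normalization can.
#' @param outlier_fraction Upper bound on the fraction of each
#'   experiment's values multiplied by `outlier_magnitude`; the affected
#'   cells are the brightest of the experiment, emulating scanner
#'   saturation of high-expression measurements (which stays within the
#'   top 0.1\% on real arrays).
#' @param outlier_magnitude Multiplier for outliers.
#' @param n_modules Number of planted co-expression modules.
#' @param genes_per_module Genes per module (modules are disjoint subsets
#'   of the expressed genes).
#' @param module_cor Latent-factor loading: pairwise log-scale correlation
#'   of module genes, in \[0, 1).
#' @param decoy_category_size Non-module genes are partitioned at random
#'   into groups of this size sharing a decoy functional category that is
#'   statistically independent of expression, mimicking the many real GO
#'   categories a co-expression predictor cannot recover; `1` gives every
#'   non-module gene a private singleton category.
#' @param junk_probe_fraction Fraction of extra control-style probes with
#'   identifiers absent from the gene catalog (exercises the unmapped
#'   path).
#' @param seed Integer RNG seed; the only source of randomness.
#' @return Validated list of class `sim_spec`.
#' @export
sim_spec <- function(n_genes = 400, probes_per_gene = 1:3, n_datasets = 6,
                     samples_per_dataset = 8, noise_mu = 36,
                     noise_sigma = 26, expressed_fraction = 0.5,
                     expr_meanlog = log(500), expr_sdlog = 1,
                     platform_scale_factors = NULL, platform_powers = NULL,
                     outlier_fraction = 0.001, outlier_magnitude = 50,
                     n_modules = 3, genes_per_module = 12, module_cor = 0.8,
                     decoy_category_size = 8,
                     junk_probe_fraction = 0.02, seed = 1) {
  spec <- list(n_genes = as.integer(n_genes),
               probes_per_gene = as.integer(probes_per_gene),
               n_datasets = as.integer(n_datasets),
               samples_per_dataset = as.integer(samples_per_dataset),
               noise_mu = noise_mu, noise_sigma = noise_sigma,
               expressed_fraction = expressed_fraction,
               expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
               platform_scale_factors = platform_scale_factors,
               platform_powers = platform_powers,
               outlier_fraction = outlier_fraction,
               outlier_magnitude = outlier_magnitude,
               n_modules = as.integer(n_modules),
               genes_per_module = as.integer(genes_per_module),
               module_cor = module_cor,
               decoy_category_size = as.integer(decoy_category_size),
               junk_probe_fraction = junk_probe_fraction,
               seed = as.integer(seed))
  if (spec$n_genes < 1 || spec$n_datasets < 1 ||
      spec$samples_per_dataset < 1)
    stop("n_genes, n_datasets and samples_per_dataset must be >= 1")
  if (any(spec$probes_per_gene < 1))
    stop("probes_per_gene must be positive")
  if (spec$expressed_fraction < 0 || spec$expressed_fraction >= 1 ||
      (spec$expressed_fraction == 0 && spec$n_modules > 0))
    stop("expressed_fraction must be in [0, 1), with 0 only when no modules")
  if (spec$noise_sigma <= 0) stop("noise_sigma must be positive")
  if (spec$outlier_fraction < 0 || spec$outlier_fraction >= 1)
    stop("outlier_fraction must be in [0, 1)")
  if (spec$module_cor < 0 || spec$module_cor >= 1)
    stop("module_cor must be in [0, 1)")
  if (spec$decoy_category_size < 1)
    stop("decoy_category_size must be >= 1")
  n_expressed <- floor(spec$expressed_fraction * spec$n_genes)
  if (spec$n_modules * spec$genes_per_module > n_expressed)
    stop("modules require more expressed genes than the spec provides")
  class(spec) <- "sim_spec"
  spec
}

# Corpus-level structure derived deterministically from the spec seed:
# expressed set, disjoint modules, platform gains/powers, dataset seeds.
.sim_layout <- function(spec) {
  set.seed(spec$seed)
  gene_ids <- 1000L + seq_len(spec$n_genes)
  n_expressed <- floor(spec$expressed_fraction * spec$n_genes)
  expressed <- sort(sample(gene_ids, n_expressed))
  module_pool <- sample(expressed)
  modules <- if (spec$n_modules > 0)
    split(sort(module_pool[seq_len(spec$n_modules * spec$genes_per_module)]),
          rep(seq_len(spec$n_modules), each = spec$genes_per_module))
  else list()
  gains <- if (is.null(spec$platform_scale_factors))
    10^stats::rnorm(spec$n_datasets, 0, 0.5)
  else rep_len(spec$platform_scale_factors, spec$n_datasets)
  powers <- if (is.null(spec$platform_powers))
    stats::runif(spec$n_datasets, 0.7, 1.3)
  else rep_len(spec$platform_powers, spec$n_datasets)
  dataset_seeds <- sample.int(2147483646L, spec$n_datasets)
  module_of <- integer(0)
  for (m in seq_along(modules))
    module_of[as.character(modules[[m]])] <- m
  decoys <- setdiff(gene_ids, unlist(modules))
  decoy_group <- stats::setNames(
    (sample(length(decoys)) - 1L) %/% spec$decoy_category_size + 1L,
    decoys)
  list(gene_ids = gene_ids, expressed = expressed, modules = modules,
       module_of = module_of, gains = gains, powers = powers,
       decoy_group = decoy_group, dataset_seeds = dataset_seeds)
}

.sim_symbol <- function(gene_ids) sprintf("SGENE%d", gene_ids)

#' Simulate one GDS dataset
#'
#' Draws one platform's probe-by-sample intensity grid under `spec`:
#' unexpressed genes from the truncated normal noise peak, expressed genes
#' from the lognormal component, module genes correlated through a shared
#' per-sample latent factor; the platform's power distortion and gain are
#' applied, per-probe efficiencies and control probes added, and a random
#' `outlier_fraction` of cells multiplied by `outlier_magnitude`.  Metadata
#' fields are set so [select_dataset()] accepts the dataset.  The same
#' `(spec, dataset_index)` always produces an identical dataset.
#'
#' @param spec A [sim_spec].
#' @param dataset_index Which dataset of the corpus to generate (1-based).
#' @return A [gds_dataset].
#' @export
simulate_dataset <- function(spec, dataset_index = 1) {
  stopifnot(inherits(spec, "sim_spec"))
  if (dataset_index < 1 || dataset_index > spec$n_datasets)
    stop("dataset_index out of range")
  layout <- .sim_layout(spec)
  set.seed(layout$dataset_seeds[dataset_index])
  S <- spec$samples_per_dataset
  G <- spec$n_genes
  gene_ids <- layout$gene_ids
  is_expr <- gene_ids %in% layout$expressed
  rho <- spec$module_cor

  L <- matrix(stats::rnorm(max(1, length(layout$modules)) * S),
              ncol = S)  # latent module factors per sample
  z <- matrix(stats::rnorm(G * S), nrow = G)
  mod_idx <- layout$module_of[as.character(gene_ids)]
  e <- z
  in_mod <- !is.na(mod_idx)
  if (any(in_mod))
    e[in_mod, ] <- sqrt(rho) * L[mod_idx[in_mod], , drop = FALSE] +
      sqrt(1 - rho) * z[in_mod, , drop = FALSE]
  X <- matrix(NA_real_, nrow = G, ncol = S)
  X[is_expr, ] <- exp(spec$expr_meanlog + spec$expr_sdlog * e[is_expr, ])
  n_noise <- sum(!is_expr) * S
  if (n_noise > 0)
    X[!is_expr, ] <- pmax(stats::rnorm(n_noise, spec$noise_mu,
                                       spec$noise_sigma), 0)

  gain <- layout$gains[dataset_index]
  pw <- layout$powers[dataset_index]
  raw <- gain * X^pw

  # probe expansion: each gene gets 1..k probes; the first probe reports the
  # full signal, the rest attenuated (isoform-specific probes)
  n_probes <- sample(spec$probes_per_gene, G, replace = TRUE)
  probe_gene_row <- rep(seq_len(G), n_probes)
  probe_rank <- sequence(n_probes)
  eff <- ifelse(probe_rank == 1L, 1,
                stats::runif(length(probe_gene_row), 0.4, 0.9))
  vals <- raw[probe_gene_row, , drop = FALSE] * eff
  probe_ids <- sprintf("P%d_%d", gene_ids[probe_gene_row], probe_rank)
  labels <- .sim_symbol(gene_ids[probe_gene_row])

  n_junk <- round(spec$junk_probe_fraction * length(probe_ids))
  if (n_junk > 0) {
    junk_vals <- matrix(pmax(stats::rnorm(n_junk * S, spec$noise_mu,
                                          spec$noise_sigma), 0),
                        nrow = n_junk) * gain
    vals <- rbind(vals, junk_vals)
    probe_ids <- c(probe_ids, sprintf("AFFX-CTRL-%d_%03d", dataset_index,
                                      seq_len(n_junk)))
    labels <- c(labels, rep("--Control", n_junk))
  }

  # saturated measurements: boost each experiment's brightest cells.
  # Saturation affects at most outlier_fraction of an experiment's values
  # (strictly fewer than flooring at the same fraction will clip), so the
  # flooring step can remove them the way it does on real arrays.
  if (spec$outlier_fraction > 0) {
    n_cells <- nrow(vals)
    max_out <- max(0L, ceiling(spec$outlier_fraction * n_cells) - 1L)
    for (j in seq_len(S)) {
      n_out <- sample(0:max_out, 1)
      if (n_out == 0) next
      idx <- order(vals[, j], decreasing = TRUE)[seq_len(n_out)]
      vals[idx, j] <- vals[idx, j] * spec$outlier_magnitude
    }
  }

  dataset_id <- sprintf("GDS%04d", 1000L + dataset_index)
  samples <- sprintf("GSM%04d%02d", 1000L + dataset_index, seq_len(S))
  meta <- c(dataset_title = sprintf("synthetic one-color corpus member %d",
                                    dataset_index),
            dataset_sample_organism = "Homo sapiens",
            dataset_type = "gene expression",
            dataset_channel_count = "1",
            dataset_value_type = "count",
            dataset_platform = sprintf("GPL9%03d", dataset_index))
  gds_dataset(dataset_id, meta, probe_ids, labels, samples, vals)
}

#' Synthetic gene catalog in NCBI gene_info layout
#'
#' @param spec A [sim_spec].
#' @return A data.frame with columns `tax_id`, `GeneID`, `Symbol`,
#'   `LocusTag`, `Synonyms`, `dbXrefs` that [load_gene_info()] accepts.
#' @export
synthetic_gene_info <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  ids <- 1000L + seq_len(spec$n_genes)
  data.frame(tax_id = 9606L, GeneID = ids, Symbol = .sim_symbol(ids),
             LocusTag = "-",
             Synonyms = sprintf("ALT%d", ids),
             dbXrefs = "-", stringsAsFactors = FALSE)
}

#' Simulate a full corpus with ground-truth annotations
#'
#' Generates `spec$n_datasets` datasets sharing one gene space and one set
#' of planted modules, plus the ground-truth functional annotations: each
#' module gets a unique synthetic category shared by its genes; every other
#' gene belongs to a decoy category shared by a random group of
#' `decoy_category_size` genes with no co-expression signal (see
#' [sim_spec]).
#'
#' @param spec A [sim_spec].
#' @param out_dir Optional directory: datasets are written as SOFT files,
#'   the truth annotations as `truth_annotations.tsv`, the catalog as
#'   `gene_info.tsv`.
#' @return List with `datasets` (list of [gds_dataset]), `annotations`
#'   (a `go_annotations`), `gene_info` (data.frame), and `truth` (the
#'   derived layout: expressed set, modules, gains, powers).
#' @export
simulate_corpus <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  layout <- .sim_layout(spec)
  datasets <- lapply(seq_len(spec$n_datasets),
                     function(i) simulate_dataset(spec, i))
  ann_df <- data.frame(gene = integer(0), category = character(0))
  for (m in seq_along(layout$modules))
    ann_df <- rbind(ann_df,
                    data.frame(gene = layout$modules[[m]],
                               category = sprintf("CAT:M%04d", m)))
  decoys <- as.integer(names(layout$decoy_group))
  ann_df <- rbind(ann_df,
                  data.frame(gene = decoys,
                             category = sprintf("CAT:D%04d",
                                                layout$decoy_group)))
  annotations <- load_annotations(ann_df)
  gi <- synthetic_gene_info(spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (d in datasets)
      write_soft(d, file.path(out_dir, paste0(d$dataset_id, ".soft")))
    utils::write.table(ann_df, file.path(out_dir, "truth_annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(gi, file.path(out_dir, "gene_info.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(datasets = datasets, annotations = annotations, gene_info = gi,
       truth = layout)
}
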