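#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end flow with its default: the
#' MM-ratio QC threshold (1.2), the flooring fraction (0.1\%), the common
#' intensity range (0-10,000), the noise-threshold SD multiplier (3) and
#' the evaluation settings (20 neighbors, 2 votes).
#'
#' @param input_dir Directory of `.soft` files (used when `datasets` is
#'   `NULL`).
#' @param datasets Optional list of [gds_dataset] objects, bypassing file
#'   input.
#' @param gene_info Path to an NCBI gene_info table, a data.frame in that
#'   layout, or a ready `gene_catalog`.
#' @param annotations Optional annotation TSV path, data.frame, or
#'   `go_annotations` object; when present the co-expression evaluation is
#'   run on the raw, scaled and normalized matrices.
#' @param mm_threshold MM-ratio QC cutoff.
#' @param floor_fraction Flooring fraction.
#' @param scale_lo,scale_hi Rescaling range.
#' @param noise_k SD multiplier for the noise threshold.
#' @param noise_source `"reference"` fits the noise model to the averaged
#'   reference distribution, `"pooled"` to all matrix values, `"auto"`
#'   (default) uses the reference when it has enough values and pools
#'   otherwise.
#' @param eval_k,eval_vote Neighbor count and vote threshold for the
#'   evaluation.
#' @param strict Stop on SOFT parse errors (`TRUE`) or skip the file with a
#'   warning (`FALSE`, default).
#' @param output_dir Optional directory for all report artifacts.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, datasets = NULL,
                            gene_info = NULL, annotations = NULL,
                            mm_threshold = 1.2, floor_fraction = 0.001,
                            scale_lo = 0, scale_hi = 10000, noise_k = 3,
                            noise_source = c("auto", "reference", "pooled"),
                            eval_k = 20, eval_vote = 2, strict = FALSE,
                            output_dir = NULL) {
  stopifnot(mm_threshold > 0, floor_fraction > 0, floor_fraction < 1,
            scale_hi > scale_lo, noise_k > 0, eval_k >= 1, eval_vote >= 1)
  structure(list(input_dir = input_dir, datasets = datasets,
                 gene_info = gene_info, annotations = annotations,
                 mm_threshold = mm_threshold,
                 floor_fraction = floor_fraction, scale_lo = scale_lo,
                 scale_hi = scale_hi, noise_k = noise_k,
                 noise_source = match.arg(noise_source), eval_k = eval_k,
                 eval_vote = eval_vote, strict = strict,
                 output_dir = output_dir),
            class = "pipeline_config")
}

.as_catalog <- function(x) {
  if (inherits(x, "gene_catalog")) x else load_gene_info(x)
}

.as_annotations <- function(x) {
  if (is.null(x) || inherits(x, "go_annotations")) x else load_annotations(x)
}

#' Assemble per-dataset gene grids into one raw expression matrix
#'
#' Takes the union of gene IDs across datasets (rows sorted ascending) and
#' concatenates experiment columns.  A sample identifier appearing in more
#' than one dataset is kept at its first occurrence and later copies are
#' dropped with a message.
#'
#' @param grids Named list (by dataset ID) of gene-by-sample matrices from
#'   [aggregate_to_genes()].
#' @return An [expression_matrix] with `state = "raw"`; experiment columns
#'   carry their source dataset in the name as `<dataset>:<sample>`.
#' @export
assemble_matrix <- function(grids) {
  stopifnot(length(grids) >= 1L)
  genes <- sort(unique(unlist(lapply(grids, function(g)
    as.integer(rownames(g))))))
  seen <- character(0)
  cols <- list()
  col_ids <- character(0)
  for (ds in names(grids)) {
    g <- grids[[ds]]
    dup <- colnames(g) %in% seen
    if (any(dup))
      message(sprintf("dropping %d duplicate sample column(s) of %s (kept first occurrence)",
                      sum(dup), ds))
    g <- g[, !dup, drop = FALSE]
    if (ncol(g) == 0L) next
    seen <- c(seen, colnames(g))
    block <- matrix(NA_real_, nrow = length(genes), ncol = ncol(g),
                    dimnames = list(genes, colnames(g)))
    block[rownames(g), ] <- g
    cols[[length(cols) + 1L]] <- block
    col_ids <- c(col_ids, paste0(ds, ":", colnames(g)))
  }
  values <- do.call(cbind, cols)
  expression_matrix(values, gene_ids = genes, experiment_ids = col_ids,
                    state = "raw")
}

#' Run the full preprocessing pipeline
#'
#' Executes, in order: SOFT parsing, dataset selection, probe mapping and
#' max-aggregation to genes, MM-ratio quality control, outlier flooring,
#' rescaling to the common range, matrix assembly, quantile normalization,
#' noise-model fitting, and (when annotations are configured) the
#' co-expression prediction evaluation on the raw, scaled and normalized
#' matrices.  A run summary records the dataset funnel (files seen,
#' selected, QC-passed) and final matrix size; all report artifacts are
#' written when `output_dir` is set.
#'
#' @param config A [pipeline_config].
#' @return List of class `pipeline_result`: `matrices` (`$raw`, `$scaled`,
#'   `$normalized` [expression_matrix] objects), `reference`, `qc_reports`,
#'   `flooring`, `noise` (a [noise_model], or `NULL` when no noise peak was
#'   detectable), `evaluation` (per-state `eval_result`s or `NULL`), and
#'   `summary` (named counts).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  datasets <- config$datasets
  if (is.null(datasets)) {
    if (is.null(config$input_dir)) stop("no datasets and no input_dir")
    files <- list.files(config$input_dir, pattern = "\\.soft$",
                        full.names = TRUE)
    if (length(files) == 0L) stop("input_dir contains no .soft files")
    datasets <- list()
    for (f in files) {
      d <- tryCatch(parse_soft(f), error = function(e) {
        if (config$strict) stop(e)
        warning(sprintf("skipping %s: %s", basename(f), conditionMessage(e)))
        NULL
      })
      if (!is.null(d)) datasets[[length(datasets) + 1L]] <- d
    }
  }
  n_seen <- length(datasets)
  keep <- vapply(datasets, function(d) select_dataset(d)$accepted, logical(1))
  datasets <- datasets[keep]
  n_selected <- length(datasets)
  if (n_selected == 0L) stop("no dataset passed the selection filters")

  catalog <- .as_catalog(config$gene_info)
  unmapped_log <- if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    file.path(config$output_dir, "unmapped_probes.txt")
  } else NULL

  grids <- list()
  qc_reports <- list()
  for (d in datasets) {
    pmap <- suppressWarnings(
      map_probes(d, catalog, unmapped_log = unmapped_log))
    grid <- aggregate_to_genes(d, pmap)
    rep <- qc_dataset(grid, threshold = config$mm_threshold,
                      dataset_id = d$dataset_id)
    qc_reports[[d$dataset_id]] <- rep
    if (rep$passed) grids[[d$dataset_id]] <- grid
  }
  n_passed <- length(grids)
  if (n_passed == 0L) {
    stop(sprintf(
      "no dataset survived QC (seen %d, selected %d, passed 0)",
      n_seen, n_selected))
  }

  raw <- assemble_matrix(grids)
  pp <- preprocess_matrix(raw, fraction = config$floor_fraction,
                          lo = config$scale_lo, hi = config$scale_hi)
  normalized <- quantile_normalize(pp$matrix)

  noise_values <- switch(config$noise_source,
    reference = normalized$reference,
    pooled = as.numeric(normalized$values),
    auto = if (length(normalized$reference) >= 1000) normalized$reference
           else as.numeric(normalized$values))
  noise <- tryCatch(fit_noise(noise_values, k = config$noise_k),
                    error = function(e) {
                      warning("noise fit failed: ", conditionMessage(e))
                      NULL
                    })

  annotations <- .as_annotations(config$annotations)
  evaluation <- NULL
  if (!is.null(annotations)) {
    evaluation <- lapply(
      list(raw = raw, scaled = pp$matrix, normalized = normalized),
      evaluate_predictions, annotations = annotations, k = config$eval_k,
      m = config$eval_vote)
  }

  summary <- c(files_seen = n_seen, selected = n_selected,
               qc_passed = n_passed,
               experiments = ncol(normalized$values),
               genes = nrow(normalized$values))
  res <- structure(
    list(matrices = list(raw = raw, scaled = pp$matrix,
                         normalized = normalized),
         reference = normalized$reference, qc_reports = qc_reports,
         flooring = pp$flooring, noise = noise, evaluation = evaluation,
         summary = summary, config = config),
    class = "pipeline_result")

  if (!is.null(config$output_dir)) {
    out <- config$output_dir
    write_matrix(normalized, file.path(out, "expression_matrix.tsv"))
    write_qc_report(qc_reports, file.path(out, "qc_report.tsv"))
    write_flooring_log(pp$flooring, file.path(out, "flooring_log.tsv"))
    write_reference(normalized$reference, file.path(out, "reference.tsv"))
    if (!is.null(noise))
      write_noise_report(noise, file.path(out, "noise_model.json"))
    utils::write.table(
      data.frame(stage = names(summary), count = as.integer(summary)),
      file.path(out, "run_summary.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  funnel: %s\n",
              paste(sprintf("%s=%d", names(x$summary), x$summary),
                    collapse = " ")))
  if (!is.null(x$noise))
    cat(sprintf("  noise: mu=%.3g sigma=%.3g threshold=%.3g\n",
                x$noise$mu, x$noise$sigma, x$noise$threshold))
  if (!is.null(x$evaluation))
    cat(sprintf("  F-measure: raw=%.3f scaled=%.3f normalized=%.3f\n",
                x$evaluation$raw$f_measure, x$evaluation$scaled$f_measure,
                x$evaluation$normalized$f_measure))
  invisible(x)
}
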