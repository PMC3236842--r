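#' Construct a gene-by-experiment expression matrix
#'
#' The central container of the pipeline: a numeric grid with genes
#' (Entrez IDs) as rows and experiments (samples, possibly pooled from many
#' datasets) as columns, `NA` marking missing cells, and a processing-state
#' tag recording how far along the pipeline the values are.
#'
#' @param values Numeric matrix (genes x experiments).
#' @param gene_ids Integer Entrez IDs, one per row.  Defaults to
#'   `rownames(values)` coerced to integer.
#' @param experiment_ids Character experiment identifiers, one per column.
#'   Defaults to `colnames(values)`.
#' @param state One of `"raw"`, `"scaled"`, `"normalized"`.
#' @param reference Optional numeric vector: the common reference
#'   distribution attached after quantile normalization (non-decreasing,
#'   one value per gene row).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids = NULL, experiment_ids = NULL,
                              state = c("raw", "scaled", "normalized"),
                              reference = NULL) {
  state <- match.arg(state)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- as.integer(rownames(values))
  if (is.null(experiment_ids)) experiment_ids <- colnames(values)
  gene_ids <- as.integer(gene_ids)
  if (anyNA(gene_ids)) stop("gene_ids must be integer Entrez IDs")
  if (length(gene_ids) != nrow(values))
    stop("gene_ids must have one entry per row")
  if (length(experiment_ids) != ncol(values))
    stop("experiment_ids must have one entry per column")
  dimnames(values) <- list(gene_ids, experiment_ids)
  if (!is.null(reference)) {
    reference <- as.numeric(reference)
    if (is.unsorted(reference))
      stop("reference distribution must be non-decreasing")
  }
  structure(list(gene_ids = gene_ids,
                 experiment_ids = as.character(experiment_ids),
                 values = values, state = state, reference = reference),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<expression_matrix> %d genes x %d experiments [state: %s, %.1f%% missing]\n",
    nrow(x$values), ncol(x$values), x$state,
    100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)
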