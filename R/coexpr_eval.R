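#' Gene-gene Pearson correlation over pairwise-complete experiments
#'
#' @param em An [expression_matrix].
#' @param min_overlap Minimum number of pairwise-complete experiments for a
#'   correlation to count; pairs below it are `NA`.
#' @return Gene-by-gene correlation matrix with `NA` diagonal.
#' @export
gene_correlations <- function(em, min_overlap = 3) {
  stopifnot(inherits(em, "expression_matrix"))
  v <- t(em$values)  # experiments x genes
  cc <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs"))
  obs <- !is.na(em$values)
  overlap <- tcrossprod(obs * 1L)
  cc[overlap < min_overlap] <- NA
  diag(cc) <- NA
  dimnames(cc) <- list(em$gene_ids, em$gene_ids)
  cc
}

#' Top co-expressed genes of a query gene
#'
#' Ranks all other genes by Pearson correlation with the query's expression
#' profile over pairwise-complete experiments and returns the `k` most
#' correlated (ties broken by ascending Entrez ID).  Genes with fewer than
#' `min_overlap` complete pairs against the query are not candidates.
#'
#' @param em An [expression_matrix].
#' @param gene Query Entrez ID.
#' @param k Number of neighbors (default 20).
#' @param min_overlap Minimum pairwise-complete experiments (default 3).
#' @param correlations Optional precomputed matrix from
#'   [gene_correlations()] to avoid recomputation across many queries.
#' @return Integer vector of up to `k` Entrez IDs, most correlated first;
#'   shorter than `k` (with a warning) when too few candidates have valid
#'   correlations.
#' @export
top_correlated <- function(em, gene, k = 20, min_overlap = 3,
                           correlations = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  gene <- as.integer(gene)
  if (!gene %in% em$gene_ids) stop("query gene not in matrix: ", gene)
  if (is.null(correlations)) correlations <- gene_correlations(em, min_overlap)
  r <- correlations[as.character(gene), ]
  cand <- which(!is.na(r))
  ids <- em$gene_ids[cand]
  rs <- r[cand]
  if (length(cand) < k)
    warning(sprintf("gene %d: only %d candidates with valid correlations",
                    gene, length(cand)))
  ord <- order(-rs, ids)
  ids[ord][seq_len(min(k, length(cand)))]
}

#' Load a gene-to-category annotation table
#'
#' Two-column TSV (Entrez ID, category ID), one pair per line, no header.
#'
#' @param path TSV path, or a data.frame with columns gene / category.
#' @return Object of class `go_annotations`: a named list mapping Entrez ID
#'   (as character) to a character vector of category IDs.
#' @export
load_annotations <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.delim(path, header = FALSE, colClasses = "character")
  genes <- as.character(as.integer(df[[1]]))
  cats <- as.character(df[[2]])
  structure(split(cats, genes), class = "go_annotations")
}

#' Predict a gene's categories from its co-expressed neighbors
#'
#' Neighbor voting: a category is predicted when at least `m` of the
#' neighbors are annotated with it (`m = 1` gives the plain union of
#' neighbor annotations).  The query gene's own annotations are never
#' consulted.
#'
#' @param gene Query Entrez ID (excluded from voting if present among
#'   `neighbors`).
#' @param neighbors Integer vector of neighbor Entrez IDs.
#' @param annotations A `go_annotations` object.
#' @param m Minimum number of neighbor votes (default 2).
#' @return Character vector of predicted category IDs (possibly empty).
#' @export
predict_categories <- function(gene, neighbors, annotations, m = 2) {
  stopifnot(length(neighbors) >= 1L)
  neighbors <- setdiff(as.integer(neighbors), as.integer(gene))
  votes <- table(unlist(annotations[as.character(neighbors)],
                        use.names = FALSE))
  names(votes)[votes >= m]
}

#' Construct an evaluation result
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and F-measure
#' `2PR/(P+R)` from pooled confusion counts; any zero-denominator case is
#' defined as 0.  `f_arithmetic`, the simple average `(P+R)/2`, is reported
#' alongside for reference but the F-measure is the harmonic mean.
#'
#' @param tp,fp,fn Pooled confusion counts.
#' @return Object of class `eval_result` with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f_measure`, `f_arithmetic`.
#' @export
eval_result <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = p, recall = r,
                 f_measure = f, f_arithmetic = (p + r) / 2),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "<eval_result> TP=%d FP=%d FN=%d  P=%.3f R=%.3f F=%.3f\n",
    x$tp, x$fp, x$fn, x$precision, x$recall, x$f_measure))
  invisible(x)
}

#' Evaluate category prediction from co-expression
#'
#' For every annotated gene in the matrix, predicts categories from its top
#' `k` co-expressed genes by neighbor voting and scores the prediction
#' against the gene's own annotations by exact category match:
#' `TP = |predicted intersect annotated|`, `FP = |predicted \\ annotated|`,
#' `FN = |annotated \\ predicted|`.  Counts are pooled over genes
#' (micro-average) before precision/recall/F are computed.  Genes with
#' fewer than `k` valid correlation candidates are skipped (recorded in
#' `skipped`).
#'
#' @param em An [expression_matrix] (any state; correlations only use
#'   ranks of values, so the state tag is not enforced).
#' @param annotations A `go_annotations` object.
#' @param k Number of neighbors (default 20).
#' @param m Minimum neighbor votes for a prediction (default 2).
#' @param min_overlap Minimum pairwise-complete experiments (default 3).
#' @return An `eval_result`; attribute-free fields `n_evaluated` and
#'   `skipped` record coverage.
#' @export
evaluate_predictions <- function(em, annotations, k = 20, m = 2,
                                 min_overlap = 3) {
  stopifnot(inherits(em, "expression_matrix"),
            inherits(annotations, "go_annotations"))
  annotated <- intersect(em$gene_ids, as.integer(names(annotations)))
  if (length(annotated) < 2L)
    stop("need >= 2 annotated genes present in the matrix")
  cc <- gene_correlations(em, min_overlap)
  tp <- fp <- fn <- 0L
  skipped <- integer(0)
  for (g in annotated) {
    r <- cc[as.character(g), ]
    cand <- which(!is.na(r))
    if (length(cand) < k) {
      skipped <- c(skipped, g)
      next
    }
    nb <- suppressWarnings(
      top_correlated(em, g, k = k, min_overlap = min_overlap,
                     correlations = cc))
    pred <- predict_categories(g, nb, annotations, m = m)
    ann <- annotations[[as.character(g)]]
    tp <- tp + length(intersect(pred, ann))
    fp <- fp + length(setdiff(pred, ann))
    fn <- fn + length(setdiff(ann, pred))
  }
  res <- eval_result(tp, fp, fn)
  res$n_evaluated <- length(annotated) - length(skipped)
  res$skipped <- skipped
  res
}
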