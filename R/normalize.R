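#' Quantile-normalize all experiment columns against a common reference
#'
#' Replaces every experiment's value distribution with a single average
#' distribution so that expression levels are directly comparable across
#' platforms.  The reference is the positionwise mean of the sorted columns;
#' each value is then substituted by the reference value at its within-column
#' rank, so rank order inside every experiment is untouched and all complete
#' columns end up with identical sorted values.
#'
#' Missing values are common when many platforms with different gene
#' coverage are pooled, so the classical equal-length construction is
#' generalised through quantile positions: a column with `n` non-missing
#' values contributes its sorted values at positions `(i - 0.5) / n`,
#' linearly interpolated onto the reference grid of `(j - 0.5) / G`
#' (`G` = number of gene rows), and each value maps back through the same
#' interpolation at its rank's quantile position.  With no missing values
#' this reduces exactly to the classical sort/average/substitute scheme.
#' Tied values receive the mean of their tied ranks' reference values.
#'
#' @param em An [expression_matrix] with `state` `"scaled"` (or
#'   `"normalized"`, in which case the operation is idempotent); every
#'   column needs at least 2 non-missing values.
#' @param reference Optional frozen reference distribution (non-decreasing
#'   numeric vector of length `nrow(em$values)`), e.g. from a previous run
#'   via [read_reference()]; when supplied, columns are projected onto it
#'   instead of a newly averaged reference.
#' @return An [expression_matrix] with `state = "normalized"` and the
#'   reference distribution in `$reference`.
#' @export
quantile_normalize <- function(em, reference = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!em$state %in% c("scaled", "normalized"))
    stop("quantile_normalize expects a scaled matrix, got state=", em$state)
  v <- em$values
  G <- nrow(v)
  if (G < 1L || ncol(v) < 1L) stop("matrix is empty")
  n_obs <- colSums(!is.na(v))
  if (any(n_obs < 2L))
    stop("every column needs >= 2 non-missing values")
  grid <- (seq_len(G) - 0.5) / G

  if (is.null(reference)) {
    acc <- matrix(NA_real_, nrow = G, ncol = ncol(v))
    for (j in seq_len(ncol(v))) {
      s <- sort(v[, j], na.last = NA)
      n <- length(s)
      acc[, j] <- if (n == G) s else
        stats::approx(x = (seq_len(n) - 0.5) / n, y = s, xout = grid,
                      rule = 2)$y
    }
    reference <- rowMeans(acc)
  } else {
    reference <- as.numeric(reference)
    if (length(reference) != G)
      stop("reference length must equal the number of gene rows")
    if (is.unsorted(reference))
      stop("reference distribution must be non-decreasing")
  }

  out <- v
  for (j in seq_len(ncol(v))) {
    obs <- which(!is.na(v[, j]))
    x <- v[obs, j]
    n <- length(x)
    mapped_sorted <- if (n == G) reference else
      stats::approx(x = grid, y = reference,
                    xout = (seq_len(n) - 0.5) / n, rule = 2)$y
    r_lo <- rank(x, ties.method = "min")
    r_hi <- rank(x, ties.method = "max")
    cs <- c(0, cumsum(mapped_sorted))
    out[obs, j] <- (cs[r_hi + 1L] - cs[r_lo]) / (r_hi - r_lo + 1L)
  }
  expression_matrix(out, gene_ids = em$gene_ids,
                    experiment_ids = em$experiment_ids,
                    state = "normalized", reference = sort(reference))
}

#' Agreement between a matrix before and after a transformation
#'
#' Squared Pearson correlation (coefficient of determination, R-squared)
#' over all paired non-missing cells of two same-shaped matrices, used to
#' confirm that quantile normalization only gently rescales values.
#'
#' @param pre,post [expression_matrix] objects with identical shape and
#'   missingness pattern.
#' @return R-squared, a scalar in \[0, 1\].
#' @export
compare_pre_post <- function(pre, post) {
  stopifnot(inherits(pre, "expression_matrix"),
            inherits(post, "expression_matrix"))
  if (!identical(dim(pre$values), dim(post$values)))
    stop("matrices must have identical shape")
  if (!identical(which(is.na(pre$values)), which(is.na(post$values))))
    stop("matrices must have identical missing-value masks")
  stats::cor(as.numeric(pre$values), as.numeric(post$values),
             use = "complete.obs")^2
}

#' Save / load a reference distribution
#'
#' The averaged reference is written as a single-column TSV so that future
#' datasets can be projected onto a frozen reference instead of recomputing
#' it.
#'
#' @param reference Non-decreasing numeric vector.
#' @param path File path.
#' @return `write_reference`: invisibly, `path`; `read_reference`: the
#'   numeric vector.
#' @export
write_reference <- function(reference, path) {
  utils::write.table(data.frame(reference = reference), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  utils::read.delim(path)$reference
}
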