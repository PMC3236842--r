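#' Floor saturated outliers in one experiment
#'
#' Scanner saturation and other technical artefacts can leave a handful of
#' probes orders of magnitude above the rest of the distribution, which
#' would distort both rescaling and the averaged reference used by quantile
#' normalization.  For each experiment the top `ceil(fraction * n)`
#' non-missing values (`fraction` defaults to 0.1\%) are identified, their
#' minimum is taken as the flooring value, and all of them are replaced by
#' it.  At least one value is always in the top set, so a column's maximum
#' after flooring equals the flooring value.
#'
#' @param column Numeric vector of one experiment's intensities (`NA` =
#'   missing).
#' @param fraction Fraction of top values to floor, in (0, 1).
#' @param experiment_id Identifier copied into the record.
#' @return List with `column` (floored values) and `record` (class
#'   `flooring_record`: `experiment_id`, `n_floored`, `flooring_value`).
#' @export
floor_outliers <- function(column, fraction = 0.001, experiment_id = "") {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop("fraction must lie in (0, 1)")
  obs <- which(!is.na(column))
  if (length(obs) == 0L) stop("column has no non-missing values")
  n_floor <- max(1L, as.integer(ceiling(fraction * length(obs))))
  ord <- obs[order(column[obs], decreasing = TRUE)]
  top <- ord[seq_len(n_floor)]
  fv <- min(column[top])
  column[top] <- fv
  list(column = column,
       record = structure(list(experiment_id = experiment_id,
                               n_floored = n_floor, flooring_value = fv),
                          class = "flooring_record"))
}

#' Rescale one experiment to a common intensity range
#'
#' Linear (affine) map of the column onto `[lo, hi]` (default 0-10,000):
#' `v -> lo + (v - min) * (hi - lo) / (max - min)`.  Rank order, and ratios
#' of differences, are preserved exactly; the output minimum and maximum hit
#' the range endpoints.  A constant column has no usable dynamic range and
#' is rejected (such data fails the MM-ratio quality screen anyway).
#'
#' @param column Numeric vector (`NA` = missing).
#' @param lo,hi Target range endpoints.
#' @return Rescaled numeric vector.
#' @export
rescale <- function(column, lo = 0, hi = 10000) {
  obs <- column[!is.na(column)]
  if (length(unique(obs)) < 2L)
    stop("degenerate-range: column needs >= 2 distinct non-missing values")
  mn <- min(obs)
  mx <- max(obs)
  lo + (column - mn) * (hi - lo) / (mx - mn)
}

#' Floor and rescale every experiment of a raw matrix
#'
#' Applies [floor_outliers()] then [rescale()] to each experiment column of
#' a raw [expression_matrix], producing the `scaled` matrix on which
#' quantile normalization operates.
#'
#' @param em An [expression_matrix] with `state = "raw"`.
#' @param fraction Flooring fraction (see [floor_outliers()]).
#' @param lo,hi Rescaling range (see [rescale()]).
#' @return List with `matrix` (the scaled [expression_matrix]) and
#'   `flooring` (list of `flooring_record`s, one per experiment).
#' @export
preprocess_matrix <- function(em, fraction = 0.001, lo = 0, hi = 10000) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$state != "raw")
    stop("preprocess_matrix expects a raw matrix, got state=", em$state)
  records <- vector("list", ncol(em$values))
  v <- em$values
  for (j in seq_len(ncol(v))) {
    fl <- floor_outliers(v[, j], fraction = fraction,
                         experiment_id = em$experiment_ids[j])
    v[, j] <- rescale(fl$column, lo = lo, hi = hi)
    records[[j]] <- fl$record
  }
  list(matrix = expression_matrix(v, gene_ids = em$gene_ids,
                                  experiment_ids = em$experiment_ids,
                                  state = "scaled"),
       flooring = records)
}

#' Write flooring records as TSV
#'
#' @param records List of `flooring_record` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_flooring_log <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(experiment_id = r$experiment_id, n_floored = r$n_floored,
               flooring_value = r$flooring_value)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
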