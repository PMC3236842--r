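#' Mean/median-ratio quality screen
#'
#' One-color microarray intensities follow an approximately lognormal
#' distribution: unexpressed genes pile up in a low-intensity noise peak
#' while expressed genes spread over orders of magnitude above it, so the
#' dataset mean must clearly exceed the median.  A mean/median (MM) ratio
#' near 1 signals corrupted, log-transformed or otherwise non-raw data.
#' Datasets fail when the MM ratio is at or below `threshold` (default 1.2),
#' when the mean or the median is zero, or when any negative intensity is
#' present (expression cannot be negative).
#'
#' Mean and median are pooled over all non-missing values of the dataset's
#' gene-by-sample grid; set `per_sample = TRUE` to instead require every
#' sample column to pass on its own.
#'
#' @param grid Numeric gene-by-sample matrix (`NA` = missing), or a
#'   `gds_dataset` (its probe grid is used).
#' @param threshold MM-ratio cutoff; fail when `mm_ratio <= threshold`.
#' @param dataset_id Identifier copied into the report.
#' @param per_sample Apply the screen per sample column instead of pooled.
#' @return An object of class `qc_report`: `dataset_id`, `mean`, `median`,
#'   `mm_ratio`, `passed`, `reason` (`""` when passed).
#' @export
qc_dataset <- function(grid, threshold = 1.2, dataset_id = "",
                       per_sample = FALSE) {
  if (inherits(grid, "gds_dataset")) {
    if (dataset_id == "") dataset_id <- grid$dataset_id
    grid <- grid$values
  }
  v <- as.numeric(grid)
  v <- v[!is.na(v)]
  report <- function(m, md, r, passed, reason)
    structure(list(dataset_id = dataset_id, mean = m, median = md,
                   mm_ratio = r, passed = passed, reason = reason),
              class = "qc_report")
  if (length(v) == 0L)
    return(report(NA_real_, NA_real_, NA_real_, FALSE, "empty"))
  if (any(v < 0))
    return(report(mean(v), stats::median(v), NA_real_, FALSE,
                  "negative-values"))
  m <- mean(v)
  md <- stats::median(v)
  if (m == 0) return(report(m, md, NA_real_, FALSE, "zero-mean"))
  if (md == 0) return(report(m, md, NA_real_, FALSE, "zero-median"))
  r <- m / md
  if (per_sample) {
    cols <- apply(as.matrix(grid), 2, function(col) {
      col <- col[!is.na(col)]
      length(col) > 0 && all(col >= 0) && mean(col) > 0 &&
        stats::median(col) > 0 &&
        mean(col) / stats::median(col) > threshold
    })
    if (!all(cols))
      return(report(m, md, r, FALSE, "low-mm-ratio"))
  }
  if (r <= threshold) return(report(m, md, r, FALSE, "low-mm-ratio"))
  report(m, md, r, TRUE, "")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s: mean=%.4g median=%.4g MM=%.4g -> %s%s\n",
              x$dataset_id, x$mean, x$median, x$mm_ratio,
              if (x$passed) "PASS" else "FAIL",
              if (x$passed) "" else paste0(" (", x$reason, ")")))
  invisible(x)
}

#' Histogram of MM ratios across datasets
#'
#' Bins the mean/median ratios of a set of QC reports (pass or fail alike)
#' and reports the median MM ratio, the corpus-level summary of data
#' quality.
#'
#' @param reports List of `qc_report` objects.
#' @param breaks Bin edges passed to [base::cut()]; default covers 0-20 in
#'   steps of 0.5 with an overflow bin.
#' @return List with `counts` (named integer vector per bin), `breaks`, and
#'   `median_ratio`.
#' @export
mm_histogram <- function(reports, breaks = c(seq(0, 20, by = 0.5), Inf)) {
  if (inherits(reports, "qc_report")) reports <- list(reports)
  stopifnot(length(reports) >= 1L)
  ratios <- vapply(reports, function(r) r$mm_ratio, numeric(1))
  ratios <- ratios[!is.na(ratios)]
  bins <- cut(ratios, breaks = breaks, include.lowest = TRUE, right = TRUE)
  list(counts = table(bins), breaks = breaks,
       median_ratio = stats::median(ratios))
}

#' Write QC reports as TSV
#'
#' @param reports List of `qc_report` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(reports, path) {
  if (inherits(reports, "qc_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, function(r)
    data.frame(dataset_id = r$dataset_id, mean = r$mean, median = r$median,
               mm_ratio = r$mm_ratio, passed = r$passed, reason = r$reason)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
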