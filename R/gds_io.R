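#' Construct a GDS dataset object
#'
#' Container for one parsed GDS SOFT file: the dataset-level metadata
#' attributes plus the probe-by-sample intensity table.  Missing values are
#' represented as `NA` (the SOFT table encodes them as the literal token
#' `"null"` or an empty cell).
#'
#' @param dataset_id Character scalar, e.g. `"GDS1234"`.
#' @param metadata Named character vector of SOFT `!dataset_*` attributes
#'   (names without the `!` prefix, lower-cased).
#' @param probe_ids Character vector of platform probe identifiers
#'   (SOFT column `ID_REF`); must be unique.
#' @param gene_labels Character vector of per-probe annotations
#'   (SOFT column `IDENTIFIER`), same length as `probe_ids`.
#' @param samples Character vector of sample (experiment) identifiers.
#' @param values Numeric matrix, `length(probe_ids)` rows by
#'   `length(samples)` columns; `NA` marks missing cells.
#' @return An object of class `gds_dataset`.
#' @export
gds_dataset <- function(dataset_id, metadata, probe_ids, gene_labels,
                        samples, values) {
  metadata <- vapply(metadata, as.character, character(1))
  names(metadata) <- tolower(trimws(names(metadata)))
  probe_ids <- as.character(probe_ids)
  gene_labels <- as.character(gene_labels)
  samples <- as.character(samples)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyDuplicated(probe_ids))
    stop("probe_ids must be unique within a dataset")
  if (length(gene_labels) != length(probe_ids))
    stop("gene_labels must align with probe_ids")
  if (!identical(dim(values), c(length(probe_ids), length(samples))))
    stop("values grid must be length(probe_ids) x length(samples)")
  dimnames(values) <- list(probe_ids, samples)
  structure(
    list(dataset_id = as.character(dataset_id), metadata = metadata,
         probe_ids = probe_ids, gene_labels = gene_labels,
         samples = samples, values = values),
    class = "gds_dataset")
}

#' @export
print.gds_dataset <- function(x, ...) {
  cat(sprintf("<gds_dataset> %s: %d probes x %d samples, %d metadata fields\n",
              x$dataset_id, length(x$probe_ids), length(x$samples),
              length(x$metadata)))
  invisible(x)
}

# Metadata fields the dataset-selection filter requires.
REQUIRED_GDS_FIELDS <- c("dataset_sample_organism", "dataset_type",
                         "dataset_channel_count", "dataset_value_type")

.parse_error <- function(line, msg) {
  stop(sprintf("SOFT parse error at line %d: %s", line, msg), call. = FALSE)
}

#' Parse a GDS SOFT file
#'
#' Reads the GDS dialect of GEO's SOFT format: one `^DATASET` entity line,
#' `!dataset_*` attribute lines, and a single tab-delimited table delimited
#' by `!dataset_table_begin` / `!dataset_table_end` whose first two columns
#' are `ID_REF` and `IDENTIFIER`.  `^SUBSET` blocks are skipped with a
#' warning.  Table cells that are empty or equal the literal string `"null"`
#' become `NA`; all other cells must parse as decimal numbers.
#'
#' @param path Path to an uncompressed SOFT text file, or a character vector
#'   of lines (anything `readLines()` accepts is a path; pass lines via
#'   `text`).
#' @param text Optional character vector of SOFT lines, used instead of
#'   `path`.
#' @return A [gds_dataset].
#' @seealso [write_soft()], [select_dataset()]
#' @export
parse_soft <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  dataset_id <- NA_character_
  meta <- character(0)
  tbl_start <- NA_integer_
  tbl_end <- NA_integer_
  in_subset <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, "^DATASET")) {
      in_subset <- FALSE
      eq <- regmatches(ln, regexpr("=.*$", ln))
      dataset_id <- if (length(eq)) trimws(sub("^=", "", eq)) else NA_character_
    } else if (startsWith(ln, "^SUBSET")) {
      if (!in_subset)
        warning("ignoring ^SUBSET block(s); subset annotations are not used")
      in_subset <- TRUE
    } else if (startsWith(ln, "!dataset_table_begin")) {
      tbl_start <- i
      break
    } else if (startsWith(ln, "!") && !in_subset) {
      eq_pos <- regexpr("=", ln, fixed = TRUE)
      if (eq_pos > 0) {
        key <- tolower(trimws(substr(ln, 2L, eq_pos - 1L)))
        meta[[key]] <- trimws(substr(ln, eq_pos + 1L, nchar(ln)))
      }
    }
  }
  if (is.na(dataset_id)) .parse_error(1L, "no ^DATASET entity line found")
  if (is.na(tbl_start)) .parse_error(length(lines), "no !dataset_table_begin")
  tbl_end <- which(startsWith(lines, "!dataset_table_end"))
  tbl_end <- tbl_end[tbl_end > tbl_start][1]
  if (is.na(tbl_end)) .parse_error(length(lines), "no !dataset_table_end")
  if (tbl_end - tbl_start < 2L)
    .parse_error(tbl_start, "table has no data rows")

  header <- strsplit(lines[[tbl_start + 1L]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 3L || toupper(header[1]) != "ID_REF" ||
      toupper(header[2]) != "IDENTIFIER")
    .parse_error(tbl_start + 1L,
                 "table header must start with ID_REF, IDENTIFIER")
  samples <- header[-(1:2)]
  body <- lines[(tbl_start + 2L):(tbl_end - 1L)]
  cells <- strsplit(body, "\t", fixed = TRUE)
  ncol_expected <- length(header)
  probe_ids <- character(length(body))
  gene_labels <- character(length(body))
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(samples))
  for (r in seq_along(body)) {
    row <- cells[[r]]
    # a trailing empty cell is dropped by strsplit; restore it
    if (length(row) == ncol_expected - 1L && endsWith(body[[r]], "\t"))
      row <- c(row, "")
    if (length(row) != ncol_expected)
      .parse_error(tbl_start + 1L + r,
                   sprintf("ragged row: %d cells, expected %d",
                           length(row), ncol_expected))
    probe_ids[r] <- row[1]
    gene_labels[r] <- row[2]
    raw <- trimws(row[-(1:2)])
    miss <- raw == "" | tolower(raw) == "null"
    num <- suppressWarnings(as.numeric(raw))
    bad <- !miss & is.na(num)
    if (any(bad))
      .parse_error(tbl_start + 1L + r,
                   sprintf("non-numeric cell '%s'", raw[which(bad)[1]]))
    num[miss] <- NA_real_
    vals[r, ] <- num
  }
  if (anyDuplicated(probe_ids))
    .parse_error(tbl_start, "duplicate ID_REF probe identifiers in table")

  missing_fields <- setdiff(REQUIRED_GDS_FIELDS, names(meta))
  ds <- gds_dataset(dataset_id, meta, probe_ids, gene_labels, samples, vals)
  attr(ds, "unparseable") <- length(missing_fields) > 0L
  attr(ds, "missing_fields") <- missing_fields
  ds
}

#' Write a GDS dataset as SOFT text
#'
#' Emits the GDS SOFT dialect that [parse_soft()] inverts exactly: the
#' `^DATASET` line, all metadata attributes, and the tab-delimited table
#' with missing values encoded as `"null"`.
#'
#' @param dataset A [gds_dataset].
#' @param path Output file path; if `NULL` the lines are returned invisibly
#'   without writing.
#' @return Invisibly, the character vector of SOFT lines.
#' @export
write_soft <- function(dataset, path = NULL) {
  stopifnot(inherits(dataset, "gds_dataset"))
  if (length(dataset$samples) == 0L)
    stop("refusing to write a dataset with no samples")
  fmt_num <- function(v) {
    out <- sprintf("%.17g", v)  # full double precision: exact round-trip
    out[is.na(v)] <- "null"
    out
  }
  lines <- c(
    sprintf("^DATASET = %s", dataset$dataset_id),
    sprintf("!%s = %s", names(dataset$metadata), unname(dataset$metadata)),
    "!dataset_table_begin",
    paste(c("ID_REF", "IDENTIFIER", dataset$samples), collapse = "\t"))
  body <- vapply(seq_along(dataset$probe_ids), function(r) {
    paste(c(dataset$probe_ids[r], dataset$gene_labels[r],
            fmt_num(dataset$values[r, ])), collapse = "\t")
  }, character(1))
  lines <- c(lines, body, "!dataset_table_end")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Dataset-selection filter for one-color human expression datasets
#'
#' Accepts a dataset iff its metadata says: organism \emph{homo sapiens},
#' dataset type \emph{nucleotide} or \emph{gene expression}, channel count
#' \emph{single} or \emph{1}, and value type \emph{count} (raw intensities,
#' not ratios or transformed values).  All comparisons are case-insensitive
#' and whitespace-trimmed.  The decision depends only on these four fields.
#'
#' @param meta Named character vector of SOFT metadata (as in
#'   [gds_dataset]), or a [gds_dataset].
#' @return A list with `accepted` (logical) and `reason` (character: `""`
#'   when accepted, otherwise the first failing field, or
#'   `"missing:<field>"`).
#' @export
select_dataset <- function(meta) {
  if (inherits(meta, "gds_dataset")) meta <- meta$metadata
  names(meta) <- tolower(trimws(names(meta)))
  get <- function(field) {
    if (!field %in% names(meta)) return(NULL)
    tolower(trimws(meta[[field]]))
  }
  checks <- list(
    dataset_sample_organism = function(v) v == "homo sapiens",
    dataset_type            = function(v) v %in% c("nucleotide",
                                                   "gene expression"),
    dataset_channel_count   = function(v) v %in% c("single", "1"),
    dataset_value_type      = function(v) v == "count")
  for (field in names(checks)) {
    v <- get(field)
    if (is.null(v))
      return(list(accepted = FALSE, reason = paste0("missing:", field)))
    if (!checks[[field]](v))
      return(list(accepted = FALSE, reason = field))
  }
  list(accepted = TRUE, reason = "")
}

#' Write an expression matrix as TSV
#'
#' Tab-delimited text: first column `EntrezID`, one column per experiment,
#' rows in ascending Entrez ID order, missing values as empty cells.
#'
#' @param em An [expression_matrix].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [read_matrix_tsv()]
#' @export
write_matrix <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  ord <- order(em$gene_ids)
  v <- em$values[ord, , drop = FALSE]
  txt <- matrix(sprintf("%.17g", v), nrow = nrow(v))
  txt[is.na(v)] <- ""
  lines <- c(paste(c("EntrezID", em$experiment_ids), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(r)
               paste(c(em$gene_ids[ord][r], txt[r, ]), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix written by [write_matrix()]
#'
#' @param path TSV path.
#' @param state Processing state tag to attach (`"raw"`, `"scaled"` or
#'   `"normalized"`).
#' @return An [expression_matrix].
#' @export
read_matrix_tsv <- function(path, state = "raw") {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  gene_ids <- as.integer(df[[1]])
  vals <- as.matrix(df[-1])
  vals[vals == ""] <- NA
  storage.mode(vals) <- "double"
  expression_matrix(vals, gene_ids = gene_ids,
                    experiment_ids = colnames(df)[-1], state = state)
}
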