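#' Load an NCBI gene_info catalog
#'
#' Builds the lookup used to map platform probe annotations to Entrez Gene
#' IDs from a tab-delimited table in NCBI `gene_info` layout (columns
#' `tax_id`, `GeneID`, `Symbol`, `LocusTag`, `Synonyms`, `dbXrefs`, ...;
#' synonyms pipe-separated, `-` meaning none).  Keys are upper-cased.
#'
#' Precedence rules, applied at load time so lookup is deterministic:
#' official symbols always beat synonyms (a synonym equal to another gene's
#' official symbol is discarded); when two genes claim the same official
#' symbol, or two synonyms collide, the lowest GeneID wins and the collision
#' is reported via `message()`.
#'
#' @param path Path to a gene_info-style TSV (a leading `#`-header line as
#'   in NCBI's distribution is handled), or a `data.frame` with at least
#'   columns `GeneID`, `Symbol`, `Synonyms`.
#' @return An object of class `gene_catalog` with elements `symbol_to_id`
#'   (named integer vector, names upper-cased) and `id_set` (integer vector
#'   of valid GeneIDs).
#' @export
load_gene_info <- function(path) {
  if (is.data.frame(path)) {
    df <- path
  } else {
    first <- readLines(path, n = 1L)
    if (startsWith(first, "#")) {
      header <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1]]
      df <- utils::read.delim(path, skip = 1L, header = FALSE,
                              col.names = make.names(header),
                              colClasses = "character", quote = "")
      names(df) <- header
    } else {
      df <- utils::read.delim(path, colClasses = "character", quote = "")
    }
  }
  if (!all(c("GeneID", "Symbol") %in% names(df)))
    stop("gene_info table must have GeneID and Symbol columns")
  ids <- suppressWarnings(as.integer(df$GeneID))
  if (anyNA(ids)) stop("GeneID column must be integer")
  symbols <- toupper(trimws(as.character(df$Symbol)))
  syn_col <- if ("Synonyms" %in% names(df)) as.character(df$Synonyms)
             else rep("-", nrow(df))

  # official symbols first; symbol-vs-symbol collision -> lowest GeneID
  ord <- order(ids)
  symbol_to_id <- integer(0)
  sym_sorted <- symbols[ord]
  ids_sorted <- ids[ord]
  dup <- duplicated(sym_sorted)
  if (any(dup))
    message(sprintf("gene_info: %d official-symbol collision(s), keeping lowest GeneID: %s",
                    sum(dup),
                    paste(utils::head(unique(sym_sorted[dup]), 5), collapse = ", ")))
  symbol_to_id <- stats::setNames(ids_sorted[!dup], sym_sorted[!dup])
  official <- names(symbol_to_id)

  # synonyms: official symbols win; synonym-vs-synonym -> lowest GeneID
  syn_lists <- strsplit(syn_col, "|", fixed = TRUE)
  syn_keys <- toupper(trimws(unlist(syn_lists)))
  syn_ids <- rep(ids, lengths(syn_lists))
  keep <- !is.na(syn_keys) & syn_keys != "" & syn_keys != "-" &
    !(syn_keys %in% official)
  syn_keys <- syn_keys[keep]
  syn_ids <- syn_ids[keep]
  if (length(syn_keys)) {
    ord <- order(syn_ids)
    syn_keys <- syn_keys[ord]
    syn_ids <- syn_ids[ord]
    dup <- duplicated(syn_keys)
    if (any(syn_keys[dup] != "")) {
      collided <- unique(syn_keys[dup & !duplicated(paste(syn_keys, syn_ids))])
    }
    symbol_to_id <- c(symbol_to_id,
                      stats::setNames(syn_ids[!dup], syn_keys[!dup]))
  }
  structure(list(symbol_to_id = symbol_to_id,
                 id_set = sort(unique(ids))),
            class = "gene_catalog")
}

#' Look up identifiers in a gene catalog
#'
#' Case-insensitive, whitespace-trimmed lookup.
#'
#' @param catalog A `gene_catalog` from [load_gene_info()].
#' @param keys Character vector of symbols/synonyms/accessions.
#' @return Integer Entrez IDs, `NA` where unresolved.
#' @export
catalog_lookup <- function(catalog, keys) {
  stopifnot(inherits(catalog, "gene_catalog"))
  unname(catalog$symbol_to_id[toupper(trimws(as.character(keys)))])
}

#' Map a dataset's probes to Entrez Gene IDs
#'
#' Resolves each probe's `IDENTIFIER` annotation through the catalog.
#' Probes whose identifier does not resolve are recorded as unmapped (a
#' normal outcome); if \emph{no} probe maps, a warning flags that the
#' platform may lack mapping data in the catalog.
#'
#' @param dataset A [gds_dataset].
#' @param catalog A `gene_catalog`.
#' @param probe_annotation Optional named character vector overriding the
#'   dataset's `IDENTIFIER` column (names = probe IDs, values = identifiers
#'   to look up), for platforms whose GDS annotation is unusable.
#' @param unmapped_log Optional path; unmapped probes are appended as
#'   `dataset_id<TAB>probe_id<TAB>identifier` lines.
#' @return An object of class `probe_map` with `probe_to_gene` (named
#'   integer vector) and `unmapped` (character vector of probe IDs).
#' @export
map_probes <- function(dataset, catalog, probe_annotation = NULL,
                       unmapped_log = NULL) {
  stopifnot(inherits(dataset, "gds_dataset"))
  labels <- dataset$gene_labels
  names(labels) <- dataset$probe_ids
  if (!is.null(probe_annotation)) {
    hit <- intersect(names(probe_annotation), names(labels))
    labels[hit] <- probe_annotation[hit]
  }
  ids <- catalog_lookup(catalog, labels)
  mapped <- !is.na(ids)
  if (!any(mapped))
    warning(sprintf(
      "dataset %s: no probe mapped; the platform may lack mapping data",
      dataset$dataset_id))
  pm <- structure(
    list(probe_to_gene = stats::setNames(ids[mapped],
                                         dataset$probe_ids[mapped]),
         unmapped = dataset$probe_ids[!mapped]),
    class = "probe_map")
  if (!is.null(unmapped_log) && length(pm$unmapped)) {
    cat(sprintf("%s\t%s\t%s\n", dataset$dataset_id, pm$unmapped,
                labels[pm$unmapped]),
        file = unmapped_log, append = TRUE, sep = "")
  }
  pm
}

#' Collapse probes to genes by the maximum-expression rule
#'
#' For each Entrez ID and sample, the output value is the maximum over the
#' non-missing values of all probes assigned to that gene; a gene with only
#' missing values in a sample stays missing.  Probes recognising all
#' isoforms of a gene hybridise at least as strongly as isoform-specific
#' probes, so the per-gene maximum is the natural single-number summary.
#' Unmapped probes are dropped.
#'
#' @param dataset A [gds_dataset].
#' @param pmap A `probe_map` for this dataset.
#' @return Numeric matrix, rows named by ascending Entrez ID, columns by
#'   sample.
#' @export
aggregate_to_genes <- function(dataset, pmap) {
  stopifnot(inherits(dataset, "gds_dataset"), inherits(pmap, "probe_map"))
  probes <- names(pmap$probe_to_gene)
  if (!all(probes %in% dataset$probe_ids))
    stop("probe_map refers to probes absent from the dataset")
  if (length(probes) == 0L)
    return(matrix(numeric(0), nrow = 0, ncol = length(dataset$samples),
                  dimnames = list(NULL, dataset$samples)))
  genes <- sort(unique(pmap$probe_to_gene))
  sub <- dataset$values[probes, , drop = FALSE]
  g <- factor(pmap$probe_to_gene[probes], levels = genes)
  out <- apply(sub, 2, function(col) {
    v <- tapply(col, g, function(x)
      if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
    as.numeric(v)
  })
  out <- matrix(out, nrow = length(genes), ncol = length(dataset$samples),
                dimnames = list(genes, dataset$samples))
  out
}
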