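# Shared in-code fixtures and independent oracles.

soft_lines_minimal <- function() {
  c("^DATASET = GDS0001",
    "!dataset_title = minimal fixture",
    "!dataset_sample_organism = Homo sapiens",
    "!dataset_type = gene expression",
    "!dataset_channel_count = 1",
    "!dataset_value_type = count",
    "!dataset_table_begin",
    "ID_REF\tIDENTIFIER\tGSM1\tGSM2",
    "P1\tTP53\t1\t2",
    "P2\tBRCA1\t3\t4",
    "!dataset_table_end")
}

# gene 9999's official symbol P53X collides with a TP53 synonym;
# genes 11111/22222 claim the same official symbol DUPX
tiny_gene_info <- function() {
  data.frame(
    tax_id = 9606L,
    GeneID = c(7157L, 672L, 9999L, 22222L, 11111L),
    Symbol = c("TP53", "BRCA1", "P53X", "DUPX", "DUPX"),
    LocusTag = "-",
    Synonyms = c("P53|LFS1|P53X", "-", "-", "-", "-"),
    dbXrefs = "-",
    stringsAsFactors = FALSE)
}

scaled_em <- function(values, ids = NULL) {
  values <- as.matrix(values)
  if (is.null(ids)) ids <- seq_len(nrow(values))
  expression_matrix(values, gene_ids = ids,
                    experiment_ids = paste0("E", seq_len(ncol(values))),
                    state = "scaled")
}

# brute-force quantile normalization: explicit sort/average/substitute,
# tied values averaged over their tied positions' reference values
qn_oracle <- function(v) {
  ref <- rowMeans(apply(v, 2, sort))
  out <- v
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    piv <- order(x)
    s <- x[piv]
    y <- stats::ave(ref, match(s, unique(s)), FUN = mean)
    out[piv, j] <- y
  }
  out
}

# brute-force per-gene maximum over assigned probe rows
aggregate_oracle <- function(values, genes_of_probes) {
  gl <- sort(unique(genes_of_probes))
  out <- matrix(NA_real_, length(gl), ncol(values),
                dimnames = list(gl, colnames(values)))
  for (g in gl) for (j in seq_len(ncol(values))) {
    vs <- values[genes_of_probes == g, j]
    vs <- vs[!is.na(vs)]
    if (length(vs)) out[as.character(g), j] <- max(vs)
  }
  out
}
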