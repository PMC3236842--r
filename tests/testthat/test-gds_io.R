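test_that("parse_soft reads a minimal GDS table", {
  d <- parse_soft(text = soft_lines_minimal())
  expect_s3_class(d, "gds_dataset")
  expect_equal(d$dataset_id, "GDS0001")
  expect_equal(d$probe_ids, c("P1", "P2"))
  expect_equal(d$gene_labels, c("TP53", "BRCA1"))
  expect_equal(d$samples, c("GSM1", "GSM2"))
  expect_equal(unname(d$values), matrix(c(1, 3, 2, 4), 2))
  expect_equal(d$metadata[["dataset_channel_count"]], "1")
  expect_false(attr(d, "unparseable"))
})

test_that("null and empty table cells become the missing marker", {
  lines <- soft_lines_minimal()
  lines[9] <- "P1\tTP53\tnull\t2"
  lines[10] <- "P2\tBRCA1\t3\t"
  d <- parse_soft(text = lines)
  expect_true(is.na(d$values[1, 1]))
  expect_true(is.na(d$values[2, 2]))
  expect_equal(d$values[1, 2], 2)
})

test_that("malformed tables give structured parse errors naming the line", {
  ragged <- soft_lines_minimal()
  ragged[10] <- "P2\tBRCA1\t3"
  expect_error(parse_soft(text = ragged), "line 10.*ragged")
  bad <- soft_lines_minimal()
  bad[9] <- "P1\tTP53\tabc\t2"
  expect_error(parse_soft(text = bad), "line 9.*non-numeric")
  noid <- soft_lines_minimal()
  noid[8] <- "PROBE\tIDENTIFIER\tGSM1\tGSM2"
  expect_error(parse_soft(text = noid), "ID_REF")
})

test_that("datasets missing required metadata are flagged unparseable", {
  lines <- soft_lines_minimal()[-5]  # drop channel count
  d <- suppressWarnings(parse_soft(text = lines))
  expect_true(attr(d, "unparseable"))
  expect_equal(attr(d, "missing_fields"), "dataset_channel_count")
})

test_that("SUBSET blocks are skipped with a warning", {
  lines <- append(soft_lines_minimal(),
                  c("^SUBSET = GDS0001_1", "!subset_type = disease state"),
                  after = 1)
  expect_warning(d <- parse_soft(text = lines), "SUBSET")
  expect_equal(dim(d$values), c(2L, 2L))
  expect_false("subset_type" %in% names(d$metadata))
})

test_that("select_dataset applies the four selection filters", {
  ok <- c(dataset_sample_organism = "Homo sapiens",
          dataset_type = "gene expression",
          dataset_channel_count = "1",
          dataset_value_type = "count")
  expect_true(select_dataset(ok)$accepted)
  expect_true(select_dataset(replace(ok, 2, "nucleotide"))$accepted)
  expect_true(select_dataset(replace(ok, 3, "single"))$accepted)

  mouse <- replace(ok, 1, "mus musculus")
  expect_equal(select_dataset(mouse),
               list(accepted = FALSE, reason = "dataset_sample_organism"))
  two_col <- replace(ok, 3, "2")
  expect_equal(select_dataset(two_col)$reason, "dataset_channel_count")
  ratio <- replace(ok, 4, "log ratio")
  expect_equal(select_dataset(ratio)$reason, "dataset_value_type")
  expect_equal(select_dataset(ok[-4])$reason, "missing:dataset_value_type")
})

test_that("selection ignores every metadata field but the four named ones", {
  base <- c(dataset_sample_organism = "HOMO SAPIENS  ",
            dataset_type = "Gene Expression",
            dataset_channel_count = "Single",
            dataset_value_type = "COUNT")
  expect_true(select_dataset(base)$accepted)  # case/whitespace-insensitive
  set.seed(11)
  for (i in 1:10) {
    extra <- stats::setNames(as.character(sample(100, 5)),
                             paste0("dataset_extra_", sample(1000, 5)))
    shuffled <- sample(c(base, extra))
    expect_true(select_dataset(shuffled)$accepted)
  }
})

test_that("write_soft and parse_soft invert each other on fixtures", {
  spec <- sim_spec(seed = 3, n_genes = 30, n_datasets = 2,
                   samples_per_dataset = 4, n_modules = 1,
                   genes_per_module = 5)
  d <- simulate_dataset(spec, 2)
  d$values[5, 2] <- NA  # inject a missing cell
  tmp <- withr::local_tempfile(fileext = ".soft")
  write_soft(d, tmp)
  d2 <- parse_soft(tmp)
  expect_equal(d2$dataset_id, d$dataset_id)
  expect_equal(d2$metadata, d$metadata)
  expect_equal(d2$probe_ids, d$probe_ids)
  expect_equal(d2$gene_labels, d$gene_labels)
  expect_equal(d2$samples, d$samples)
  expect_equal(d2$values, d$values, tolerance = 1e-12)
})

test_that("write_soft encodes missing as a single null token and refuses empty", {
  d <- parse_soft(text = soft_lines_minimal())
  d$values[2, 1] <- NA
  lines <- write_soft(d)
  body <- lines[(which(lines == "!dataset_table_begin") + 2):
                (which(lines == "!dataset_table_end") - 1)]
  expect_equal(sum(unlist(strsplit(body, "\t")) == "null"), 1L)

  empty <- d
  empty$samples <- character(0)
  empty$values <- d$values[, 0, drop = FALSE]
  expect_error(write_soft(empty), "no samples")
})

test_that("write_matrix emits sorted TSV with empty cells and round-trips", {
  v <- matrix(c(10, 20, NA, 40), 2, 2)
  em <- expression_matrix(v, gene_ids = c(70, 7),
                          experiment_ids = c("GSM1", "GSM2"), state = "raw")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(em, tmp)
  lines <- readLines(tmp)
  expect_length(lines, 3L)
  expect_equal(lines[1], "EntrezID\tGSM1\tGSM2")
  expect_equal(lines[2], "7\t20\t40")       # ascending Entrez order
  expect_equal(lines[3], "70\t10\t")        # masked cell -> empty field
  back <- read_matrix_tsv(tmp)
  expect_equal(back$gene_ids, c(7L, 70L))
  expect_equal(unname(back$values), unname(em$values[c(2, 1), ]))
})
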