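test_that("the seed fully determines the corpus", {
  s1 <- simulate_corpus(sim_spec(seed = 9, n_genes = 40, n_datasets = 2,
                                 samples_per_dataset = 3,
                                 n_modules = 1, genes_per_module = 5))
  s2 <- simulate_corpus(sim_spec(seed = 9, n_genes = 40, n_datasets = 2,
                                 samples_per_dataset = 3,
                                 n_modules = 1, genes_per_module = 5))
  expect_identical(s1$datasets, s2$datasets)
  expect_identical(s1$annotations, s2$annotations)
  # byte-identical SOFT text
  expect_identical(write_soft(s1$datasets[[2]]), write_soft(s2$datasets[[2]]))
})

test_that("generated datasets pass selection and round-trip by construction", {
  spec <- sim_spec(seed = 10, n_genes = 30, n_datasets = 3,
                   samples_per_dataset = 4, n_modules = 0)
  corpus <- simulate_corpus(spec)
  for (d in corpus$datasets) {
    expect_true(select_dataset(d)$accepted)
    expect_identical(parse_soft(text = write_soft(d))$values, d$values)
  }
})

test_that("pure-noise datasets fail QC, default datasets pass", {
  noise_only <- simulate_dataset(
    sim_spec(seed = 11, expressed_fraction = 0, n_modules = 0), 1)
  r <- qc_dataset(noise_only)
  expect_false(r$passed)

  ok <- vapply(1:25, function(s) {
    r <- qc_dataset(simulate_dataset(sim_spec(seed = s), 1))
    r$passed && r$mm_ratio > 1.2
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("modules are disjoint, drawn from expressed genes, and annotated", {
  spec <- sim_spec(seed = 12, n_modules = 4, genes_per_module = 10)
  corpus <- simulate_corpus(spec)
  mods <- corpus$truth$modules
  expect_length(mods, 4L)
  expect_equal(anyDuplicated(unlist(mods)), 0L)
  expect_true(all(unlist(mods) %in% corpus$truth$expressed))
  # every gene carries at least one category
  expect_setequal(as.integer(names(corpus$annotations)),
                  corpus$truth$gene_ids)
  # module genes share their module category
  first <- mods[[1]]
  cats <- unlist(corpus$annotations[as.character(first)])
  expect_length(unique(cats), 1L)
})

test_that("module genes are co-expressed at the requested strength", {
  spec <- sim_spec(seed = 13, n_datasets = 4, samples_per_dataset = 25,
                   n_modules = 1, genes_per_module = 12, module_cor = 0.8,
                   platform_scale_factors = 1, platform_powers = 1,
                   probes_per_gene = 1, junk_probe_fraction = 0,
                   outlier_fraction = 0)
  corpus <- simulate_corpus(spec)
  mod <- corpus$truth$modules[[1]]
  # log-scale correlation of module genes across samples approximates rho
  logs <- do.call(cbind, lapply(corpus$datasets, function(d) {
    idx <- match(sprintf("P%d_1", mod), d$probe_ids)
    log(d$values[idx, ])
  }))
  cc <- cor(t(logs))
  expect_equal(mean(cc[upper.tri(cc)]), 0.8, tolerance = 0.1)
})

test_that("platform gains and powers are honored and recycled", {
  spec <- sim_spec(seed = 14, n_datasets = 4,
                   platform_scale_factors = c(1, 10),
                   platform_powers = c(1, 1.2))
  layout <- gdsnorm:::.sim_layout(spec)
  expect_equal(layout$gains, c(1, 10, 1, 10))
  expect_equal(layout$powers, c(1, 1.2, 1, 1.2))
})

test_that("invalid simulation specs are rejected", {
  expect_error(sim_spec(expressed_fraction = 1), "expressed_fraction")
  expect_error(sim_spec(expressed_fraction = 0, n_modules = 1),
               "expressed_fraction")
  expect_error(sim_spec(n_modules = 50, genes_per_module = 20),
               "more expressed genes")
  expect_error(sim_spec(module_cor = 1), "module_cor")
  expect_error(sim_spec(noise_sigma = 0), "noise_sigma")
  expect_error(sim_spec(decoy_category_size = 0), "decoy_category_size")
  expect_error(simulate_dataset(sim_spec(n_datasets = 2), 3), "out of range")
})

test_that("corpus files are written for offline use", {
  out <- withr::local_tempdir()
  spec <- sim_spec(seed = 15, n_genes = 25, n_datasets = 2,
                   samples_per_dataset = 3, n_modules = 1,
                   genes_per_module = 5)
  corpus <- simulate_corpus(spec, out_dir = out)
  expect_setequal(list.files(out),
                  c("GDS1001.soft", "GDS1002.soft",
                    "truth_annotations.tsv", "gene_info.tsv"))
  reread <- parse_soft(file.path(out, "GDS1001.soft"))
  expect_identical(reread$values, corpus$datasets[[1]]$values)
})
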