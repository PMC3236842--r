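make_em <- function(v, ids = NULL) {
  if (is.null(ids)) ids <- 100L + seq_len(nrow(v))
  expression_matrix(v, gene_ids = ids,
                    experiment_ids = paste0("e", seq_len(ncol(v))),
                    state = "normalized")
}

test_that("a copied gene ranks first and an anticorrelated gene last", {
  set.seed(51)
  a <- rlnorm(8, 3, 1)
  v <- rbind(a, a + 0.001, max(a) - a + min(a),
             matrix(rlnorm(4 * 8, 3, 1), 4))
  em <- make_em(v)  # genes 101 (query), 102 (copy), 103 (mirror), 104-107
  nb <- top_correlated(em, 101, k = 6)
  expect_equal(nb[1], 102L)      # r = 1
  expect_equal(nb[6], 103L)      # r = -1 ranks last
  expect_false(103L %in% top_correlated(em, 101, k = 5))
})

test_that("neighbor ordering matches brute-force Pearson with ID tie-break", {
  set.seed(52)
  for (i in 1:5) {
    v <- matrix(rlnorm(5 * 7, 3, 1), 5, 7)
    em <- make_em(v, ids = c(30L, 10L, 20L, 50L, 40L))
    got <- top_correlated(em, 30, k = 4)
    r <- vapply(2:5, function(j) cor(v[1, ], v[j, ]), 0)
    ids <- c(10L, 20L, 50L, 40L)[order(-vapply(2:5, function(j)
      cor(v[1, ], v[j, ]), 0), c(10L, 20L, 50L, 40L))]
    # recompute independently: order by descending correlation, then ID
    cand <- data.frame(id = c(10L, 20L, 50L, 40L), r = r)
    cand <- cand[order(-cand$r, cand$id), ]
    expect_equal(got, cand$id)
  }
})

test_that("pairs below the minimum experiment overlap are excluded", {
  v <- rbind(c(1, 5, 3, NA, NA, NA),
             c(2, 4, 9, NA, NA, NA),
             c(NA, NA, 2, 7, 1, 4),
             c(1, 2, 3, 4, 5, 6))
  em <- make_em(v)
  cc <- gene_correlations(em, min_overlap = 3)
  expect_true(is.na(cc["101", "103"]))   # overlap 1
  expect_false(is.na(cc["101", "102"]))  # overlap 3
  expect_warning(top_correlated(em, 103, k = 3), "candidates")
})

test_that("neighbor voting predicts categories above the vote threshold", {
  ann <- load_annotations(data.frame(
    gene = c(1:20, 1, 2),
    category = c(rep("X", 20), "Y", "Y")))
  expect_equal(predict_categories(99, 1:20, ann, m = 2), c("X", "Y"))
  expect_equal(predict_categories(99, 1:20, ann, m = 3), "X")
  # a category held by one neighbor is not predicted at m = 2
  expect_false("Y" %in% predict_categories(99, c(1, 3:20), ann, m = 2))
  # m = 1 gives the union
  expect_setequal(predict_categories(99, c(1, 3), ann, m = 1), c("X", "Y"))
  # the query's own annotations are never consulted
  expect_equal(predict_categories(1, c(1, 3:20), ann, m = 2), "X")
})

test_that("precision, recall and F follow the stated formulas", {
  r <- eval_result(1, 1, 1)
  expect_equal(r$precision, 0.5)
  expect_equal(r$recall, 0.5)
  expect_equal(r$f_measure, 0.5)
  perfect <- eval_result(10, 0, 0)
  expect_equal(perfect$f_measure, 1)
  nothing <- eval_result(0, 0, 5)
  expect_equal(nothing$precision, 0)
  expect_equal(nothing$f_measure, 0)  # zero-denominator cases are 0
  r2 <- eval_result(3, 1, 2)
  expect_equal(r2$f_measure,
               2 * (3 / 4) * (3 / 5) / (3 / 4 + 3 / 5))
  expect_equal(r2$f_arithmetic, (3 / 4 + 3 / 5) / 2)
})

test_that("confusion counting agrees with a brute-force oracle", {
  set.seed(53)
  cats <- LETTERS[1:8]
  for (i in 1:20) {
    pred <- sample(cats, sample(0:5, 1))
    ann <- sample(cats, sample(1:5, 1))
    tp <- sum(pred %in% ann)
    fp <- sum(!pred %in% ann)
    fn <- sum(!ann %in% pred)
    r <- eval_result(tp, fp, fn)
    p_oracle <- if (length(pred)) tp / length(pred) else 0
    r_oracle <- tp / length(ann)
    expect_equal(r$precision, p_oracle)
    expect_equal(r$recall, r_oracle)
    f_oracle <- if (p_oracle + r_oracle > 0)
      2 * p_oracle * r_oracle / (p_oracle + r_oracle) else 0
    expect_equal(r$f_measure, f_oracle)
  }
})

test_that("planted modules are recovered from a normalized corpus", {
  spec <- sim_spec(seed = 6, n_datasets = 5, samples_per_dataset = 10,
                   n_modules = 3, genes_per_module = 25, module_cor = 0.8)
  corpus <- simulate_corpus(spec)
  cfg <- pipeline_config(datasets = corpus$datasets,
                         gene_info = corpus$gene_info)
  res <- suppressWarnings(suppressMessages(run_pipeline(cfg)))
  modules <- corpus$truth$modules
  ann <- load_annotations(data.frame(
    gene = unlist(modules),
    category = rep(sprintf("M%d", seq_along(modules)),
                   lengths(modules))))
  ev <- evaluate_predictions(res$matrices$normalized, ann)
  expect_gt(ev$f_measure, 0.5)
})

test_that("without module correlation F drops to the permutation baseline", {
  spec <- sim_spec(seed = 7, n_datasets = 5, samples_per_dataset = 10,
                   n_modules = 3, genes_per_module = 25, module_cor = 0)
  corpus <- simulate_corpus(spec)
  cfg <- pipeline_config(datasets = corpus$datasets,
                         gene_info = corpus$gene_info)
  res <- suppressWarnings(suppressMessages(run_pipeline(cfg)))
  modules <- corpus$truth$modules
  cats <- rep(sprintf("M%d", seq_along(modules)), lengths(modules))
  em <- res$matrices$normalized
  f_obs <- evaluate_predictions(
    em, load_annotations(data.frame(gene = unlist(modules),
                                    category = cats)))$f_measure
  # baseline: the same annotation structure on random gene sets
  set.seed(71)
  f_perm <- replicate(5, evaluate_predictions(
    em, load_annotations(data.frame(
      gene = sample(em$gene_ids, length(cats)),
      category = cats)))$f_measure)
  expect_lt(abs(f_obs - mean(f_perm)), 0.15)

  # and far below the strongly-correlated corpus of the previous test
  expect_lt(f_obs, 0.6)
})
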