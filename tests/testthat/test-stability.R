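test_that("ranks_from_importance uses descending order with average ties", {
  expect_equal(unname(ranks_from_importance(c(a = 3, b = 2, c = 1))),
               c(1, 2, 3))
  expect_equal(unname(ranks_from_importance(c(a = 5, b = 5, c = 1))),
               c(1.5, 1.5, 3))
  expect_error(ranks_from_importance(numeric(0)), "empty")
  expect_error(ranks_from_importance(c(a = 1, b = NaN)), "non-finite")
  # permutation-sum oracle: rank sums are G(G+1)/2 for any score vector
  set.seed(19)
  for (i in 1:25) {
    scores <- stats::setNames(round(rnorm(54), sample(0:2, 1)),
                              paste0("g", 1:54))
    expect_equal(sum(ranks_from_importance(scores)), 54 * 55 / 2)
  }
})

test_that("rank tensor: shape, determinism, and per-combination rank sums", {
  co <- quick_cohort(n = 120)
  plan <- make_splits(120, co$outcome, n_repeats = 2, inner_folds = 3,
                      seed = 4)
  pl <- default_pipeline_set()[c("base", "ct-limit-40")]
  specs <- quick_specs()[c("ridge-logistic", "random-forest")]
  t1 <- build_rank_tensor(co, specs, pl, plan, tune_folds = 3,
                          importance_B = 3, seed = 9)
  expect_s3_class(t1, "rank_tensor")
  expect_equal(dim(t1), c(2L, 2L, 2L, 12L))
  # every combination's ranks are a tie-averaged permutation of 1..G
  cm <- pcspanel:::tensor_combos(t1)
  expect_equal(nrow(cm), 8L)
  expect_true(all(abs(rowSums(cm) - 12 * 13 / 2) < 1e-9))
  t2 <- build_rank_tensor(co, specs, pl, plan, tune_folds = 3,
                          importance_B = 3, seed = 9)
  expect_identical(unclass(t1), unclass(t2))
})

test_that("a 1x1x1 tensor is exactly that single ranking", {
  co <- quick_cohort(n = 100)
  plan <- make_splits(100, co$outcome, n_repeats = 1, inner_folds = 3,
                      seed = 2)
  spec <- quick_specs()["ridge-logistic"]
  tensor <- build_rank_tensor(co, spec, default_pipeline_set()["base"],
                              plan, tune_folds = 3, seed = 5)
  expect_equal(dim(tensor), c(1L, 1L, 1L, 12L))
  # recompute the same fit directly
  dev <- plan$repeats[[1]]$dev
  pp <- preprocess_split(default_pipeline_set()[["base"]],
                         ct_subset(co$ct, dev))
  x <- cbind(pp$dev,
             pcspanel:::clinical_matrix(co$clinical, clinical_covariates())[dev, ])
  fit <- tune_and_fit(spec[[1]], x, co$outcome[dev],
                      seed = pcspanel:::derive_seed(5, 1, 1, 1), folds = 3)
  imp <- gene_importance(fit, x, co$outcome[dev],
                         genes(co$ct, include_reference = FALSE))
  expect_equal(as.numeric(tensor[1, 1, 1, ]),
               unname(ranks_from_importance(imp)))
})

test_that("aggregate_ranks matches brute-force loops in every mode", {
  tensor <- random_rank_tensor(np = 3, nm = 2, nr = 5, ng = 8, seed = 33)
  arr <- unclass(tensor)
  dn <- dimnames(arr)
  pcs <- aggregate_ranks(tensor, "pcs_ensembled")
  for (g in dn[[4]]) {
    acc <- c()
    for (p in 1:3) for (m in 1:2) for (r in 1:5) acc <- c(acc, arr[p, m, r, g])
    expect_equal(pcs$mean_rank[pcs$gene == g], mean(acc))
  }
  me <- aggregate_ranks(tensor, "model_ensembled")
  for (p in dn[[1]]) for (g in dn[[4]]) {
    acc <- c()
    for (m in 1:2) for (r in 1:5) acc <- c(acc, arr[p, m, r, g])
    expect_equal(me$mean_rank[me$pipeline == p & me$gene == g], mean(acc))
  }
  ms <- aggregate_ranks(tensor, "model_specific")
  for (p in dn[[1]]) for (m in dn[[2]]) for (g in dn[[4]]) {
    expect_equal(
      ms$mean_rank[ms$pipeline == p & ms$model == m & ms$gene == g],
      mean(arr[p, m, , g]))
  }
  expect_error(aggregate_ranks(tensor, "nope"))
})

test_that("constant and symmetric tensors aggregate as expected", {
  arr <- array(rep(1:6, each = 4), dim = c(2, 2, 1, 6),
               dimnames = list(pipeline = c("p1", "p2"),
                               model = c("m1", "m2"), rep = NULL,
                               gene = paste0("g", 1:6)))
  class(arr) <- c("rank_tensor", "array")
  for (mode in c("pcs_ensembled", "model_ensembled", "model_specific")) {
    agg <- aggregate_ranks(arr, mode)
    expect_equal(agg$mean_rank, as.numeric(sub("g", "", agg$gene)))
  }
  # two combos with swapped 2-gene rankings average to 1.5 each
  sym <- array(c(1, 2, 2, 1), dim = c(2, 1, 1, 2),
               dimnames = list(pipeline = c("p1", "p2"), model = "m1",
                               rep = NULL, gene = c("gA", "gB")))
  class(sym) <- c("rank_tensor", "array")
  agg <- aggregate_ranks(sym, "pcs_ensembled")
  expect_equal(agg$mean_rank, c(1.5, 1.5))
})

test_that("stability_summary equals direct recomputation on random tensors", {
  for (s in 1:5) {
    tensor <- random_rank_tensor(np = 2, nm = 3, nr = 4, ng = 54, seed = s)
    cm <- pcspanel:::tensor_combos(tensor)
    summ <- stability_summary(tensor)
    for (g in sample(colnames(cm), 6)) {
      v <- cm[, g]
      row <- summ[summ$gene == g, ]
      expect_equal(row$mean_rank, mean(v))
      expect_equal(row$sd_rank, sqrt(mean((v - mean(v))^2)))  # population SD
      expect_equal(row$prop_top5, mean(v <= 5))
      expect_equal(row$prop_top10, mean(v <= 10))
      expect_equal(row$prop_top17, mean(v <= 17))
    }
  }
  # constant tensor has SD zero everywhere
  rk <- sample(10)
  big <- array(rep(rk, each = 8), dim = c(2, 2, 2, 10),
               dimnames = list(pipeline = c("p1", "p2"),
                               model = c("m1", "m2"), rep = NULL,
                               gene = paste0("g", 1:10)))
  class(big) <- c("rank_tensor", "array")
  expect_true(all(stability_summary(big)$sd_rank == 0))
  # half rank 1, half rank 11 -> prop_top10 = 0.5
  half <- array(c(1, 11), dim = c(2, 1, 1, 1),
                dimnames = list(pipeline = c("p1", "p2"), model = "m1",
                                rep = NULL, gene = "gX"))
  class(half) <- c("rank_tensor", "array")
  expect_equal(stability_summary(half)$prop_top10, 0.5)
})

test_that("select_panel applies strict thresholds and appends the reference", {
  summ <- data.frame(
    gene = paste0("g", 1:10),
    mean_rank = c(2, 3, 4, 5, 6, 7, 12, 15, 20, 25),
    sd_rank = 1,
    prop_top10 = c(rep(0.9, 6), 0.5, 0.3, 0.1, 0.05))
  panel <- select_panel(summ, max_mean_rank = 10, min_prop_top10 = 0.7,
                        reference_gene = "KLK3")
  expect_equal(panel$genes, paste0("g", 1:6))
  expect_equal(panel_size(panel), 7L)  # 6 covariate genes + reference
  expect_equal(panel$reference_gene, "KLK3")
  expect_error(select_panel(summ, max_mean_rank = 1, min_prop_top10 = 0.99),
               "no gene met")
})

test_that("borderline next gene triggers the panel+next variant", {
  summ <- data.frame(
    gene = paste0("g", 1:8),
    mean_rank = c(2, 3, 4, 5, 6, 7, 8, 30),
    sd_rank = 1,
    prop_top10 = c(rep(0.9, 6), 0.68, 0.1))  # g7 misses one criterion by 0.02
  panel <- select_panel(summ, slack = 0.05)
  expect_equal(length(panel$genes), 6L)
  expect_false(is.null(panel$extended))
  expect_equal(panel$extended$borderline, "g7")
  expect_equal(length(panel$extended$genes), 7L)
})

test_that("loosening min_prop_top10 never removes a selected gene", {
  set.seed(44)
  summ <- data.frame(gene = paste0("g", 1:20),
                     mean_rank = runif(20, 1, 20), sd_rank = 1,
                     prop_top10 = runif(20))
  prev <- character(0)
  for (thr in c(0.9, 0.7, 0.5, 0.3, 0.1)) {
    sel <- tryCatch(
      select_panel(summ, max_mean_rank = 15, min_prop_top10 = thr)$genes,
      error = function(e) character(0))
    expect_true(all(prev %in% sel))
    prev <- sel
  }
})

test_that("pcs-ensembled means equal combination-weighted model-ensembled means", {
  tensor <- random_rank_tensor(np = 3, nm = 2, nr = 4, ng = 7, seed = 5)
  pcs <- aggregate_ranks(tensor, "pcs_ensembled")
  me <- aggregate_ranks(tensor, "model_ensembled")
  # equal combination counts per pipeline -> simple mean across pipelines
  for (g in paste0("g", 1:7)) {
    expect_equal(pcs$mean_rank[pcs$gene == g],
                 mean(me$mean_rank[me$gene == g]))
  }
})

test_that("rank tensor TSV round-trips", {
  tensor <- random_rank_tensor(np = 2, nm = 2, nr = 3, ng = 6, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rank_tensor_tsv(tensor, path)
  back <- read_rank_tensor_tsv(path)
  expect_equal(unclass(back), unclass(tensor))
})
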