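test_that("make_splits partitions, sizes, and stratifies correctly", {
  y <- rep(c(0, 1), c(60, 40))
  plan <- make_splits(100, y, n_repeats = 4, test_fraction = 0.25,
                      inner_folds = 4, seed = 3)
  for (r in plan$repeats) {
    expect_length(r$test, 25L)
    expect_length(r$dev, 75L)
    expect_equal(sort(c(r$dev, r$test)), 1:100)   # partition
    expect_length(intersect(r$dev, r$test), 0L)
    # outcome-stratified test set within one sample of proportionality
    expect_lte(abs(sum(y[r$test]) - 0.4 * 25), 1)
    # inner folds stratified too
    for (f in 1:4) {
      rows <- r$dev[r$fold == f]
      expect_lte(abs(sum(y[rows]) - 0.4 * length(rows)), 1.5)
    }
  }
  # determinism
  plan2 <- make_splits(100, y, n_repeats = 4, test_fraction = 0.25,
                       inner_folds = 4, seed = 3)
  expect_identical(plan, plan2)
  expect_error(make_splits(10, rep(0, 10)), "both outcome classes")
})

test_that("evaluate_grid bookkeeping: one record per (pipeline, model, repeat, fold)", {
  co <- quick_cohort(n = 120)
  plan <- make_splits(120, co$outcome, n_repeats = 2, inner_folds = 3,
                      seed = 2)
  specs <- quick_specs()[c("logistic", "ridge-logistic")]
  perf <- evaluate_grid(co, default_pipeline_set()["base"], specs, plan,
                        tune_folds = 3)
  expect_equal(nrow(perf$folds), 1L * 2L * 2L * 3L)
  expect_equal(sort(unique(perf$cells$n_evals)), 6L)
  expect_true(all(perf$cells$mean_auroc >= 0 & perf$cells$mean_auroc <= 1))
  expect_true(all(c("grand_mean_auroc", "pipeline_range", "gap_to_best")
                  %in% names(perf$model_variation)))
})

test_that("a perfectly separable gene yields AUROC 1 in every cell", {
  set.seed(6)
  n <- 80
  y <- rep(c(0L, 1L), each = n / 2)
  vals <- cbind(GA = 34 - 6 * y + rnorm(n, 0, 0.2),   # clean separation
                GB = rnorm(n, 30), KLK3 = rep(21, n))
  rownames(vals) <- paste0("S", 1:n)
  co <- list(ct = ct_matrix(vals, reference_gene = "KLK3"),
             clinical = data.frame(sample_id = rownames(vals),
                                   age = rnorm(n, 60), race = 0,
                                   family_history = 0, abnormal_dre = 0,
                                   prior_neg_biopsy = 0,
                                   psa = runif(n, 3, 10)),
             outcome = y)
  plan <- make_splits(n, y, n_repeats = 2, inner_folds = 3, seed = 1)
  perf <- evaluate_grid(co, default_pipeline_set()["base"],
                        quick_specs()["ridge-logistic"], plan,
                        tune_folds = 3)
  expect_true(all(perf$folds$auroc == 1))
})

test_that("no-signal cohorts hover at chance level", {
  cfg <- sim_config(n_samples = 400, n_genes = 8,
                    gene_names = sprintf("N%02d", 1:8),
                    signal_genes = numeric(0),
                    clinical_effects = c(age = 0, race = 0,
                                         family_history = 0,
                                         abnormal_dre = 0,
                                         prior_neg_biopsy = 0, psa = 0),
                    volume_effect = 0, seed = 12)
  co <- simulate_cohort(cfg)
  plan <- make_splits(400, co$outcome, n_repeats = 3, inner_folds = 3,
                      seed = 1)
  perf <- evaluate_grid(co, default_pipeline_set()["base"],
                        quick_specs()["ridge-logistic"], plan,
                        tune_folds = 3)
  expect_lt(abs(perf$cells$mean_auroc - 0.5), 0.1)
})

test_that("prediction_filter keeps ties and borderline pipeline winners", {
  cells <- data.frame(
    pipeline = rep(paste0("p", 1:4), times = 3),
    model = rep(c("logistic", "modelA", "modelB"), each = 4),
    mean_auroc = c(0.772, 0.772, 0.772, 0.772,   # reference
                   0.760, 0.766, 0.775, 0.775,   # borderline: one pipeline wins
                   0.750, 0.760, 0.765, 0.770))  # uniformly below
  filt <- prediction_filter(perf_summary(cells))
  expect_true("modelA" %in% filt$kept)
  expect_true("modelB" %in% filt$dropped)
  expect_true("logistic" %in% filt$kept)
  # exact tie with the reference keeps the model
  cells$mean_auroc[cells$model == "modelB"] <- 0.772
  expect_length(prediction_filter(perf_summary(cells))$dropped, 0L)
  expect_error(prediction_filter(perf_summary(cells), "nope"),
               "not present")
})

test_that("raising every fold AUROC can never flip kept to dropped", {
  set.seed(8)
  for (i in 1:20) {
    cells <- data.frame(
      pipeline = rep(c("p1", "p2"), times = 3),
      model = rep(c("logistic", "m1", "m2"), each = 2),
      mean_auroc = runif(6, 0.6, 0.9))
    f0 <- prediction_filter(perf_summary(cells))
    up <- cells
    lift <- runif(1, 0, 0.05)
    up$mean_auroc[up$model == "m1"] <- up$mean_auroc[up$model == "m1"] + lift
    f1 <- prediction_filter(perf_summary(up))
    if ("m1" %in% f0$kept) expect_true("m1" %in% f1$kept)
  }
})
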