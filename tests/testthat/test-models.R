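test_that("default model grid declares the nine learners with printed grids", {
  specs <- default_model_grid()
  expect_length(specs, 9L)
  expect_equal(nrow(specs[["logistic"]]$grid), 0L)            # no hyperparameters
  expect_equal(nrow(specs[["lasso-logistic"]]$grid), 13L)     # C = 10^(-3..3)
  expect_equal(nrow(specs[["ridge-logistic"]]$grid), 13L)
  expect_equal(nrow(specs[["elasticnet-logistic"]]$grid), 13L * 5L)
  expect_setequal(unique(specs[["elasticnet-logistic"]]$grid$l1_ratio),
                  c(0.1, 0.25, 0.5, 0.75, 0.9))
  expect_setequal(specs[["random-forest"]]$grid$min_samples_leaf,
                  c(1, 3, 5, 10))
  expect_equal(specs[["random-forest"]]$fixed$n_estimators, 500)
  expect_equal(nrow(specs[["gbdt"]]$grid), 3L * 3L * 2L)
  expect_setequal(specs[["rulefit"]]$grid$max_rules, c(5, 10, 30, 50))
  expect_setequal(specs[["figs"]]$grid$max_rules,
                  c(5, 10, 12, 15, 20, 30, 50))
  # Python-only learners are declared but not fittable here
  expect_false(specs[["rf-plus"]]$available)
  expect_length(available_specs(specs), 6L)
})

test_that("tune_and_fit: empty grid fits directly, one-point grid is forced", {
  co <- quick_cohort()
  expr <- apply_pipeline(fit_pipeline(default_pipeline_set()[["base"]],
                                      co$ct), co$ct)
  x <- cbind(expr, as.matrix(co$clinical[clinical_covariates()]))
  plain <- tune_and_fit(default_model_grid()[["logistic"]], x, co$outcome)
  expect_length(plain$chosen, 0L)
  one <- tune_and_fit(model_spec("ridge-logistic", "glmnet",
                                 grid = data.frame(C = 0.5),
                                 fixed = list(alpha = 0)),
                      x, co$outcome)
  expect_equal(one$chosen$C, 0.5)
  expect_error(tune_and_fit(plain <- default_model_grid()[["rulefit"]],
                            x, co$outcome), "not available")
  expect_error(tune_and_fit(default_model_grid()[["logistic"]],
                            x, rep(1, nrow(x))), "single class")
})

test_that("tuning is reproducible and probabilities are valid", {
  co <- quick_cohort()
  expr <- apply_pipeline(fit_pipeline(default_pipeline_set()[["base"]],
                                      co$ct), co$ct)
  x <- cbind(expr, as.matrix(co$clinical[clinical_covariates()]))
  spec <- model_spec("lasso-logistic", "glmnet",
                     grid = data.frame(C = 10^seq(-3, 3, 1)),
                     fixed = list(alpha = 1))
  f1 <- tune_and_fit(spec, x, co$outcome, seed = 5)
  f2 <- tune_and_fit(spec, x, co$outcome, seed = 5)
  expect_identical(f1$chosen, f2$chosen)
  expect_identical(predict_prob(f1, x), predict_prob(f2, x))
  pr <- predict_prob(f1, x)
  expect_true(all(pr >= 0 & pr <= 1))
  rf <- tune_and_fit(quick_specs()[["random-forest"]], x, co$outcome,
                     seed = 3)
  pr_rf <- predict_prob(rf, x)
  expect_true(all(pr_rf >= 0 & pr_rf <= 1))
})

test_that("linear gene importance is |coef| * sd and zero for zero coef", {
  set.seed(13)
  n <- 300
  x <- cbind(g1 = rnorm(n), g2 = rnorm(n, sd = 4), g3 = rnorm(n))
  y <- rbinom(n, 1, plogis(1.5 * x[, "g1"]))
  # heavy lasso zeroes the null genes
  fit <- tune_and_fit(model_spec("lasso-logistic", "glmnet",
                                 grid = data.frame(C = 0.02),
                                 fixed = list(alpha = 1)), x, y)
  imp <- gene_importance(fit, x, y, c("g1", "g2", "g3"))
  expect_gt(imp[["g1"]], 0)
  # a zero coefficient gives exactly zero importance regardless of scale
  cf <- stats::coef(fit$fit$fit, s = fit$fit$lambda)
  zeroed <- rownames(cf)[-1][as.numeric(cf)[-1] == 0]
  expect_true(all(imp[intersect(zeroed, c("g2", "g3"))] == 0))
  expect_error(gene_importance(fit, x, y, "nope"), "not among")
})

test_that("forest permutation importance separates signal from null genes", {
  set.seed(31)
  n <- 400
  x <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("g", 1:8)))
  y <- rbinom(n, 1, plogis(2 * x[, "g1"]))
  fit <- tune_and_fit(model_spec("random-forest", "rf",
                                 grid = data.frame(min_samples_leaf = 5),
                                 fixed = list(n_estimators = 150)),
                      x, y, seed = 1)
  imp <- gene_importance(fit, x, y, paste0("g", 1:8), B = 5, seed = 1)
  expect_equal(names(which.max(imp)), "g1")
  # out-of-bag predictions are honest: below the memorized in-sample fit
  rf <- fit$fit$fit
  expect_lt(auroc(predict_oob(rf, x), y), auroc(predict(rf, x), y))
  # never-used features sit at (floored) Monte-Carlo zero
  expect_lt(max(imp[paste0("g", 2:8)]), imp[["g1"]] / 3)
  expect_true(all(imp >= 0))
})

test_that("planted strongest gene tops ridge importance across seeds", {
  wins <- 0L
  for (s in 1:10) {
    co <- quick_cohort(n = 250, seed = 100 + s)
    expr <- apply_pipeline(fit_pipeline(default_pipeline_set()[["base"]],
                                        co$ct), co$ct)
    x <- cbind(expr, as.matrix(co$clinical[clinical_covariates()]))
    fit <- tune_and_fit(quick_specs()[["ridge-logistic"]], x, co$outcome,
                        seed = s)
    imp <- gene_importance(fit, x, co$outcome, colnames(expr))
    wins <- wins + (names(which.max(imp)) == co$truth$gene[1])
  }
  expect_gte(wins, 9L)
})

test_that("gbdt fits, predicts probabilities, and learns signal", {
  set.seed(17)
  n <- 300
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("g", 1:5)))
  y <- rbinom(n, 1, plogis(2 * x[, 1]))
  fit <- gbdt_fit(x, y, n_trees = 100, learning_rate = 0.1, max_depth = 3,
                  min_leaf = 5)
  pr <- predict(fit, x)
  expect_true(all(pr >= 0 & pr <= 1))
  x2 <- matrix(rnorm(n * 5), n, 5, dimnames = dimnames(x))
  y2 <- rbinom(n, 1, plogis(2 * x2[, 1]))
  expect_gt(auroc(predict(fit, x2), y2), 0.75)
})
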