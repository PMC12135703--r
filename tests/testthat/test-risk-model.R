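make_final_fixture <- function(n = 200, seed = 3) {
  co <- quick_cohort(n = n, seed = seed)
  panel <- structure(list(genes = co$truth$gene, reference_gene = "KLK3",
                          thresholds = list()), class = "gene_panel")
  list(cohort = co, panel = panel)
}

test_that("fit_final_model is deterministic and volume toggles one covariate", {
  fx <- make_final_fixture()
  pipe <- default_pipeline_set()[["base"]]
  m1 <- fit_final_model(fx$cohort, fx$panel, pipeline = pipe, seed = 2)
  m2 <- fit_final_model(fx$cohort, fx$panel, pipeline = pipe, seed = 2)
  expect_identical(m1$coefficients, m2$coefficients)
  mv <- fit_final_model(fx$cohort, fx$panel, include_volume = TRUE,
                        pipeline = pipe, seed = 2)
  expect_equal(setdiff(mv$clinical_vars, m1$clinical_vars), "volume")
  expect_equal(length(mv$coefficients), length(m1$coefficients) + 1L)
  expect_error(fit_final_model(fx$cohort, c("NOPE"), pipeline = pipe),
               "absent")
  pr <- predict(m1, fx$cohort$ct, fx$cohort$clinical)
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("planted gene coefficients recover the planted sign across seeds", {
  good <- 0L
  for (s in 1:10) {
    fx <- make_final_fixture(n = 250, seed = 400 + s)
    m <- fit_final_model(fx$cohort, fx$panel,
                         pipeline = default_pipeline_set()[["base"]],
                         seed = s)
    cf <- m$coefficients[fx$cohort$truth$gene]
    good <- good + all(sign(cf) == sign(fx$cohort$truth$effect))
  }
  expect_gte(good, 9L)
})

test_that("recalibration recovers identity on training data and preserves AUROC", {
  fx <- make_final_fixture(n = 500, seed = 21)
  m <- fit_final_model(fx$cohort, fx$panel,
                       pipeline = default_pipeline_set()[["base"]], seed = 1)
  # self-calibration identity needs a (nearly) unshrunk model: heavy ridge
  # shrinkage would legitimately be undone by a slope > 1
  m$coefficients[] <- 0
  fitml <- suppressWarnings(stats::glm.fit(
    cbind(1, cbind(apply_pipeline(m$pipeline, fx$cohort$ct)[, m$panel_genes],
                   as.matrix(fx$cohort$clinical[m$clinical_vars]))),
    fx$cohort$outcome, family = stats::binomial()))
  m$coefficients <- stats::setNames(fitml$coefficients,
                                    names(m$coefficients))
  lp <- risk_lp(m, fx$cohort$ct, fx$cohort$clinical)
  m2 <- recalibrate(m, lp, fx$cohort$outcome)
  # maximum-likelihood invariance: refitting intercept and slope of an
  # ML-fitted linear predictor on its own training data returns (0, 1)
  expect_lt(abs(m2$calibration$a - 0), 1e-3)
  expect_lt(abs(m2$calibration$b - 1), 1e-3)
  expect_gt(m2$calibration$b, 0)
  p_before <- predict(m, fx$cohort$ct, fx$cohort$clinical)
  p_after <- predict(m2, fx$cohort$ct, fx$cohort$clinical)
  expect_equal(auroc(p_before, fx$cohort$outcome),
               auroc(p_after, fx$cohort$outcome))
  # locked models refuse recalibration
  locked <- lock_model(m2)
  expect_error(recalibrate(locked, lp, fx$cohort$outcome), "locked")
  expect_error(recalibrate(m, lp, rep(1, length(lp))), "both outcome")
})

test_that("risk model JSON serialization carries panel, coefficients, lock state", {
  fx <- make_final_fixture()
  m <- lock_model(fit_final_model(fx$cohort, fx$panel,
                                  pipeline = default_pipeline_set()[["base"]]))
  path <- withr::local_tempfile(fileext = ".json")
  write_risk_model_json(m, path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(js$panel_genes, m$panel_genes)
  expect_true(js$locked)
  expect_equal(js$calibration$b, 1)
  expect_equal(unlist(js$coefficients), m$coefficients,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("threshold_for_sensitivity maximizes specificity under the floor", {
  # exhaustive-scan oracle on random draws
  set.seed(55)
  for (i in 1:50) {
    n <- sample(30:120, 1)
    s <- round(runif(n), 2)
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    target <- sample(c(0.8, 0.9, 0.95, 1), 1)
    thr <- threshold_for_sensitivity(s, y, target)
    sens <- function(t) mean(s[y == 1] >= t)
    expect_gte(sens(thr), target)
    # any strictly larger candidate threshold violates the floor
    larger <- sort(unique(s[s > thr]))
    if (length(larger)) expect_lt(sens(larger[1]), target)
  }
  # target 1 captures every positive
  s <- c(0.1, 0.4, 0.6, 0.9); y <- c(0, 1, 0, 1)
  expect_equal(threshold_for_sensitivity(s, y, 1), 0.4)
  expect_error(threshold_for_sensitivity(s, y, 0), "target")
})

test_that("confusion identities hold on fuzzed score/label draws", {
  set.seed(77)
  for (i in 1:30) {
    n <- sample(50:200, 1)
    s <- runif(n); y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    thr <- runif(1)
    m <- clinical_metrics(s, y, thr)
    expect_equal(m$tp + m$fn, sum(y == 1))
    expect_equal(m$tn + m$fp, sum(y == 0))
    expect_equal(m$tp + m$fp + m$tn + m$fn, n)
    # brute-force counting
    expect_equal(m$tp, sum(s >= thr & y == 1))
    expect_equal(m$tn, sum(s < thr & y == 0))
    if (m$tp + m$fn > 0)
      expect_equal(m$sensitivity, 100 * m$tp / (m$tp + m$fn))
    if (m$tn + m$fp > 0)
      expect_equal(m$specificity, 100 * m$tn / (m$tn + m$fp))
    if (m$tn + m$fn > 0) expect_equal(m$npv, 100 * m$tn / (m$tn + m$fn))
    if (m$tp + m$fp > 0) expect_equal(m$ppv, 100 * m$tp / (m$tp + m$fp))
  }
  # all calls positive: specificity 0, sensitivity 100
  m <- clinical_metrics(c(0.9, 0.8, 0.7), c(1, 0, 1), threshold = 0)
  expect_equal(m$specificity, 0)
  expect_equal(m$sensitivity, 100)
  # empty denominator flagged undefined, not NaN
  m2 <- clinical_metrics_from_counts(tp = 0, fp = 0, tn = 5, fn = 5)
  expect_true(is.na(m2$ppv))
  expect_true(m2$undefined[["ppv"]])
})

test_that("minimum test tradeoff follows the inverse-gap law", {
  expect_equal(min_test_tradeoff(0.8, 0.78, 0.2)$mtt, 1 / (0.2 * 0.02))
  # doubling the gap halves the tradeoff
  expect_equal(min_test_tradeoff(0.84, 0.80, 0.2)$mtt,
               min_test_tradeoff(0.82, 0.80, 0.2)$mtt / 2)
  # zero gap diverges
  expect_equal(min_test_tradeoff(0.8, 0.8, 0.2)$mtt, Inf)
  # interval endpoints equal pointwise evaluation at gap +/- uncertainty
  tr <- min_test_tradeoff(0.807, 0.784, 0.2, auc_uncertainty = 0.01)
  expect_equal(unname(tr$mtt_range["lower"]),
               mtt_inverse_gap(0.023 + 0.01, 0.2))
  expect_equal(unname(tr$mtt_range["upper"]),
               mtt_inverse_gap(0.023 - 0.01, 0.2))
  # monotone decreasing in gap and in prevalence
  gaps <- seq(0.005, 0.1, by = 0.005)
  mtts <- sapply(gaps, function(g) min_test_tradeoff(0.8 + g, 0.8, 0.2)$mtt)
  expect_true(all(diff(mtts) < 0))
  prevs <- seq(0.05, 0.5, by = 0.05)
  mttp <- sapply(prevs, function(p) min_test_tradeoff(0.82, 0.8, p)$mtt)
  expect_true(all(diff(mttp) < 0))
  expect_error(min_test_tradeoff(0.7, 0.8, 0.2))
})
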