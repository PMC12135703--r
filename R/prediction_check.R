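# derive a child seed (< 2^31) from a base seed and loop indices
derive_seed <- function(seed, i = 0L, j = 0L, k = 0L) {
  as.integer((abs(seed) * 48271 + i * 100003 + j * 1009 + k * 31) %%
               2147483647 + 1)
}

# stratified draw of size n_take from a 0/1 outcome, exact total,
# per-class counts within one sample of proportionality
stratified_take <- function(outcome, rows, n_take) {
  classes <- split(rows, outcome[rows])
  target <- vapply(classes, length, 0L) * n_take / length(rows)
  base <- floor(target)
  extra <- n_take - sum(base)
  if (extra > 0) {
    ord <- order(target - base, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1L
  }
  unlist(mapply(function(cls_rows, k) {
    if (k == 0L) integer() else sample(cls_rows, k)
  }, classes, base, SIMPLIFY = FALSE), use.names = FALSE)
}

#' Repeated stratified development/test splits with inner CV folds
#'
#' Builds `n_repeats` independent outcome-stratified partitions of the
#' cohort into a development and a test set, and within each development
#' set an outcome-stratified `inner_folds`-fold cross-validation
#' assignment. All downstream stages (prediction check, rank tensor,
#' panel-size sweep) reuse one plan so results are comparable across
#' stages.
#'
#' @param n_rows Number of cohort rows.
#' @param outcome Binary 0/1 outcome vector of length `n_rows`.
#' @param n_repeats Number of development/test splits (default 10).
#' @param test_fraction Fraction of rows held out per repeat (default 0.25,
#'   a 3:1 development:test split).
#' @param inner_folds CV folds within each development set (default 4).
#' @param seed Integer seed; the plan is deterministic given it.
#' @return Object of class `split_plan`: list of repeats, each with `dev`
#'   and `test` row indices and a `fold` assignment aligned with `dev`.
#' @export
make_splits <- function(n_rows, outcome, n_repeats = 10L,
                        test_fraction = 0.25, inner_folds = 4L, seed = 1L) {
  outcome <- as.integer(outcome)
  stopifnot(length(outcome) == n_rows, all(outcome %in% c(0L, 1L)),
            test_fraction > 0, test_fraction < 1)
  tab <- table(outcome)
  if (length(tab) < 2L)
    stop("make_splits: both outcome classes must be present")
  if (any(tab < inner_folds))
    stop("make_splits: a class is too small to stratify over ",
         inner_folds, " folds")
  set.seed(seed)
  n_test <- round(n_rows * test_fraction)
  reps <- lapply(seq_len(n_repeats), function(r) {
    test <- sort(stratified_take(outcome, seq_len(n_rows), n_test))
    dev <- setdiff(seq_len(n_rows), test)
    fold <- integer(length(dev))
    for (cls in c(0L, 1L)) {
      pos <- which(outcome[dev] == cls)
      fold[pos] <- sample(rep_len(seq_len(inner_folds), length(pos)))
    }
    list(dev = dev, test = test, fold = fold)
  })
  structure(list(n_repeats = as.integer(n_repeats),
                 inner_folds = as.integer(inner_folds),
                 test_fraction = test_fraction, seed = as.integer(seed),
                 repeats = reps),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf(
    "split_plan: %d repeats, %d inner folds, test fraction %.2f (seed %d)\n",
    x$n_repeats, x$inner_folds, x$test_fraction, x$seed))
  invisible(x)
}

# clinical covariates as a numeric matrix
clinical_matrix <- function(clinical, vars) {
  missing <- setdiff(vars, names(clinical))
  if (length(missing))
    stop("clinical covariate column(s) missing: ",
         paste(missing, collapse = ", "))
  m <- as.matrix(clinical[vars])
  storage.mode(m) <- "double"
  m
}

#' Construct a performance summary
#'
#' Normally produced by [evaluate_grid()]; can also be built directly from a
#' per-cell table (columns `pipeline`, `model`, `mean_auroc`, optionally
#' other metrics), e.g. to apply [prediction_filter()] to published
#' numbers.
#'
#' @param cells Data.frame with one row per (pipeline, model) cell.
#' @param folds Optional fold-level records behind the cells.
#' @return Object of class `perf_summary`.
#' @export
perf_summary <- function(cells, folds = NULL) {
  stopifnot(all(c("pipeline", "model", "mean_auroc") %in% names(cells)))
  structure(list(cells = cells, folds = folds), class = "perf_summary")
}

#' @export
print.perf_summary <- function(x, ...) {
  cat(sprintf("perf_summary: %d (pipeline, model) cells\n", nrow(x$cells)))
  print(utils::head(x$cells, 12))
  invisible(x)
}

#' Evaluate every (pipeline, model) cell by repeated cross-validation
#'
#' For each preprocessing pipeline, model spec, development/test repeat, and
#' inner CV fold: the pipeline is fitted on the training folds only, the
#' model is tuned and fitted on the preprocessed training folds (all 54
#' genes plus clinical covariates), and AUROC/AUPRC/accuracy are scored on
#' the held-out fold. Cell summaries average the fold-level values;
#' degenerate folds (a single outcome class) are skipped with a warning and
#' excluded from denominators.
#'
#' @param cohort List with `ct` ([ct_matrix()]), `clinical` (data.frame) and
#'   `outcome` (0/1), e.g. a [simulate_cohort()] result.
#' @param pipelines Named list of [pcs_pipeline()]s.
#' @param specs Named list of available [model_spec()]s.
#' @param plan A [make_splits()] plan.
#' @param clinical_vars Clinical covariate columns (default the six standard
#'   ones).
#' @param tune_folds Inner tuning folds for [tune_and_fit()] (default 5).
#' @param seed Base seed for model fits.
#' @return A [perf_summary()] with fold-level records (`$folds`), per-cell
#'   means with inner 95% AUROC quantiles (`$cells`), and the per-model
#'   cross-pipeline variation table (`$model_variation`: range of pipeline
#'   means and gap to the best model's grand mean).
#' @export
evaluate_grid <- function(cohort, pipelines, specs, plan,
                          clinical_vars = clinical_covariates(),
                          tune_folds = 5L, seed = 1L) {
  stopifnot(inherits(plan, "split_plan"), length(pipelines) >= 1,
            length(specs) >= 1)
  y <- as.integer(cohort$outcome)
  clin <- clinical_matrix(cohort$clinical, clinical_vars)
  gene_names <- genes(cohort$ct, include_reference = FALSE)
  recs <- list()
  for (pname in names(pipelines)) {
    for (r in seq_len(plan$n_repeats)) {
      rep_r <- plan$repeats[[r]]
      for (f in seq_len(plan$inner_folds)) {
        tr_rows <- rep_r$dev[rep_r$fold != f]
        va_rows <- rep_r$dev[rep_r$fold == f]
        if (length(unique(y[va_rows])) < 2L) {
          warning("evaluate_grid: degenerate fold skipped (pipeline ",
                  pname, ", repeat ", r, ", fold ", f, ")")
          next
        }
        pp <- preprocess_split(pipelines[[pname]],
                               ct_subset(cohort$ct, tr_rows),
                               ct_subset(cohort$ct, va_rows))
        x_tr <- cbind(pp$dev, clin[tr_rows, , drop = FALSE])
        x_va <- cbind(pp$new, clin[va_rows, , drop = FALSE])
        for (sname in names(specs)) {
          fit <- tune_and_fit(specs[[sname]], x_tr, y[tr_rows],
                              seed = derive_seed(seed, r, f,
                                                 match(sname, names(specs))),
                              folds = tune_folds)
          pr <- predict_prob(fit, x_va)
          recs[[length(recs) + 1L]] <- data.frame(
            pipeline = pname, model = sname, rep = r, fold = f,
            auroc = auroc(pr, y[va_rows]), auprc = auprc(pr, y[va_rows]),
            accuracy = accuracy(pr, y[va_rows]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  folds_df <- do.call(rbind, recs)
  cells <- do.call(rbind, lapply(
    split(folds_df, folds_df[c("pipeline", "model")], drop = TRUE),
    function(d) data.frame(
      pipeline = d$pipeline[1], model = d$model[1],
      mean_auroc = mean(d$auroc), mean_auprc = mean(d$auprc),
      mean_accuracy = mean(d$accuracy),
      auroc_q025 = unname(stats::quantile(d$auroc, 0.025)),
      auroc_q975 = unname(stats::quantile(d$auroc, 0.975)),
      n_evals = nrow(d), stringsAsFactors = FALSE)))
  rownames(cells) <- NULL
  out <- perf_summary(cells, folds_df)
  out$model_variation <- model_variation(cells)
  out
}

# per-model cross-pipeline range and gap to the best model
model_variation <- function(cells) {
  grand <- tapply(cells$mean_auroc, cells$model, mean)
  rng <- tapply(cells$mean_auroc, cells$model,
                function(v) max(v) - min(v))
  data.frame(model = names(grand), grand_mean_auroc = as.numeric(grand),
             pipeline_range = as.numeric(rng),
             gap_to_best = max(grand) - as.numeric(grand),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter models against a reference model's prediction performance
#'
#' A model passes the prediction check if its grand-mean AUROC across
#' pipelines is at least the reference model's grand mean, or if at least
#' one of its per-pipeline mean AUROCs exceeds the reference grand mean -
#' i.e. a model is kept whenever preprocessing uncertainty is larger than
#' its deficit to the reference. The reference model is always kept.
#'
#' @param perf A [perf_summary()] (or a data.frame with columns `pipeline`,
#'   `model`, `mean_auroc`).
#' @param reference_model Name of the reference model (default
#'   `"logistic"`).
#' @return List with `kept` and `dropped` model-name vectors and a `report`
#'   data.frame (per model: grand mean, best pipeline mean, decision,
#'   reason).
#' @export
prediction_filter <- function(perf, reference_model = "logistic") {
  cells <- if (inherits(perf, "perf_summary")) perf$cells else perf
  stopifnot(all(c("pipeline", "model", "mean_auroc") %in% names(cells)))
  if (!reference_model %in% cells$model)
    stop("prediction_filter: reference model '", reference_model,
         "' not present")
  grand <- tapply(cells$mean_auroc, cells$model, mean)
  best_pipe <- tapply(cells$mean_auroc, cells$model, max)
  ref <- grand[[reference_model]]
  models <- names(grand)
  keep_grand <- grand >= ref
  keep_pipe <- best_pipe > ref
  kept <- keep_grand | keep_pipe | models == reference_model
  reason <- ifelse(models == reference_model, "reference model",
            ifelse(keep_grand, "grand-mean AUROC >= reference",
            ifelse(keep_pipe, "a pipeline mean exceeds reference grand mean",
                   "all pipeline means below reference grand mean")))
  report <- data.frame(model = models, grand_mean_auroc = as.numeric(grand),
                       best_pipeline_auroc = as.numeric(best_pipe),
                       reference_auroc = ref, kept = as.logical(kept),
                       reason = reason, stringsAsFactors = FALSE,
                       row.names = NULL)
  list(kept = models[kept], dropped = models[!kept], report = report)
}

#' Write a performance summary as tidy TSV
#' @param perf A [perf_summary()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_perf_tsv <- function(perf, path) {
  stopifnot(inherits(perf, "perf_summary"))
  long <- do.call(rbind, lapply(
    c(auroc = "mean_auroc", auprc = "mean_auprc",
      accuracy = "mean_accuracy"),
    function(col) if (col %in% names(perf$cells))
      data.frame(pipeline = perf$cells$pipeline, model = perf$cells$model,
                 metric = sub("mean_", "", col), mean = perf$cells[[col]],
                 q025 = if (col == "mean_auroc") perf$cells$auroc_q025 else NA,
                 q975 = if (col == "mean_auroc") perf$cells$auroc_q975 else NA,
                 stringsAsFactors = FALSE)))
  utils::write.table(long, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
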