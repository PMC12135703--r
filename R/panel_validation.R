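#' Default panel-size grid for the internal validation sweep
#' @param n_genes Total candidate genes (default 54).
#' @return Integer vector of panel sizes.
#' @export
default_k_grid <- function(n_genes = 54L) {
  k <- c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 10L, 12L, 15L, 17L, 20L, 25L, 30L,
         40L, 54L)
  unique(pmin(k[k <= n_genes], n_genes))
}

# ranking for one repeat from its tensor slice only (no pooling across
# repeats, so held-out test rows never influence the ranking they evaluate)
repeat_ranking <- function(tensor, mode, r, p = NULL, m = NULL) {
  arr <- unclass(tensor)
  sl <- switch(mode,
    pcs_ensembled = apply(arr[, , r, , drop = FALSE], 4, mean, na.rm = TRUE),
    model_ensembled = apply(arr[p, , r, , drop = FALSE], 4, mean,
                            na.rm = TRUE),
    model_specific = arr[p, m, r, ])
  stats::setNames(as.numeric(sl), dimnames(arr)[[4]])
}

#' Internal validation: sweep panel size and ranking mode
#'
#' For each development/test repeat, pipeline, prediction-checked model,
#' ranking mode, and panel size k: take the top-k genes of that repeat's
#' ranking (derived from development rows only), train the model on the
#' repeat's preprocessed development rows using those genes plus the
#' clinical covariates, and score the held-out test rows. Results are
#' averaged over repeats. `k = 0` is permitted and gives the clinical-only
#' baseline.
#'
#' @inheritParams evaluate_grid
#' @param tensor The [build_rank_tensor()] result for the same plan.
#' @param specs Named list of kept [model_spec()]s to retrain.
#' @param k_grid Panel sizes to sweep (default [default_k_grid()]).
#' @param modes Ranking modes to compare (default all three).
#' @return Object of class `sweep_result`: data.frame with per
#'   (pipeline, model, mode, k) mean test AUROC/AUPRC/accuracy over
#'   repeats.
#' @export
panel_size_sweep <- function(cohort, plan, tensor, specs, pipelines,
                             k_grid = NULL,
                             modes = c("pcs_ensembled", "model_ensembled",
                                       "model_specific"),
                             clinical_vars = clinical_covariates(),
                             tune_folds = 5L, seed = 1L) {
  stopifnot(inherits(plan, "split_plan"), inherits(tensor, "rank_tensor"))
  y <- as.integer(cohort$outcome)
  clin <- clinical_matrix(cohort$clinical, clinical_vars)
  gene_names <- genes(cohort$ct, include_reference = FALSE)
  if (is.null(k_grid)) k_grid <- default_k_grid(length(gene_names))
  if (any(k_grid > length(gene_names)))
    stop("panel_size_sweep: k exceeds the number of candidate genes")
  modes <- match.arg(modes, several.ok = TRUE)
  recs <- list()
  for (p in seq_along(pipelines)) {
    for (r in seq_len(plan$n_repeats)) {
      rep_r <- plan$repeats[[r]]
      pp <- preprocess_split(pipelines[[p]],
                             ct_subset(cohort$ct, rep_r$dev),
                             ct_subset(cohort$ct, rep_r$test))
      for (m in seq_along(specs)) {
        for (mode in modes) {
          rk <- repeat_ranking(tensor, mode, r, p, m)
          ord <- names(sort(rk))
          for (k in k_grid) {
            top <- if (k > 0) ord[seq_len(k)] else character()
            x_dev <- cbind(pp$dev[, top, drop = FALSE],
                           clin[rep_r$dev, , drop = FALSE])
            x_te <- cbind(pp$new[, top, drop = FALSE],
                          clin[rep_r$test, , drop = FALSE])
            fit <- tune_and_fit(specs[[m]], x_dev, y[rep_r$dev],
                                seed = derive_seed(seed, p, m, r),
                                folds = tune_folds)
            pr <- predict_prob(fit, x_te)
            recs[[length(recs) + 1L]] <- data.frame(
              pipeline = names(pipelines)[p], model = names(specs)[m],
              mode = mode, k = k, rep = r,
              auroc = auroc(pr, y[rep_r$test]),
              auprc = auprc(pr, y[rep_r$test]),
              accuracy = accuracy(pr, y[rep_r$test]),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  per_rep <- do.call(rbind, recs)
  agg <- do.call(rbind, lapply(
    split(per_rep, per_rep[c("pipeline", "model", "mode", "k")], drop = TRUE),
    function(d) data.frame(
      pipeline = d$pipeline[1], model = d$model[1], mode = d$mode[1],
      k = d$k[1], mean_auroc = mean(d$auroc), mean_auprc = mean(d$auprc),
      mean_accuracy = mean(d$accuracy), n_reps = nrow(d),
      stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  attr(agg, "per_rep") <- per_rep
  class(agg) <- c("sweep_result", "data.frame")
  agg
}

#' Summarize the panel-size sweep
#'
#' Per (pipeline, model, mode): the AUROC-maximizing k and its mean AUROC.
#' Per (model, mode, k): the range of mean AUROCs across pipelines (the
#' preprocessing-robustness diagnostic) and each cell's drop relative to
#' its best k.
#'
#' @param sweep A [panel_size_sweep()] result.
#' @return List with `best_k` (argmax table), `k_ranges` (cross-pipeline
#'   min/max/range per k), and `detail` (the sweep rows plus
#'   `drop_from_best`).
#' @export
best_k_report <- function(sweep) {
  stopifnot(inherits(sweep, "data.frame"), nrow(sweep) > 0)
  best_k <- do.call(rbind, lapply(
    split(sweep, sweep[c("pipeline", "model", "mode")], drop = TRUE),
    function(d) {
      i <- which.max(d$mean_auroc)
      data.frame(pipeline = d$pipeline[1], model = d$model[1],
                 mode = d$mode[1], best_k = d$k[i],
                 best_auroc = d$mean_auroc[i], stringsAsFactors = FALSE)
    }))
  rownames(best_k) <- NULL
  k_ranges <- do.call(rbind, lapply(
    split(sweep, sweep[c("model", "mode", "k")], drop = TRUE),
    function(d) data.frame(
      model = d$model[1], mode = d$mode[1], k = d$k[1],
      min_auroc = min(d$mean_auroc), max_auroc = max(d$mean_auroc),
      range = max(d$mean_auroc) - min(d$mean_auroc),
      stringsAsFactors = FALSE)))
  rownames(k_ranges) <- NULL
  detail <- as.data.frame(sweep)
  key <- interaction(detail$pipeline, detail$model, detail$mode, drop = TRUE)
  detail$drop_from_best <- stats::ave(detail$mean_auroc, key,
                                      FUN = function(v) max(v) - v)
  list(best_k = best_k, k_ranges = k_ranges, detail = detail)
}

#' Write the sweep result as tidy TSV
#' @param sweep A [panel_size_sweep()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_tsv <- function(sweep, path) {
  utils::write.table(as.data.frame(sweep), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
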