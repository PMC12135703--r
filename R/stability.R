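#' Convert importance scores to gene ranks
#'
#' Descending importance maps to ascending rank (rank 1 = most important);
#' exact ties share the average of the tied positions, so every rank vector
#' sums to G(G+1)/2.
#'
#' @param imp Named finite numeric importance vector.
#' @return Named rank vector over the same genes.
#' @export
ranks_from_importance <- function(imp) {
  if (!length(imp)) stop("ranks_from_importance: empty importance vector")
  if (any(!is.finite(imp))) stop("ranks_from_importance: non-finite scores")
  rank(-imp, ties.method = "average")
}

#' Build the gene-rank tensor over all perturbation combinations
#'
#' For every (preprocessing pipeline, prediction-checked model,
#' development/test repeat) combination: the pipeline is fitted on that
#' repeat's development rows, the model is tuned and fitted there (genes +
#' clinical covariates), gene importances are extracted, and converted to
#' ranks. With 4 pipelines, 6 kept models, and 10 repeats this yields the
#' full 240-combination rank tensor.
#'
#' @inheritParams evaluate_grid
#' @param specs Named list of kept (prediction-checked) [model_spec()]s.
#' @param importance_B Permutation repeats for tree-model importance.
#' @return Object of class `rank_tensor`: a 4-d array with dimensions
#'   (pipeline, model, repeat, gene). Failed fits are recorded in
#'   `attr(, "failed")` and left as `NA` slices, excluded from all
#'   downstream denominators.
#' @export
build_rank_tensor <- function(cohort, specs, pipelines, plan,
                              clinical_vars = clinical_covariates(),
                              tune_folds = 5L, importance_B = 5L,
                              seed = 1L) {
  stopifnot(inherits(plan, "split_plan"), length(specs) >= 1)
  y <- as.integer(cohort$outcome)
  clin <- clinical_matrix(cohort$clinical, clinical_vars)
  gene_names <- genes(cohort$ct, include_reference = FALSE)
  tensor <- array(
    NA_real_,
    dim = c(length(pipelines), length(specs), plan$n_repeats,
            length(gene_names)),
    dimnames = list(pipeline = names(pipelines), model = names(specs),
                    rep = NULL, gene = gene_names))
  failed <- list()
  for (p in seq_along(pipelines)) {
    for (r in seq_len(plan$n_repeats)) {
      dev <- plan$repeats[[r]]$dev
      pp <- preprocess_split(pipelines[[p]], ct_subset(cohort$ct, dev))
      x_dev <- cbind(pp$dev, clin[dev, , drop = FALSE])
      for (m in seq_along(specs)) {
        res <- tryCatch({
          fit <- tune_and_fit(specs[[m]], x_dev, y[dev],
                              seed = derive_seed(seed, p, m, r),
                              folds = tune_folds)
          imp <- gene_importance(fit, x_dev, y[dev], gene_names,
                                 B = importance_B,
                                 seed = derive_seed(seed, p, m, r + 1000L))
          ranks_from_importance(imp)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failed[[length(failed) + 1L]] <- data.frame(
            pipeline = names(pipelines)[p], model = names(specs)[m],
            rep = r, message = conditionMessage(res),
            stringsAsFactors = FALSE)
          warning("build_rank_tensor: fit failed (", names(pipelines)[p],
                  ", ", names(specs)[m], ", repeat ", r, "): ",
                  conditionMessage(res))
        } else {
          tensor[p, m, r, ] <- res[gene_names]
        }
      }
    }
  }
  attr(tensor, "failed") <- if (length(failed)) do.call(rbind, failed)
                            else NULL
  class(tensor) <- c("rank_tensor", "array")
  tensor
}

#' @export
print.rank_tensor <- function(x, ...) {
  d <- dim(x)
  nfail <- if (is.null(attr(x, "failed"))) 0L else nrow(attr(x, "failed"))
  cat(sprintf(
    "rank_tensor: %d pipelines x %d models x %d repeats x %d genes (%d failed fits)\n",
    d[1], d[2], d[3], d[4], nfail))
  invisible(x)
}

# combination-major matrix view: rows = (pipeline, model, repeat), cols = genes
tensor_combos <- function(tensor) {
  d <- dim(tensor)
  m <- matrix(aperm(unclass(tensor), c(3, 2, 1, 4)), nrow = d[1] * d[2] * d[3],
              ncol = d[4])
  colnames(m) <- dimnames(tensor)[[4]]
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Aggregate gene ranks across perturbation strata
#'
#' `pcs_ensembled` averages ranks over every (pipeline, model, repeat)
#' combination; `model_ensembled` averages over models and repeats, giving
#' one ranking per pipeline; `model_specific` averages over repeats only,
#' giving one ranking per (pipeline, model).
#'
#' @param tensor A [build_rank_tensor()] result.
#' @param mode One of `"pcs_ensembled"`, `"model_ensembled"`,
#'   `"model_specific"`.
#' @return Data.frame with a `gene` and `mean_rank` column plus the stratum
#'   columns the mode retains, sorted by stratum then mean rank.
#' @export
aggregate_ranks <- function(tensor, mode = c("pcs_ensembled",
                                             "model_ensembled",
                                             "model_specific")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tensor, "rank_tensor"))
  arr <- unclass(tensor)
  dn <- dimnames(arr)
  if (mode == "pcs_ensembled") {
    mr <- apply(arr, 4, mean, na.rm = TRUE)
    out <- data.frame(gene = dn[[4]], mean_rank = as.numeric(mr),
                      stringsAsFactors = FALSE)
    out[order(out$mean_rank), , drop = FALSE]
  } else if (mode == "model_ensembled") {
    mr <- apply(arr, c(1, 4), mean, na.rm = TRUE)
    out <- data.frame(
      pipeline = rep(dn[[1]], times = length(dn[[4]])),
      gene = rep(dn[[4]], each = length(dn[[1]])),
      mean_rank = as.numeric(mr), stringsAsFactors = FALSE)
    out[order(out$pipeline, out$mean_rank), , drop = FALSE]
  } else {
    mr <- apply(arr, c(1, 2, 4), mean, na.rm = TRUE)
    out <- expand.grid(pipeline = dn[[1]], model = dn[[2]], gene = dn[[4]],
                       stringsAsFactors = FALSE)
    out$mean_rank <- as.numeric(mr)
    out[order(out$pipeline, out$model, out$mean_rank), , drop = FALSE]
  }
}

#' Per-gene stability metrics over the rank tensor
#'
#' For each gene: the mean rank, the population standard deviation of its
#' rank across combinations, and for each m in `top_m` the proportion of
#' combinations in which the gene ranked in the top m.
#'
#' @param tensor A [build_rank_tensor()] result.
#' @param top_m Rank cutoffs for the proportion metrics (default 5, 10, 17).
#' @return Data.frame (class `rank_summary`) with columns `gene`,
#'   `mean_rank`, `sd_rank`, and `prop_top<m>`, sorted by mean rank.
#' @export
stability_summary <- function(tensor, top_m = c(5, 10, 17)) {
  stopifnot(inherits(tensor, "rank_tensor"))
  cm <- tensor_combos(tensor)
  if (!nrow(cm)) stop("stability_summary: no successful combinations")
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  out <- data.frame(
    gene = colnames(cm),
    mean_rank = colMeans(cm),
    sd_rank = apply(cm, 2, pop_sd),
    stringsAsFactors = FALSE, row.names = NULL)
  for (m in top_m)
    out[[paste0("prop_top", m)]] <- colMeans(cm <= m)
  out <- out[order(out$mean_rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rank_summary", "data.frame")
  out
}

#' Select the stable gene panel
#'
#' Keeps genes with mean rank strictly below `max_mean_rank` and top-10
#' proportion strictly above `min_prop_top10`, ordered by mean rank, and
#' appends the reference gene for assay accounting (a k-gene covariate
#' panel requires measuring k+1 genes). When the next-best gene misses
#' exactly one criterion by at most `slack`, a `panel+next` variant
#' (`$extended`) is also emitted, mirroring the borderline-gene case.
#'
#' @param summary A [stability_summary()] result.
#' @param max_mean_rank Mean-rank ceiling (strict; default 10).
#' @param min_prop_top10 Top-10 proportion floor (strict; default 0.7).
#' @param reference_gene Reference gene to append (default `"KLK3"`).
#' @param slack Tolerance for the borderline next gene (default 0.05 on the
#'   proportion scale and the same value in rank units).
#' @return Object of class `gene_panel`: `genes` (ordered covariate genes),
#'   `reference_gene`, `thresholds`, and optionally `extended` (the
#'   panel-plus-borderline-gene variant).
#' @export
select_panel <- function(summary, max_mean_rank = 10, min_prop_top10 = 0.7,
                         reference_gene = "KLK3", slack = 0.05) {
  stopifnot(inherits(summary, "data.frame"),
            "prop_top10" %in% names(summary),
            max_mean_rank > 0, min_prop_top10 >= 0, min_prop_top10 < 1)
  ok <- summary$mean_rank < max_mean_rank &
        summary$prop_top10 > min_prop_top10
  if (!any(ok))
    stop("select_panel: no gene met the stability criteria (mean rank < ",
         max_mean_rank, " and prop_top10 > ", min_prop_top10, ")")
  sel <- summary[ok, , drop = FALSE]
  sel <- sel[order(sel$mean_rank), , drop = FALSE]
  panel <- structure(
    list(genes = sel$gene, reference_gene = reference_gene,
         thresholds = list(max_mean_rank = max_mean_rank,
                           min_prop_top10 = min_prop_top10)),
    class = "gene_panel")
  rest <- summary[!summary$gene %in% sel$gene, , drop = FALSE]
  rest <- rest[order(rest$mean_rank), , drop = FALSE]
  if (nrow(rest)) {
    nxt <- rest[1L, ]
    miss_rank <- nxt$mean_rank - max_mean_rank
    miss_prop <- min_prop_top10 - nxt$prop_top10
    near <- sum(c(miss_rank > 0, miss_prop > 0) ) == 1L &&
      max(miss_rank, 0) <= slack && max(miss_prop, 0) <= slack
    if (near) {
      ext <- panel
      ext$genes <- c(panel$genes, nxt$gene)
      ext$borderline <- nxt$gene
      panel$extended <- ext
    }
  }
  panel
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("gene_panel: %d covariate genes + reference %s (%d measured)\n  %s\n",
              length(x$genes), x$reference_gene, length(x$genes) + 1L,
              paste(x$genes, collapse = ", ")))
  if (!is.null(x$extended))
    cat("  borderline variant adds:", x$extended$borderline, "\n")
  invisible(x)
}

#' Number of genes the assay must measure for a panel
#' @param panel A [select_panel()] result.
#' @return Covariate genes + 1 reference gene.
#' @export
panel_size <- function(panel) length(panel$genes) + 1L

#' Write the stability summary as TSV
#' @param summary A [stability_summary()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rank_summary_tsv <- function(summary, path) {
  utils::write.table(as.data.frame(summary), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the per-(pipeline, model) mean-rank heatmap table as TSV
#'
#' The granular view of the rank tensor: mean gene rank per preprocessing
#' pipeline and model, averaged over repeats.
#'
#' @param tensor A [build_rank_tensor()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rank_heatmap_tsv <- function(tensor, path) {
  utils::write.table(aggregate_ranks(tensor, "model_specific"), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
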