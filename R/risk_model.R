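#' Fit the final locked-panel ridge risk model
#'
#' Trains a ridge-penalized logistic regression on the full supplied cohort
#' using the panel genes (delta-Ct expression under the given pipeline,
#' fitted on the same cohort) plus the clinical covariates, with the ridge
#' strength chosen by stratified 5-fold CV over the standard C grid. The
#' model starts with identity recalibration (a = 0, b = 1) and can be
#' recalibrated to a new cohort's prevalence with [recalibrate()] and
#' frozen with [lock_model()].
#'
#' @param cohort List with `ct`, `clinical`, `outcome`.
#' @param panel A [select_panel()] result (or character vector of genes).
#' @param clinical_vars Clinical covariates (default the six standard
#'   ones).
#' @param include_volume Add prostate volume as a covariate (the "+" model
#'   variant)?
#' @param pipeline The [pcs_pipeline()] used to preprocess Ct data.
#' @param seed Seed for the CV tuning.
#' @return Object of class `risk_model`.
#' @export
fit_final_model <- function(cohort, panel,
                            clinical_vars = clinical_covariates(),
                            include_volume = FALSE, pipeline, seed = 1L) {
  genes_sel <- if (inherits(panel, "gene_panel")) panel$genes else panel
  vars <- c(clinical_vars, if (include_volume) "volume")
  fitted_pipe <- fit_pipeline(pipeline, cohort$ct)
  expr <- apply_pipeline(fitted_pipe, cohort$ct)
  missing <- setdiff(genes_sel, colnames(expr))
  if (length(missing))
    stop("fit_final_model: panel gene(s) absent from cohort: ",
         paste(missing, collapse = ", "))
  x <- cbind(expr[, genes_sel, drop = FALSE],
             clinical_matrix(cohort$clinical, vars))
  spec <- model_spec("ridge-logistic", "glmnet",
                     grid = data.frame(C = c_grid()),
                     fixed = list(alpha = 0))
  fit <- tune_and_fit(spec, x, as.integer(cohort$outcome), seed = seed)
  cf <- stats::coef(fit$fit$fit, s = fit$fit$lambda, exact = FALSE)
  coefs <- stats::setNames(as.numeric(cf), rownames(cf))
  structure(
    list(panel_genes = genes_sel,
         reference_gene = if (inherits(panel, "gene_panel"))
           panel$reference_gene else cohort$ct$reference_gene,
         clinical_vars = vars, include_volume = include_volume,
         pipeline = fitted_pipe, coefficients = coefs,
         chosen = fit$chosen, features = fit$features,
         calibration = list(a = 0, b = 1), locked = FALSE),
    class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf(
    "risk_model: %d panel genes + %d clinical covariates%s; calibration a=%.3f b=%.3f%s\n",
    length(x$panel_genes), length(x$clinical_vars),
    if (x$include_volume) " (incl. volume)" else "",
    x$calibration$a, x$calibration$b,
    if (x$locked) " [locked]" else ""))
  invisible(x)
}

#' Linear predictor (log-odds) of a risk model on new data
#'
#' Applies the model's fitted preprocessing pipeline to the Ct matrix and
#' evaluates the stored ridge coefficients. The recalibration parameters
#' are not applied here; see [predict.risk_model()].
#'
#' @param model A [fit_final_model()] result.
#' @param ct A [ct_matrix()] containing the panel and reference genes.
#' @param clinical Clinical table with the model's covariate columns.
#' @return Numeric linear predictors.
#' @export
risk_lp <- function(model, ct, clinical) {
  stopifnot(inherits(model, "risk_model"))
  expr <- apply_pipeline(model$pipeline, ct)
  x <- cbind(expr[, model$panel_genes, drop = FALSE],
             clinical_matrix(clinical, model$clinical_vars))
  beta <- model$coefficients
  drop(cbind(1, x[, names(beta)[-1], drop = FALSE]) %*% beta)
}

#' Predicted high-grade risk from a risk model
#'
#' @param object A `risk_model`.
#' @param ct A [ct_matrix()].
#' @param clinical Clinical table.
#' @param ... Unused.
#' @return Recalibrated probabilities `plogis(a + b * lp)`.
#' @export
predict.risk_model <- function(object, ct, clinical, ...) {
  lp <- risk_lp(object, ct, clinical)
  stats::plogis(object$calibration$a + object$calibration$b * lp)
}

#' Logistic recalibration of a fitted risk model
#'
#' Fits `logit(p) = a + b * lp` by maximum likelihood on the supplied
#' sample (typically a new cohort with a different outcome prevalence) and
#' stores `(a, b)` in the model. The original ridge coefficients are
#' untouched, and because `b > 0` in any sane recalibration, discrimination
#' (AUROC) is unchanged.
#'
#' @param model A [fit_final_model()] result (not yet locked).
#' @param linear_predictors Model linear predictors on the recalibration
#'   sample (see [risk_lp()]).
#' @param outcomes Binary 0/1 outcomes, both classes present.
#' @return The updated `risk_model`; the fitted parameters are in
#'   `$calibration` (list with `a`, `b`).
#' @export
recalibrate <- function(model, linear_predictors, outcomes) {
  stopifnot(inherits(model, "risk_model"))
  if (model$locked)
    stop("recalibrate: model is locked")
  outcomes <- as.integer(outcomes)
  stopifnot(length(linear_predictors) == length(outcomes),
            all(outcomes %in% c(0L, 1L)))
  if (length(unique(outcomes)) < 2L)
    stop("recalibrate: both outcome classes required")
  fit <- suppressWarnings(
    stats::glm(outcomes ~ linear_predictors, family = stats::binomial()))
  ab <- stats::coef(fit)
  if (!fit$converged || any(!is.finite(ab)) || abs(ab[2]) > 1e3)
    stop("recalibrate: non-finite maximum likelihood estimate (separation?)")
  model$calibration <- list(a = unname(ab[1]), b = unname(ab[2]))
  model
}

#' Lock a risk model prior to external validation
#'
#' A locked model's coefficients and calibration are frozen; recalibration
#' attempts error.
#'
#' @param model A `risk_model`.
#' @return The locked model.
#' @export
lock_model <- function(model) {
  stopifnot(inherits(model, "risk_model"))
  model$locked <- TRUE
  model
}

#' Serialize a risk model to JSON
#' @param model A `risk_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_risk_model_json <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  jsonlite::write_json(
    list(panel_genes = model$panel_genes,
         reference_gene = model$reference_gene,
         clinical_vars = model$clinical_vars,
         include_volume = model$include_volume,
         pipeline = model$pipeline$name,
         coefficients = as.list(model$coefficients),
         chosen = model$chosen,
         calibration = model$calibration, locked = model$locked),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Sensitivity-anchored decision threshold
#'
#' Returns the largest threshold whose sensitivity (with the convention
#' that scores at or above the threshold are called positive) is at least
#' `target` - i.e. the operating point maximizing specificity subject to
#' the sensitivity floor. Deterministic: the threshold is the
#' `ceiling(target * n_pos)`-th largest positive-class score.
#'
#' @param scores Risk scores.
#' @param labels Binary 0/1 outcomes, both classes present.
#' @param target Sensitivity floor in (0, 1\] (default 0.95).
#' @return The threshold.
#' @export
threshold_for_sensitivity <- function(scores, labels, target = 0.95) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), target > 0, target <= 1)
  pos <- sort(scores[labels == 1L], decreasing = TRUE)
  if (!length(pos) || all(labels == 1L))
    stop("threshold_for_sensitivity: both outcome classes required")
  need <- ceiling(target * length(pos) - 1e-9)
  pos[need]
}

new_threshold_metrics <- function(tp, fp, tn, fn, threshold) {
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  per1000 <- function(num, den) if (den == 0) NA_integer_
             else as.integer(round(1000 * num / den))
  structure(
    list(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = pct(tp, tp + fn), specificity = pct(tn, tn + fp),
         npv = pct(tn, tn + fn), ppv = pct(tp, tp + fp),
         biopsies_avoided_per_1000 = per1000(tn, tn + fp),
         cancers_missed_per_1000 = per1000(fn, fn + tp),
         undefined = c(sensitivity = tp + fn == 0,
                       specificity = tn + fp == 0,
                       npv = tn + fn == 0, ppv = tp + fp == 0)),
    class = "threshold_metrics")
}

#' Confusion-matrix clinical metrics at a threshold
#'
#' Counts use the score-at-or-above-threshold-is-positive convention.
#' Percentages follow the standard definitions: sensitivity TP/(TP+FN),
#' specificity TN/(TN+FP), NPV TN/(TN+FN), PPV TP/(TP+FP). "Biopsies
#' avoided per 1000 patients" is `round(1000 * TN/(TN+FP))` (patients
#' without high-grade cancer spared a biopsy under rule-out testing);
#' "cancers missed per 1000" is `round(1000 * FN/(FN+TP))` (high-grade
#' patients below the threshold). Empty denominators yield `NA` flagged in
#' `$undefined` rather than propagating NaN.
#'
#' @param scores Risk scores.
#' @param labels Binary 0/1 outcomes.
#' @param threshold Finite decision threshold.
#' @return Object of class `threshold_metrics`.
#' @export
clinical_metrics <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), is.finite(threshold))
  call_pos <- scores >= threshold
  new_threshold_metrics(
    tp = sum(call_pos & labels == 1L), fp = sum(call_pos & labels == 0L),
    tn = sum(!call_pos & labels == 0L), fn = sum(!call_pos & labels == 1L),
    threshold = threshold)
}

#' Clinical metrics directly from confusion counts
#'
#' @param tp,fp,tn,fn Confusion-matrix counts.
#' @return Object of class `threshold_metrics` (threshold `NA`).
#' @export
clinical_metrics_from_counts <- function(tp, fp, tn, fn) {
  new_threshold_metrics(tp, fp, tn, fn, threshold = NA_real_)
}

#' @export
print.threshold_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("threshold_metrics (threshold %s):\n",
           "  TP %d  FP %d  TN %d  FN %d\n",
           "  sensitivity %.1f%%  specificity %.1f%%  NPV %.1f%%  PPV %.1f%%\n",
           "  biopsies avoided per 1000: %d  cancers missed per 1000: %d\n"),
    ifelse(is.na(x$threshold), "from counts", format(x$threshold, digits = 4)),
    x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity, x$npv, x$ppv,
    x$biopsies_avoided_per_1000, x$cancers_missed_per_1000))
  invisible(x)
}

#' @export
as.data.frame.threshold_metrics <- function(x, ...) {
  data.frame(threshold = x$threshold, tp = x$tp, fp = x$fp, tn = x$tn,
             fn = x$fn, sensitivity = x$sensitivity,
             specificity = x$specificity, npv = x$npv, ppv = x$ppv,
             biopsies_avoided_per_1000 = x$biopsies_avoided_per_1000,
             cancers_missed_per_1000 = x$cancers_missed_per_1000)
}

#' Inverse-gap minimum-test-tradeoff formula
#'
#' Default approximation: the minimum number of additional-marker test sets
#' per true positive scales inversely with the prevalence-weighted AUROC
#' gain, `1 / (prevalence * gap)`.
#'
#' @param gap AUROC difference (larger minus smaller panel).
#' @param prevalence Outcome prevalence in (0, 1).
#' @return The tradeoff; `Inf` for a non-positive gap.
#' @export
mtt_inverse_gap <- function(gap, prevalence) {
  if (gap <= 0) Inf else 1 / (prevalence * gap)
}

#' Minimum test tradeoff between a larger and a smaller panel
#'
#' Quantifies how many administrations of the larger (more expensive) panel
#' are needed per true positive for its extra discrimination to yield a
#' positive net benefit over the smaller panel. The tradeoff decays
#' hyperbolically as the AUROC gap grows; with an AUROC uncertainty
#' (e.g. the spread induced by preprocessing choices) the interval obtained
#' by shifting the gap by +/- that uncertainty is reported as well. The
#' approximation formula is pluggable; the default is [mtt_inverse_gap()].
#'
#' @param auc_large AUROC of the larger panel (>= `auc_small`).
#' @param auc_small AUROC of the smaller panel.
#' @param prevalence Outcome prevalence in (0, 1).
#' @param auc_uncertainty Half-width of the AUROC-gap uncertainty
#'   (default 0).
#' @param formula Function `(gap, prevalence) -> tradeoff`.
#' @return Object of class `tradeoff_result`: `mtt`, `mtt_range`
#'   (`c(lower, upper)` from gap + / - uncertainty), inputs.
#' @export
min_test_tradeoff <- function(auc_large, auc_small, prevalence,
                              auc_uncertainty = 0,
                              formula = mtt_inverse_gap) {
  stopifnot(prevalence > 0, prevalence < 1, auc_large >= auc_small,
            auc_uncertainty >= 0)
  gap <- auc_large - auc_small
  structure(
    list(prevalence = prevalence, auc_large = auc_large,
         auc_small = auc_small, gap = gap,
         mtt = formula(gap, prevalence),
         mtt_range = c(lower = formula(gap + auc_uncertainty, prevalence),
                       upper = formula(max(gap - auc_uncertainty, 0),
                                       prevalence)),
         auc_uncertainty = auc_uncertainty),
    class = "tradeoff_result")
}

#' @export
print.tradeoff_result <- function(x, ...) {
  cat(sprintf(
    "tradeoff_result: AUROC %.3f vs %.3f (gap %.3f) at prevalence %.2f\n  MTT %.1f%s\n",
    x$auc_large, x$auc_small, x$gap, x$prevalence, x$mtt,
    if (x$auc_uncertainty > 0)
      sprintf("  [%.1f, %.1f] under +/-%.3f AUROC uncertainty",
              x$mtt_range[1], x$mtt_range[2], x$auc_uncertainty)
    else ""))
  invisible(x)
}
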