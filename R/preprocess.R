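#' Truncate Ct values at a detection limit
#'
#' Clamps every Ct reading above `limit` to `limit` and replaces undetected
#' wells by `limit`, clearing their undetected flags. This is the
#' "Ct limit" preprocessing perturbation: it treats very late or absent
#' amplification as "expression at the detection floor".
#'
#' @param ct A [ct_matrix()].
#' @param limit Positive Ct limit in cycles (conventionally 40).
#' @return A `ct_matrix` with no values above `limit` and an empty mask for
#'   the replaced entries.
#' @export
truncate_ct <- function(ct, limit) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (!is.numeric(limit) || length(limit) != 1L || limit <= 0)
    stop("truncate_ct: limit must be a positive scalar")
  vals <- ct$values
  mask <- ct$undetected
  vals[mask] <- limit
  vals[vals > limit] <- limit
  mask[] <- FALSE
  ct_matrix(vals, mask, ct$reference_gene)
}

#' Impute undetected Ct wells
#'
#' `"limit-fill"` sets undetected wells to the configured Ct limit (no
#' amplification = expression at the detection floor). `"per-gene-max-fill"`
#' sets them to the gene's maximum observed Ct, i.e. to the weakest level at
#' which that gene was actually seen. For train/test discipline the fill
#' values can be supplied precomputed (from training rows) via
#' `fill_values`.
#'
#' @param ct A [ct_matrix()].
#' @param strategy `"limit-fill"` or `"per-gene-max-fill"`.
#' @param limit Ct limit used by `"limit-fill"`.
#' @param fill_values Optional named vector of per-gene fill values
#'   overriding the strategy's own computation (used when applying
#'   training-fitted fills to new samples).
#' @return A `ct_matrix` with an empty undetected mask.
#' @export
impute_undetected <- function(ct, strategy = c("limit-fill",
                                               "per-gene-max-fill"),
                              limit = 40, fill_values = NULL) {
  stopifnot(inherits(ct, "ct_matrix"))
  strategy <- match.arg(strategy)
  vals <- ct$values
  mask <- ct$undetected
  if (!any(mask) && is.null(fill_values))
    return(ct)
  if (is.null(fill_values)) {
    fill_values <- switch(strategy,
      "limit-fill" = stats::setNames(rep(limit, ncol(vals)), colnames(vals)),
      "per-gene-max-fill" = {
        fv <- vapply(seq_len(ncol(vals)), function(j) {
          obs <- vals[!mask[, j], j]
          if (!length(obs)) NA_real_ else max(obs)
        }, numeric(1))
        names(fv) <- colnames(vals)
        if (anyNA(fv))
          stop("impute_undetected: gene(s) with all wells undetected: ",
               paste(names(fv)[is.na(fv)], collapse = ", "))
        fv
      })
  }
  for (j in colnames(vals)) {
    mj <- mask[, j]
    if (any(mj)) vals[mj, j] <- fill_values[[j]]
  }
  mask[] <- FALSE
  out <- ct_matrix(vals, mask, ct$reference_gene)
  attr(out, "fill_values") <- fill_values
  out
}

#' Delta-Ct normalization against the reference gene
#'
#' Computes `expression(sample, gene) = Ct(sample, reference) - Ct(sample,
#' gene)` and drops the reference column, so higher expression corresponds
#' to lower Ct (earlier amplification). This is the standard qPCR delta-Ct
#' normalization; the reference gene absorbs sample-level input variation.
#'
#' @param ct A [ct_matrix()] with no remaining undetected/missing wells.
#' @param reference_gene Reference gene; defaults to the matrix's own.
#' @return Numeric samples x genes expression matrix (reference excluded).
#' @export
delta_ct_normalize <- function(ct, reference_gene = ct$reference_gene) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (!reference_gene %in% colnames(ct$values))
    stop("delta_ct_normalize: reference gene '", reference_gene,
         "' not present")
  if (any(ct$undetected) || anyNA(ct$values))
    stop("delta_ct_normalize: undetected/missing Ct values remain; impute first")
  ref <- ct$values[, reference_gene]
  keep <- setdiff(colnames(ct$values), reference_gene)
  expr <- ref - ct$values[, keep, drop = FALSE]
  colnames(expr) <- keep
  expr
}

#' Define a preprocessing pipeline
#'
#' A pipeline is an ordered, deterministic composition of (optional) Ct
#' truncation, undetected-well imputation, delta-Ct normalization, and
#' (optional) per-gene standardization. Standardization statistics and
#' per-gene-max fills are fitted on development rows only (see
#' [fit_pipeline()]) and then applied unchanged to new samples, so no test
#' information leaks into preprocessing.
#'
#' @param name Unique pipeline identifier.
#' @param truncate_limit Ct truncation limit, or `NULL` for no truncation.
#' @param impute Imputation strategy, see [impute_undetected()].
#' @param impute_limit Ct limit used by `"limit-fill"`.
#' @param standardize Standardize each expression column (fitted on
#'   development rows)?
#' @return An object of class `pcs_pipeline`.
#' @export
pcs_pipeline <- function(name, truncate_limit = NULL,
                         impute = "limit-fill", impute_limit = 40,
                         standardize = FALSE) {
  stopifnot(is.character(name), nchar(name) > 0)
  structure(
    list(name = name, truncate_limit = truncate_limit,
         impute = impute, impute_limit = impute_limit,
         standardize = standardize, fitted = NULL),
    class = "pcs_pipeline"
  )
}

#' @export
print.pcs_pipeline <- function(x, ...) {
  cat(sprintf("pcs_pipeline '%s': truncate=%s, impute=%s(%g), standardize=%s%s\n",
              x$name,
              if (is.null(x$truncate_limit)) "none" else x$truncate_limit,
              x$impute, x$impute_limit, x$standardize,
              if (is.null(x$fitted)) "" else " [fitted]"))
  invisible(x)
}

#' The default perturbation set of four preprocessing pipelines
#'
#' The stability analysis perturbs preprocessing across four named
#' pipelines: `base` (limit-fill imputation + delta-Ct), `ct-limit-40`
#' (truncation of all Ct at 40 + delta-Ct), `base-genemax` (per-gene-max
#' imputation + delta-Ct), and `ct-limit-40-std` (truncation + delta-Ct +
#' per-gene standardization). The set is an ordinary named list, so user
#' pipelines can be added or substituted freely.
#'
#' @param limit Ct detection limit shared by the pipelines (default 40).
#' @return Named list of four [pcs_pipeline()] objects.
#' @export
default_pipeline_set <- function(limit = 40) {
  list(
    "base" = pcs_pipeline("base", impute = "limit-fill",
                          impute_limit = limit),
    "ct-limit-40" = pcs_pipeline("ct-limit-40", truncate_limit = limit,
                                 impute = "limit-fill", impute_limit = limit),
    "base-genemax" = pcs_pipeline("base-genemax",
                                  impute = "per-gene-max-fill",
                                  impute_limit = limit),
    "ct-limit-40-std" = pcs_pipeline("ct-limit-40-std",
                                     truncate_limit = limit,
                                     impute = "limit-fill",
                                     impute_limit = limit,
                                     standardize = TRUE)
  )
}

# Ct-space steps shared by fit and apply
pipeline_ct_steps <- function(pipeline, ct, fill_values = NULL) {
  if (!is.null(pipeline$truncate_limit))
    ct <- truncate_ct(ct, pipeline$truncate_limit)
  impute_undetected(ct, pipeline$impute, pipeline$impute_limit,
                    fill_values = fill_values)
}

#' Fit a pipeline's data-dependent statistics on development rows
#'
#' Per-gene-max fills and standardization means/SDs are computed from the
#' supplied (development) Ct matrix only. The returned pipeline can then be
#' applied to any rows, including held-out ones, without touching them.
#'
#' @param pipeline A [pcs_pipeline()].
#' @param ct Development-row [ct_matrix()].
#' @return The pipeline with a populated `fitted` field.
#' @export
fit_pipeline <- function(pipeline, ct) {
  stopifnot(inherits(pipeline, "pcs_pipeline"), inherits(ct, "ct_matrix"))
  ct1 <- if (is.null(pipeline$truncate_limit)) ct
         else truncate_ct(ct, pipeline$truncate_limit)
  fill_values <- if (pipeline$impute == "per-gene-max-fill") {
    vals <- ct1$values; mask <- ct1$undetected
    fv <- vapply(seq_len(ncol(vals)), function(j) {
      obs <- vals[!mask[, j], j]
      if (!length(obs)) NA_real_ else max(obs)
    }, numeric(1))
    names(fv) <- colnames(vals)
    if (anyNA(fv))
      stop("fit_pipeline: gene(s) with all wells undetected: ",
           paste(names(fv)[is.na(fv)], collapse = ", "))
    fv
  } else {
    stats::setNames(rep(pipeline$impute_limit, ncol(ct$values)),
                    colnames(ct$values))
  }
  ct2 <- impute_undetected(ct1, pipeline$impute, pipeline$impute_limit,
                           fill_values = fill_values)
  expr <- delta_ct_normalize(ct2)
  fitted <- list(fill_values = fill_values)
  if (isTRUE(pipeline$standardize)) {
    mu <- colMeans(expr)
    sdv <- apply(expr, 2, stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    fitted$center <- mu
    fitted$scale <- sdv
  }
  pipeline$fitted <- fitted
  pipeline
}

#' Apply a fitted pipeline to a Ct matrix
#'
#' @param pipeline A [fit_pipeline()]-fitted (or purely sample-wise)
#'   [pcs_pipeline()].
#' @param ct A [ct_matrix()].
#' @return Expression matrix (samples x genes, reference gene excluded),
#'   with no missing values.
#' @export
apply_pipeline <- function(pipeline, ct) {
  stopifnot(inherits(pipeline, "pcs_pipeline"), inherits(ct, "ct_matrix"))
  if (is.null(pipeline$fitted) &&
      (pipeline$impute == "per-gene-max-fill" || isTRUE(pipeline$standardize)))
    stop("apply_pipeline: pipeline has data-dependent steps; call fit_pipeline() first")
  fills <- pipeline$fitted$fill_values
  ct2 <- pipeline_ct_steps(pipeline, ct, fill_values = fills)
  expr <- delta_ct_normalize(ct2)
  if (isTRUE(pipeline$standardize)) {
    expr <- sweep(expr, 2, pipeline$fitted$center[colnames(expr)], `-`)
    expr <- sweep(expr, 2, pipeline$fitted$scale[colnames(expr)], `/`)
  }
  expr
}

#' Fit on development rows and apply to both development and new rows
#'
#' Convenience wrapper enforcing the no-leakage discipline used throughout
#' the package: all data-dependent preprocessing statistics come from
#' `ct_dev`.
#'
#' @param pipeline A [pcs_pipeline()].
#' @param ct_dev Development-row [ct_matrix()].
#' @param ct_new Optional held-out [ct_matrix()].
#' @return List with `dev` and (if given) `new` expression matrices and the
#'   fitted `pipeline`.
#' @export
preprocess_split <- function(pipeline, ct_dev, ct_new = NULL) {
  fitted <- fit_pipeline(pipeline, ct_dev)
  out <- list(dev = apply_pipeline(fitted, ct_dev), pipeline = fitted)
  if (!is.null(ct_new)) out$new <- apply_pipeline(fitted, ct_new)
  out
}
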