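#' Construct a Ct matrix
#'
#' Container for raw qPCR cycle-threshold (Ct) readings: a samples x genes
#' numeric matrix plus a logical mask of undetected wells (reactions that
#' never crossed the fluorescence threshold) and the name of the designated
#' reference gene used later for delta-Ct normalization. Lower Ct means
#' higher expression.
#'
#' @param values Numeric matrix, samples in rows (rownames = sample ids),
#'   genes in columns (unique colnames). Ct values are non-negative cycles.
#' @param undetected Logical matrix of the same shape flagging undetected
#'   wells; `NA` entries in `values` are flagged automatically. Default: no
#'   undetected wells beyond the `NA`s.
#' @param reference_gene Name of the reference gene column (e.g. `"KLK3"`).
#' @return An object of class `ct_matrix` with fields `values`, `undetected`,
#'   `reference_gene`.
#' @export
ct_matrix <- function(values, undetected = NULL, reference_gene) {
  values <- as.matrix(values)
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("ct_matrix: gene (column) names must be present and unique")
  if (!reference_gene %in% colnames(values))
    stop("ct_matrix: reference gene '", reference_gene, "' not found")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(undetected)) {
    undetected <- is.na(values)
  } else {
    undetected <- as.matrix(undetected) | is.na(values)
  }
  storage.mode(undetected) <- "logical"
  if (!identical(dim(undetected), dim(values)))
    stop("ct_matrix: undetected mask shape mismatch")
  dimnames(undetected) <- dimnames(values)
  if (any(values[!undetected] < 0, na.rm = TRUE))
    stop("ct_matrix: negative Ct values")
  structure(
    list(values = values, undetected = undetected,
         reference_gene = reference_gene),
    class = "ct_matrix"
  )
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf(
    "ct_matrix: %d samples x %d genes (reference: %s), %d undetected wells\n",
    nrow(x$values), ncol(x$values), x$reference_gene, sum(x$undetected)))
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$values)

#' Gene names of a Ct matrix
#' @param ct A `ct_matrix`.
#' @param include_reference Keep the reference gene in the result?
#' @return Character vector of gene names.
#' @export
genes <- function(ct, include_reference = TRUE) {
  g <- colnames(ct$values)
  if (!include_reference) g <- setdiff(g, ct$reference_gene)
  g
}

#' Subset a Ct matrix by samples
#' @param ct A `ct_matrix`.
#' @param rows Row index vector (integer, logical, or sample ids).
#' @return A `ct_matrix` restricted to `rows`.
#' @export
ct_subset <- function(ct, rows) {
  ct_matrix(ct$values[rows, , drop = FALSE],
            ct$undetected[rows, , drop = FALSE],
            ct$reference_gene)
}

#' Read a Ct matrix from CSV
#'
#' Expects a header row of gene names and a `sample_id` column. Undetected
#' wells are encoded by a literal token (qPCR exports commonly print
#' `"Undetermined"`) or an empty cell; both are masked.
#'
#' @param path CSV file path.
#' @param reference_gene Reference gene column name.
#' @param undetected_token Token marking undetected wells.
#' @return A `ct_matrix`.
#' @export
read_ct_csv <- function(path, reference_gene,
                        undetected_token = "Undetermined") {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character", na.strings = NULL)
  if (!"sample_id" %in% names(df))
    stop("read_ct_csv: no 'sample_id' column in ", path)
  if (anyDuplicated(names(df)))
    stop("read_ct_csv: duplicate gene names: ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  ids <- df[["sample_id"]]
  df <- df[setdiff(names(df), "sample_id")]
  mask <- vapply(df, function(col) col == undetected_token | col == "",
                 logical(nrow(df)))
  vals <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) {  # vapply drops to vector shape consistency
    mask <- matrix(mask, nrow = 1L, dimnames = list(NULL, names(df)))
    vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, names(df)))
  }
  bad <- is.na(vals) & !mask
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop("read_ct_csv: non-numeric Ct at row ", w[1L], ", column '",
         colnames(vals)[w[2L]], "'")
  }
  vals[mask] <- NA_real_
  rownames(vals) <- ids
  ct_matrix(vals, mask, reference_gene)
}

#' Write a Ct matrix to CSV
#'
#' Inverse of [read_ct_csv()]: undetected wells are written as the token.
#'
#' @param ct A `ct_matrix`.
#' @param path Output CSV path.
#' @param undetected_token Token marking undetected wells.
#' @return `path`, invisibly.
#' @export
write_ct_csv <- function(ct, path, undetected_token = "Undetermined") {
  ch <- matrix(format(ct$values, trim = TRUE, digits = 10),
               nrow = nrow(ct$values), dimnames = dimnames(ct$values))
  ch[ct$undetected] <- undetected_token
  df <- data.frame(sample_id = rownames(ct$values), ch,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a clinical covariate table from CSV
#'
#' @param path CSV with a `sample_id` column plus covariate columns
#'   (and optionally the binary `outcome` column).
#' @return A data.frame keyed by `sample_id`.
#' @export
read_clinical_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"sample_id" %in% names(df))
    stop("read_clinical_csv: no 'sample_id' column in ", path)
  df
}

#' Align a Ct matrix with a clinical table
#'
#' Verifies that the two tables describe the same samples and returns the
#' clinical rows reordered to the Ct matrix's sample order.
#'
#' @param ct A `ct_matrix`.
#' @param clinical Data.frame with a `sample_id` column.
#' @return The reordered clinical data.frame.
#' @export
align_cohort <- function(ct, clinical) {
  ids <- rownames(ct$values)
  missing_clin <- setdiff(ids, clinical$sample_id)
  missing_ct <- setdiff(clinical$sample_id, ids)
  if (length(missing_clin) || length(missing_ct))
    stop("align_cohort: sample_id mismatch; missing from clinical: [",
         paste(missing_clin, collapse = ", "), "]; missing from ct: [",
         paste(missing_ct, collapse = ", "), "]")
  clinical[match(ids, clinical$sample_id), , drop = FALSE]
}
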