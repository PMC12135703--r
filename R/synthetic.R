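#' The six standard clinical covariates
#'
#' Names of the clinical predictors carried through every modeling stage:
#' age, race, family history of prostate cancer, abnormal digital rectal
#' examination, prior negative biopsy, and serum PSA. Prostate volume is
#' simulated as well but only enters "+" risk models on request.
#' @return Character vector of column names.
#' @export
clinical_covariates <- function() {
  c("age", "race", "family_history", "abnormal_dre",
    "prior_neg_biopsy", "psa")
}

default_signal_genes <- function(gene_names, block_size) {
  # spread the planted genes across distinct correlation blocks; moderate
  # effect sizes chosen so the planted panel sits in the rank-stability
  # regime the package is built to detect (see the methods vignette):
  # below ~0.9 per-SD log-odds a gene falls under the detectability floor
  # of forest-based importance at n ~ 750 with 54 correlated candidates
  idx <- 1L + block_size * (0:5)
  idx <- idx[idx <= length(gene_names)]
  effects <- c(1.4, 1.3, 1.2, 1.1, 1.0, 0.9)[seq_along(idx)]
  stats::setNames(effects, gene_names[idx])
}

#' Simulation configuration for a synthetic qPCR cohort
#'
#' Describes a synthetic biopsy cohort: a panel of candidate genes measured
#' by qPCR cycle thresholds (Ct) with right-censored detection, six clinical
#' covariates plus prostate volume, and a binary high-grade outcome generated
#' from a logistic model over the planted signal genes and clinical effects.
#'
#' Defaults emulate the development setting the package targets: 54
#' candidate genes plus a highly expressed reference gene, elevated-PSA
#' patients (PSA 3-10 ng/mL), a Ct detection limit of 40 cycles, and a
#' configurable high-grade prevalence (default 0.35 for development-style
#' cohorts; external-validation-style cohorts typically use 0.20).
#'
#' @param n_samples Number of patients.
#' @param n_genes Number of candidate genes (default 54), excluding the
#'   reference gene.
#' @param gene_names Optional candidate gene names (length `n_genes`).
#' @param reference_gene Reference gene name (default `"KLK3"`).
#' @param signal_genes Named numeric vector of per-SD log-odds effects for
#'   the planted informative genes (names must be candidate genes). Default:
#'   six genes spread across distinct correlation blocks with effects 1.4
#'   down to 0.9 (see the methods vignette for why this regime).
#' @param clinical_effects Named log-odds effects (per SD for continuous
#'   covariates) for the six clinical covariates.
#' @param volume_effect Log-odds effect of (log) prostate volume; volume is
#'   simulated but excluded from the default covariate set.
#' @param prevalence_target Target fraction of high-grade outcomes, in (0,1).
#' @param ct_censor_limit Detection limit in cycles; reactions beyond it are
#'   undetected (default 40).
#' @param block_corr Within-block equicorrelation of latent expression,
#'   in \[0, 1).
#' @param block_size Genes per correlation block (default 6).
#' @param noise_sd Measurement noise SD in Ct cycles (default 0.5, a
#'   typical qPCR replicate SD).
#' @param sample_effect_sd SD (cycles) of the per-sample loading factor
#'   shifting every well of a sample equally; delta-Ct normalization
#'   cancels it (default 1).
#' @param ct_baseline Mean per-gene Ct at average expression (default 30).
#' @param baseline_spread SD of per-gene baseline Ct around `ct_baseline`
#'   (default 3; low-expression genes land near the detection limit).
#' @param ct_scale Cycles of Ct shift per SD of latent expression
#'   (default 1.5); Ct = baseline - scale x expression, so lower Ct means
#'   higher expression.
#' @param seed Integer seed; identical config + seed reproduces the cohort.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples,
                       n_genes = 54L,
                       gene_names = NULL,
                       reference_gene = "KLK3",
                       signal_genes = NULL,
                       clinical_effects = c(age = 0.3, race = 0.2,
                                            family_history = 0.2,
                                            abnormal_dre = 0.4,
                                            prior_neg_biopsy = -0.3,
                                            psa = 0.35),
                       volume_effect = -0.4,
                       prevalence_target = 0.35,
                       ct_censor_limit = 40,
                       block_corr = 0.3,
                       block_size = 6L,
                       noise_sd = 0.5,
                       sample_effect_sd = 1,
                       ct_baseline = 30,
                       baseline_spread = 3,
                       ct_scale = 1.5,
                       seed = 1L) {
  stopifnot(n_samples >= 1, n_genes >= 1,
            prevalence_target > 0, prevalence_target < 1,
            ct_censor_limit > 0, block_corr >= 0, block_corr < 1,
            block_size >= 1, noise_sd >= 0, ct_scale > 0)
  if (is.null(gene_names))
    gene_names <- sprintf("G%02d", seq_len(n_genes))
  stopifnot(length(gene_names) == n_genes, !anyDuplicated(gene_names),
            !reference_gene %in% gene_names)
  if (is.null(signal_genes))
    signal_genes <- default_signal_genes(gene_names, block_size)
  if (length(signal_genes) && !all(names(signal_genes) %in% gene_names))
    stop("sim_config: signal genes must be a subset of gene_names")
  stopifnot(setequal(names(clinical_effects), clinical_covariates()))
  structure(
    list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
         gene_names = gene_names, reference_gene = reference_gene,
         signal_genes = signal_genes,
         clinical_effects = clinical_effects[clinical_covariates()],
         volume_effect = volume_effect,
         prevalence_target = prevalence_target,
         ct_censor_limit = ct_censor_limit,
         block_corr = block_corr, block_size = as.integer(block_size),
         noise_sd = noise_sd, sample_effect_sd = sample_effect_sd,
         ct_baseline = ct_baseline,
         baseline_spread = baseline_spread, ct_scale = ct_scale,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Planted ground truth of a simulation configuration
#'
#' @param config A [sim_config()].
#' @return Data.frame with columns `gene` and `effect` (per-SD log-odds),
#'   empty if no signal genes are planted.
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  data.frame(gene = names(config$signal_genes) %||% character(),
             effect = unname(config$signal_genes),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# truncated lognormal on [lo, hi] by inverse-CDF sampling
rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(plo + stats::runif(n) * (phi - plo), meanlog, sdlog)
}

# solve the logistic intercept so that mean p matches the target prevalence
solve_intercept <- function(lp, target, tol = 1e-3) {
  f <- function(b0) mean(stats::plogis(b0 + lp)) - target
  lo <- -30; hi <- 30
  if (!is.finite(f(lo)) || !is.finite(f(hi)) || f(lo) > 0 || f(hi) < 0)
    stop("solve_intercept: infeasible prevalence target")
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (abs(f(mid)) < tol) return(mid)
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  mid
}

#' Simulate a synthetic cohort with planted signal genes
#'
#' Latent gene expression is drawn from a block-equicorrelated multivariate
#' normal (each block of `block_size` genes shares correlation `block_corr`).
#' The binary high-grade outcome follows a logistic model over the planted
#' signal genes, standardized clinical covariates, and log prostate volume;
#' the intercept is solved by bisection so the expected prevalence matches
#' `prevalence_target`. Observed Ct is `baseline - ct_scale x expression`
#' plus Gaussian noise, right-censored at `ct_censor_limit` (censored wells
#' are flagged undetected). The reference gene is highly expressed and
#' carries no outcome effect.
#'
#' @param config A [sim_config()].
#' @return An object of class `synthetic_cohort`: list with `ct`
#'   (a [ct_matrix()] including the reference gene), `clinical` (data.frame
#'   with `sample_id`, the six covariates, and `volume`), `outcome`
#'   (0/1 integer vector), `truth` (the planted-gene table), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  G <- config$n_genes

  # latent expression: block-equicorrelated standard normals
  nblk <- ceiling(G / config$block_size)
  blk <- rep(seq_len(nblk), each = config$block_size)[seq_len(G)]
  shared <- matrix(stats::rnorm(n * nblk), n, nblk)
  indiv <- matrix(stats::rnorm(n * G), n, G)
  rho <- config$block_corr
  z <- sqrt(rho) * shared[, blk, drop = FALSE] + sqrt(1 - rho) * indiv
  colnames(z) <- config$gene_names

  clinical <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    age = stats::rnorm(n, 62, 8),
    race = stats::rbinom(n, 1, 0.15),
    family_history = stats::rbinom(n, 1, 0.20),
    abnormal_dre = stats::rbinom(n, 1, 0.15),
    prior_neg_biopsy = stats::rbinom(n, 1, 0.25),
    psa = rlnorm_trunc(n, log(5), 0.5, 3, 10),
    volume = stats::rlnorm(n, log(45), 0.4),
    stringsAsFactors = FALSE
  )

  std <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  gamma <- config$clinical_effects
  lp_clin <- gamma[["age"]] * std(clinical$age) +
    gamma[["race"]] * clinical$race +
    gamma[["family_history"]] * clinical$family_history +
    gamma[["abnormal_dre"]] * clinical$abnormal_dre +
    gamma[["prior_neg_biopsy"]] * clinical$prior_neg_biopsy +
    gamma[["psa"]] * std(clinical$psa) +
    config$volume_effect * std(log(clinical$volume))
  lp_gene <- if (length(config$signal_genes))
    drop(z[, names(config$signal_genes), drop = FALSE] %*% config$signal_genes)
  else rep(0, n)
  lp <- lp_gene + lp_clin

  b0 <- solve_intercept(lp, config$prevalence_target)
  outcome <- stats::rbinom(n, 1, stats::plogis(b0 + lp))

  # per-gene baseline Ct; reference gene highly expressed (low Ct).
  # A per-sample loading factor shifts every well of a sample equally
  # (urine input variation); delta-Ct against the stable reference gene
  # cancels it exactly, which is the point of the normalization.
  baselines <- stats::rnorm(G, config$ct_baseline, config$baseline_spread)
  loading <- stats::rnorm(n, 0, config$sample_effect_sd)
  baselines_all <- c(baselines, 22)
  gene_names_all <- c(config$gene_names, config$reference_gene)
  z_all <- cbind(z, rep(0, n))  # reference carries no biological signal
  ct_vals <- sweep(-config$ct_scale * z_all, 2, baselines_all, `+`) +
    loading +
    matrix(stats::rnorm(n * (G + 1), 0, config$noise_sd), n, G + 1)
  ct_vals <- pmax(ct_vals, 0)
  colnames(ct_vals) <- gene_names_all
  rownames(ct_vals) <- clinical$sample_id
  undet <- ct_vals > config$ct_censor_limit
  ct_vals[undet] <- NA_real_

  structure(
    list(ct = ct_matrix(ct_vals, undet, config$reference_gene),
         clinical = clinical,
         outcome = as.integer(outcome),
         truth = planted_truth(config),
         config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d samples, %d candidate genes + %s, prevalence %.3f\n",
    length(x$outcome), x$config$n_genes, x$config$reference_gene,
    mean(x$outcome)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes `ct.csv` (sample_id + gene columns, undetected wells as the
#' token), `clinical.csv` (sample_id, covariates, outcome), and
#' `truth.json` (planted genes and effects).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ct_csv(cohort$ct, file.path(dir, "ct.csv"))
  clin <- cohort$clinical
  clin$outcome <- cohort$outcome
  utils::write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(reference_gene = cohort$config$reference_gene,
         prevalence_target = cohort$config$prevalence_target,
         signal_genes = stats::setNames(
           as.list(cohort$truth$effect), cohort$truth$gene)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
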