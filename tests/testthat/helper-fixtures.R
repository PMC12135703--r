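# Shared fixtures, built in code.

# tiny deterministic Ct matrix with known censoring
toy_ct <- function() {
  vals <- matrix(c(30, 25, 41, 22,
                   35, NA, 38, 23,
                   28, 33, 40, 21),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(paste0("S", 1:3),
                                 c("GA", "GB", "GC", "KLK3")))
  ct_matrix(vals, reference_gene = "KLK3")
}

# small cohort with strong planted signal for fast model tests
quick_cohort <- function(n = 200, seed = 7, n_genes = 12,
                         prevalence = 0.35) {
  gn <- sprintf("Q%02d", seq_len(n_genes))
  sim_config(n_samples = n, n_genes = n_genes, gene_names = gn,
             signal_genes = stats::setNames(c(1.5, 1.2), gn[c(1, 7)]),
             prevalence_target = prevalence, block_size = 6,
             seed = seed) |> simulate_cohort()
}

# reduced model specs that fit in seconds
quick_specs <- function() {
  list(
    "logistic" = model_spec("logistic", "glm"),
    "ridge-logistic" = model_spec(
      "ridge-logistic", "glmnet",
      grid = data.frame(C = c(0.01, 0.1, 1)), fixed = list(alpha = 0)),
    "random-forest" = model_spec(
      "random-forest", "rf",
      grid = data.frame(min_samples_leaf = 5),
      fixed = list(n_estimators = 60))
  )
}

# random tie-free rank tensor for aggregation oracles
random_rank_tensor <- function(np = 2, nm = 3, nr = 4, ng = 10,
                               seed = 1) {
  set.seed(seed)
  arr <- array(NA_real_, dim = c(np, nm, nr, ng),
               dimnames = list(pipeline = paste0("p", seq_len(np)),
                               model = paste0("m", seq_len(nm)),
                               rep = NULL,
                               gene = paste0("g", seq_len(ng))))
  for (p in seq_len(np)) for (m in seq_len(nm)) for (r in seq_len(nr))
    arr[p, m, r, ] <- sample(ng)
  class(arr) <- c("rank_tensor", "array")
  arr
}
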