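#' Define a model specification
#'
#' A spec names a learner, its hyperparameter grid (each row one candidate,
#' listed simplest/most-regularized first so ties break toward simplicity),
#' and fixed settings. Specs whose engines depend on third-party learners
#' not shipped here (`rulefit`, `rf-plus`, `figs`) are declared but flagged
#' unavailable; the ranking procedure runs with any subset of two or more
#' available specs.
#'
#' @param name Unique spec name.
#' @param engine One of `"glm"`, `"glmnet"`, `"rf"`, `"gbdt"`, `"none"`.
#' @param grid Data.frame of hyperparameter candidates (0 rows = none).
#' @param fixed Named list of fixed settings (e.g. `n_estimators`).
#' @param available Can this spec actually be fitted here?
#' @param optional Is the spec an optional plug-in slot?
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(name, engine, grid = data.frame(),
                       fixed = list(), available = TRUE, optional = FALSE) {
  structure(list(name = name, engine = engine, grid = grid, fixed = fixed,
                 available = available, optional = optional),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec '%s' (engine %s): %d hyperparameter candidate(s)%s\n",
              x$name, x$engine, max(nrow(x$grid), 1L),
              if (x$available) "" else " [unavailable]"))
  invisible(x)
}

# inverse-regularization candidates C = 10^i, i = -3, -2.5, ..., 3
c_grid <- function() 10^seq(-3, 3, by = 0.5)

#' The default nine-learner model grid
#'
#' Plain logistic regression (no hyperparameters); lasso-, ridge-, and
#' elastic-net-penalized logistic regression with inverse regularization
#' strength C = 10^i for i in \{-3, -2.5, ..., 3\} (13 candidates; elastic
#' net also sweeps the L1 mixing ratio over \{0.1, 0.25, 0.5, 0.75, 0.9\});
#' a 500-tree random forest with minimum leaf sizes \{1, 3, 5, 10\}; a
#' 500-round gradient-boosted tree model with learning rates
#' \{0.05, 0.1, 0.15\}, leaf sizes \{1, 5, 10\}, and depths \{3, 5\}; plus
#' three declared-but-pluggable slots (RuleFit with max rules
#' \{5, 10, 30, 50\}, random forest plus with its implementation-default
#' grid, and fast interpretable greedy-tree sums with max rules
#' \{5, 10, 12, 15, 20, 30, 50\}) whose reference implementations are
#' Python-only and therefore flagged unavailable in this package.
#'
#' Hyperparameters are tuned by stratified 5-fold cross-validation
#' maximizing AUROC (see [tune_and_fit()]). Penalized grids are ordered
#' strongest-regularization-first and tree grids simplest-first, so exact
#' CV ties resolve toward the simpler model.
#'
#' @return Named list of nine [model_spec()] objects.
#' @export
default_model_grid <- function() {
  cg <- c_grid()
  specs <- list(
    model_spec("logistic", "glm"),
    model_spec("lasso-logistic", "glmnet",
               grid = data.frame(C = cg), fixed = list(alpha = 1)),
    model_spec("ridge-logistic", "glmnet",
               grid = data.frame(C = cg), fixed = list(alpha = 0)),
    model_spec("elasticnet-logistic", "glmnet",
               grid = expand.grid(C = cg,
                                  l1_ratio = c(0.1, 0.25, 0.5, 0.75, 0.9))),
    model_spec("random-forest", "rf",
               grid = data.frame(min_samples_leaf = c(10, 5, 3, 1)),
               fixed = list(n_estimators = 500)),
    model_spec("gbdt", "gbdt",
               grid = expand.grid(learning_rate = c(0.05, 0.1, 0.15),
                                  min_samples_leaf = c(10, 5, 1),
                                  max_depth = c(3, 5)),
               fixed = list(n_estimators = 500)),
    model_spec("rulefit", "none",
               grid = data.frame(max_rules = c(5, 10, 30, 50)),
               available = FALSE, optional = TRUE),
    model_spec("rf-plus", "none", available = FALSE, optional = TRUE),
    model_spec("figs", "none",
               grid = data.frame(max_rules = c(5, 10, 12, 15, 20, 30, 50)),
               available = FALSE, optional = TRUE)
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Available specs from a model grid
#' @param specs List of [model_spec()]s.
#' @return The subset with a working engine.
#' @export
available_specs <- function(specs) {
  Filter(function(s) isTRUE(s$available), specs)
}

# sklearn-style inverse regularization -> glmnet lambda on the mean
# log-likelihood scale
c_to_lambda <- function(C, n) 1 / (n * C)

# stratified k-fold assignment (returns fold id per row)
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

fit_engine <- function(engine, x, y, params, fixed) {
  n <- nrow(x)
  if (engine == "glm") {
    fit <- suppressWarnings(
      stats::glm.fit(cbind("(Intercept)" = 1, x), y,
                     family = stats::binomial()))
    list(kind = "glm", coef = fit$coefficients)
  } else if (engine == "glmnet") {
    alpha <- if (!is.null(params$l1_ratio)) params$l1_ratio else fixed$alpha
    lam <- c_to_lambda(params$C, n)
    # fit a short path down to the target lambda for warm-start stability
    lam_path <- sort(unique(c(lam * c(16, 8, 4, 2), lam)), decreasing = TRUE)
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                          lambda = lam_path, standardize = TRUE)
    list(kind = "glmnet", fit = fit, lambda = lam)
  } else if (engine == "rf") {
    n_trees <- fixed$n_estimators %||% 500L
    list(kind = "rf",
         fit = rf_fit(x, y, n_trees = n_trees,
                      min_leaf = params$min_samples_leaf %||% 1L))
  } else if (engine == "gbdt") {
    n_trees <- fixed$n_estimators %||% 500L
    list(kind = "gbdt",
         fit = gbdt_fit(x, y, n_trees = n_trees,
                        learning_rate = params$learning_rate %||% 0.1,
                        max_depth = params$max_depth %||% 3L,
                        min_leaf = params$min_samples_leaf %||% 1L))
  } else {
    stop("fit_engine: engine '", engine, "' is not available")
  }
}

predict_engine <- function(eng, x) {
  switch(eng$kind,
    glm = {
      beta <- eng$coef
      beta[is.na(beta)] <- 0
      drop(stats::plogis(cbind(1, x[, names(beta)[-1], drop = FALSE]) %*% beta))
    },
    glmnet = drop(stats::predict(eng$fit, x, s = eng$lambda,
                                 type = "response", exact = FALSE)),
    rf = predict(eng$fit, x),
    gbdt = predict(eng$fit, x)
  )
}

#' Tune hyperparameters by stratified 5-fold CV and fit the final model
#'
#' Candidates are scored by mean held-out AUROC over stratified folds;
#' the best candidate (first among exact ties, i.e. the most regularized /
#' simplest, given the grid ordering) is refit on all rows. Specs with an
#' empty grid are fitted directly. All randomness (fold assignment,
#' bootstrap resampling) derives from `seed`.
#'
#' For the penalized logistic engines the full regularization path is fitted
#' once per fold and evaluated at every candidate, rather than refitting per
#' candidate.
#'
#' @param spec A [model_spec()].
#' @param x Numeric feature matrix (genes + clinical covariates), no missing
#'   values.
#' @param y Binary 0/1 outcome with both classes present.
#' @param seed Integer seed.
#' @param folds Number of CV folds (default 5).
#' @return Object of class `fitted_model` with elements `name`, `engine`,
#'   `chosen` (named list of selected hyperparameters, empty if none),
#'   `cv_auroc` (per-candidate mean CV AUROC, `NULL` if no tuning),
#'   `features`, and the trained engine.
#' @export
tune_and_fit <- function(spec, x, y, seed = 1L, folds = 5L) {
  stopifnot(inherits(spec, "model_spec"))
  if (!isTRUE(spec$available))
    stop("tune_and_fit: spec '", spec$name, "' is not available in this build")
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(!anyNA(x), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2L)
    stop("tune_and_fit: outcome has a single class")
  grid <- spec$grid
  set.seed(seed)
  cv_auroc <- NULL
  if (nrow(grid) > 1L) {
    fold <- stratified_folds(y, folds)
    scores <- matrix(NA_real_, folds, nrow(grid))
    for (f in seq_len(folds)) {
      tr <- fold != f
      te <- !tr
      if (length(unique(y[te])) < 2L) next
      if (spec$engine == "glmnet") {
        # one path per alpha level, evaluated at all C candidates
        alphas <- if ("l1_ratio" %in% names(grid)) unique(grid$l1_ratio)
                  else spec$fixed$alpha
        for (a in alphas) {
          rows <- if ("l1_ratio" %in% names(grid)) which(grid$l1_ratio == a)
                  else seq_len(nrow(grid))
          lams <- c_to_lambda(grid$C[rows], sum(tr))
          ord <- order(lams, decreasing = TRUE)
          fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr],
                                family = "binomial", alpha = a,
                                lambda = lams[ord], standardize = TRUE)
          pr <- stats::predict(fit, x[te, , drop = FALSE], s = lams,
                               type = "response", exact = FALSE)
          scores[f, rows] <- apply(pr, 2, auroc, labels = y[te])
        }
      } else {
        for (g in seq_len(nrow(grid))) {
          eng <- fit_engine(spec$engine, x[tr, , drop = FALSE], y[tr],
                            as.list(grid[g, , drop = FALSE]), spec$fixed)
          scores[f, g] <- auroc(predict_engine(eng, x[te, , drop = FALSE]),
                                y[te])
        }
      }
    }
    cv_auroc <- colMeans(scores, na.rm = TRUE)
    best <- which.max(cv_auroc)  # first among ties = simplest candidate
    chosen <- as.list(grid[best, , drop = FALSE])
  } else if (nrow(grid) == 1L) {
    chosen <- as.list(grid[1L, , drop = FALSE])
  } else {
    chosen <- list()
  }
  eng <- fit_engine(spec$engine, x, y, chosen, spec$fixed)
  structure(list(name = spec$name, engine = spec$engine, chosen = chosen,
                 cv_auroc = cv_auroc, features = colnames(x), fit = eng),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  ch <- if (length(x$chosen))
    paste(names(x$chosen), unlist(x$chosen), sep = "=", collapse = ", ")
  else "none"
  cat(sprintf("fitted_model '%s' (%d features); chosen hyperparameters: %s\n",
              x$name, length(x$features), ch))
  invisible(x)
}

#' Predicted class-1 probabilities from a fitted model
#'
#' @param model A [tune_and_fit()] result.
#' @param x Feature matrix containing the training columns.
#' @return Probabilities in \[0, 1\].
#' @export
predict_prob <- function(model, x) {
  stopifnot(inherits(model, "fitted_model"))
  x <- as.matrix(x)
  missing <- setdiff(model$features, colnames(x))
  if (length(missing))
    stop("predict_prob: missing feature columns: ",
         paste(missing, collapse = ", "))
  predict_engine(model$fit, x[, model$features, drop = FALSE])
}

#' Serializable summary of a fitted model
#' @param model A `fitted_model`.
#' @return List (spec name, engine, chosen hyperparameters, features)
#'   suitable for `jsonlite::write_json()`.
#' @export
model_summary <- function(model) {
  list(name = model$name, engine = model$engine,
       chosen = model$chosen, features = model$features)
}

linear_coefs <- function(model) {
  if (model$fit$kind == "glm") {
    beta <- model$fit$coef
    beta[is.na(beta)] <- 0
    beta[setdiff(names(beta), "(Intercept)")]
  } else {
    cf <- stats::coef(model$fit$fit, s = model$fit$lambda, exact = FALSE)
    stats::setNames(as.numeric(cf)[-1L], rownames(cf)[-1L])
  }
}

#' Gene importance scores from a fitted model
#'
#' Linear models (plain and penalized logistic regression) score each gene
#' by the absolute standardized coefficient `|beta_g| * sd(x_g)`, making
#' scores comparable across genes measured on different scales. Tree
#' ensembles use seeded permutation importance: the mean AUROC drop over
#' `B` random permutations of the gene's column, floored at zero - computed
#' on out-of-bag predictions for random forests (Breiman's convention,
#' which avoids the in-sample memorization ceiling) and on the supplied
#' rows for boosted trees. Clinical
#' covariates are never scored - only the names passed in `genes` are.
#'
#' @param model A [tune_and_fit()] result.
#' @param x Feature matrix the importance is evaluated on (development
#'   rows).
#' @param y Binary outcome for `x` (used by permutation importance).
#' @param genes Candidate gene names to score (must be model features).
#' @param B Permutation repeats for tree ensembles (default 5).
#' @param seed Seed for the permutations.
#' @return Named non-negative numeric vector over exactly `genes`.
#' @export
gene_importance <- function(model, x, y, genes, B = 5L, seed = 1L) {
  stopifnot(inherits(model, "fitted_model"))
  x <- as.matrix(x)
  missing <- setdiff(genes, model$features)
  if (length(missing))
    stop("gene_importance: gene(s) not among model features: ",
         paste(missing, collapse = ", "))
  if (model$engine %in% c("glm", "glmnet")) {
    beta <- linear_coefs(model)
    sds <- apply(x[, genes, drop = FALSE], 2, stats::sd)
    imp <- abs(beta[genes]) * sds
  } else if (model$engine == "rf") {
    # Breiman OOB permutation importance, computed in compiled code
    set.seed(seed)
    y <- as.integer(y)
    xo <- x[, model$features, drop = FALSE]
    rf <- model$fit$fit
    imp <- forest_perm_importance_cpp(
      rf$trees, rf$oob, xo, y, match(genes, colnames(xo)) - 1L,
      as.integer(B))
    names(imp) <- genes
  } else {
    # boosted trees have no bags: permutation importance on supplied rows
    set.seed(seed)
    y <- as.integer(y)
    xo <- x[, model$features, drop = FALSE]
    base <- auroc(predict_prob(model, xo), y)
    imp <- vapply(genes, function(g) {
      drop_b <- vapply(seq_len(B), function(b) {
        xp <- xo
        xp[, g] <- xp[sample.int(nrow(xp)), g]
        base - auroc(predict_prob(model, xp), y)
      }, numeric(1))
      max(mean(drop_b), 0)
    }, numeric(1))
  }
  imp <- stats::setNames(as.numeric(imp), genes)
  if (any(!is.finite(imp))) stop("gene_importance: non-finite scores")
  imp
}
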