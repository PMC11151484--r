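# Feature importance: gradient-boosted tree split gain and permutation
# importance.
#
# The tree ranker trains a gradient-boosted decision-tree ensemble per
# cross-validation fold and scores each feature by its normalised total
# split gain -- the share of the summed node-impurity decrease
# (w_j*C_j - w_left*C_left - w_right*C_right over nodes splitting on the
# feature, divided by the total over all nodes) -- averaged over trees and
# folds. Permutation importance corrupts one feature at a time (K seeded
# permutations) and reports the drop in balanced accuracy relative to the
# intact data; the final ranking averages the four classifier families.

#' Gradient-boosted tree (Gini/gain) feature importance
#'
#' @param x numeric feature matrix.
#' @param y factor labels (`low`/`high`; `high` positive).
#' @param n_folds training folds; the ensemble is fitted on each fold's
#'   training split and importances are averaged (5).
#' @param nrounds,max_depth,eta boosting rounds and tree parameters.
#' @param seed RNG seed.
#' @return tibble `feature, importance` (normalised gain summing to 1 when
#'   any split was made; features never split on score 0), sorted.
#' @export
gbm_gini_importance <- function(x, y, n_folds = 5, nrounds = 50,
                                max_depth = 4, eta = 0.1, seed = 1) {
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  stopifnot(nlevels(y) == 2)
  lab <- as.numeric(y == "high")
  fid <- stratified_folds(y, n_folds)
  imp <- matrix(0, n_folds, ncol(x), dimnames = list(NULL, colnames(x)))
  for (f in seq_len(n_folds)) {
    tr <- fid != f
    dtrain <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = lab[tr],
                                   nthread = 1)
    bst <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
                    eta = eta, nthread = 1),
      data = dtrain, nrounds = nrounds, verbose = 0)
    gi <- xgboost::xgb.importance(model = bst)
    if (!is.null(gi) && nrow(gi)) imp[f, gi$Feature] <- gi$Gain
  }
  tibble(feature = colnames(x), importance = colMeans(imp)) %>%
    arrange(dplyr::desc(.data$importance))
}

#' Permutation feature importance
#'
#' `i_j = s - mean_k(s_kj)`: the reference balanced accuracy minus the mean
#' balanced accuracy over `K` permutations of feature `j`. A feature the
#' model ignores scores exactly 0; negative values mean the model improved
#' when the feature was corrupted.
#'
#' @param model a fitted classifier (from the package's classification
#'   stage) or any object usable through `predict_fun`.
#' @param x,y evaluation data.
#' @param K permutations per feature (5).
#' @param seed RNG seed.
#' @param predict_fun `function(model, x)` returning factor predictions;
#'   defaults to the package's classifier predictor.
#' @return tibble `feature, importance`, sorted.
#' @export
permutation_importance <- function(model, x, y, K = 5, seed = 1,
                                   predict_fun = NULL) {
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  if (is.null(predict_fun)) predict_fun <- predict_classifier
  s <- evaluate_predictions(y, predict_fun(model, x))$balanced_accuracy
  imp <- vapply(seq_len(ncol(x)), function(j) {
    skj <- vapply(seq_len(K), function(k) {
      xp <- x
      xp[, j] <- xp[sample.int(nrow(x)), j]
      evaluate_predictions(y, predict_fun(model, xp))$balanced_accuracy
    }, numeric(1))
    s - mean(skj)
  }, numeric(1))
  tibble(feature = colnames(x), importance = imp) %>%
    arrange(dplyr::desc(.data$importance))
}

#' Permutation importance averaged over the four classifier families
#'
#' Fits each family on the full data (fixed, sensible hyperparameters) and
#' averages the per-family permutation importances.
#'
#' @param x,y data (should be preprocessed/standardised).
#' @param classifiers families to include.
#' @param K permutations per feature (5).
#' @param seed RNG seed.
#' @param params optional named list of per-family parameter lists.
#' @return tibble `feature, importance` (mean over families), sorted.
#' @export
ensemble_permutation_importance <- function(x, y,
                                            classifiers = c("svm_rbf", "knn",
                                                            "rf", "gnb"),
                                            K = 5, seed = 1, params = list()) {
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  per <- purrr::map(classifiers, function(family) {
    m <- fit_classifier(x, y, family, params[[family]] %||% list())
    permutation_importance(m, x, y, K = K, seed = seed + 1)
  })
  bind_rows(per) %>%
    group_by(.data$feature) %>%
    summarise(importance = mean(.data$importance), .groups = "drop") %>%
    arrange(dplyr::desc(.data$importance))
}
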