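# Low/high fatigue binary classification.
#
# Two cross-validation designs: intersubject (five-fold leave-subjects-out;
# scores binarised with the fixed rule 0-2 low / 3-6 high) and intrasubject
# (five-fold CV within each subject's windows; binarised after splitting,
# threshold = mean of the training scores, score > threshold = high). Per
# fold: training-median imputation, SMOTE oversampling of the training
# minority class to parity, standardisation with (post-SMOTE) training
# statistics, seeded shuffling; the test split is only imputed and scaled
# with training parameters, never resampled. Four classifier families (RBF
# SVM, kNN, random forest, Gaussian naive Bayes) are tuned by exhaustive
# grid search with inner stratified 10-fold CV scored by balanced accuracy.
# High fatigue is the positive class throughout.

#' Binarise fatigue scores
#'
#' @param scores integer scores 0-6.
#' @param scheme `"intersubject"` (fixed rule: 0-2 low, 3-6 high) or
#'   `"intrasubject"` (threshold = mean of `training_scores`; scores
#'   strictly above the threshold are high).
#' @param training_scores training-split scores (required for
#'   `"intrasubject"`).
#' @return factor with levels `c("low", "high")`.
#' @export
binarise_labels <- function(scores, scheme = c("intersubject", "intrasubject"),
                            training_scores = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "intersubject") {
    lab <- ifelse(scores >= 3, "high", "low")
  } else {
    if (is.null(training_scores)) {
      stop("intrasubject binarisation needs training_scores", call. = FALSE)
    }
    thr <- mean(training_scores)
    lab <- ifelse(scores > thr, "high", "low")
  }
  factor(lab, levels = c("low", "high"))
}

#' Cross-validation folds
#'
#' Intersubject: subjects are shuffled and split into `n_folds` groups; all
#' of a subject's windows share a side. Intrasubject: each subject's windows
#' are shuffled and split into `n_folds` near-equal folds (subjects with
#' fewer than 2 windows are skipped; folds may shrink to one test window).
#'
#' @param subject_ids subject id per row of the dataset.
#' @param scheme `"intersubject"` or `"intrasubject"`.
#' @param n_folds number of folds (5).
#' @param seed RNG seed for the shuffles.
#' @return list of folds, each `list(fold, subject, train, test)` with row
#'   indices; `subject` is `NA` for intersubject folds.
#' @export
make_folds <- function(subject_ids, scheme = c("intersubject", "intrasubject"),
                       n_folds = 5, seed = 1) {
  scheme <- match.arg(scheme)
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  folds <- list()
  if (scheme == "intersubject") {
    subj <- sample(unique(subject_ids))
    grp <- rep(seq_len(n_folds), length.out = length(subj))
    for (k in seq_len(n_folds)) {
      test_subj <- subj[grp == k]
      test <- which(subject_ids %in% test_subj)
      if (!length(test) || length(test) == length(subject_ids)) next
      folds[[length(folds) + 1]] <- list(fold = k, subject = NA_character_,
                                         train = setdiff(seq_along(subject_ids),
                                                         test),
                                         test = test)
    }
  } else {
    for (sid in unique(subject_ids)) {
      rows <- which(subject_ids == sid)
      if (length(rows) < 2) {
        message("subject ", sid, " skipped: fewer than 2 windows")
        next
      }
      rows <- sample(rows)
      k_eff <- min(n_folds, length(rows))
      grp <- rep(seq_len(k_eff), length.out = length(rows))
      for (k in seq_len(k_eff)) {
        test <- sort(rows[grp == k])
        folds[[length(folds) + 1]] <- list(fold = k, subject = sid,
                                           train = sort(rows[grp != k]),
                                           test = test)
      }
    }
  }
  folds
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Oversamples the minority class to exact parity by interpolating between a
#' random minority sample and one of its `k` nearest minority neighbours
#' (Euclidean distance).
#'
#' @param x numeric feature matrix.
#' @param y factor labels (two classes).
#' @param k neighbour count; reduced automatically to `minority - 1`.
#' @return `list(x, y)` with synthetic rows appended.
#' @export
smote_balance <- function(x, y, k = 5) {
  tab <- table(y)
  if (length(tab) < 2 || min(tab) < 2) {
    stop("SMOTE needs at least two samples in each class", call. = FALSE)
  }
  if (tab[1] == tab[2]) return(list(x = x, y = y))
  minority <- names(tab)[which.min(tab)]
  need <- abs(diff(tab))
  mi <- which(y == minority)
  xm <- x[mi, , drop = FALSE]
  k <- min(k, length(mi) - 1)
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- apply(d, 1, function(r) order(r)[seq_len(k)], simplify = FALSE)
  base_i <- sample.int(length(mi), need, replace = TRUE)
  syn <- t(vapply(base_i, function(i) {
    j <- nn[[i]][sample.int(k, 1)]
    u <- runif(1)
    xm[i, ] + u * (xm[j, ] - xm[i, ])
  }, numeric(ncol(x))))
  list(x = rbind(x, syn),
       y = factor(c(as.character(y), rep(minority, need)),
                  levels = levels(y)))
}

#' Prepare one cross-validation fold
#'
#' Training-median imputation, SMOTE to class parity, standardisation with
#' post-SMOTE training statistics, seeded row shuffle. The test split is
#' imputed and scaled with training-derived parameters only.
#'
#' @param train_x,test_x feature matrices.
#' @param train_y training labels (factor low/high).
#' @param smote_k SMOTE neighbour count.
#' @return list `train_x, train_y, test_x, params` (medians, centre, scale).
#' @export
preprocess_fold <- function(train_x, train_y, test_x, smote_k = 5) {
  med <- apply(train_x, 2, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  fill <- function(m) {
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- med[j]
    m
  }
  train_x <- fill(train_x)
  test_x <- fill(test_x)
  sm <- smote_balance(train_x, train_y, k = smote_k)
  centre <- colMeans(sm$x)
  scl <- apply(sm$x, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  zs <- function(m) sweep(sweep(m, 2, centre), 2, scl, "/")
  ord <- sample.int(nrow(sm$x))
  list(train_x = zs(sm$x)[ord, , drop = FALSE], train_y = sm$y[ord],
       test_x = zs(test_x),
       params = list(medians = med, centre = centre, scale = scl))
}

#' Classification metrics with high fatigue as the positive class
#'
#' precision = TP/(TP+FP), recall = TP/(TP+FN), balanced accuracy =
#' (TP/(TP+FN) + TN/(TN+FP)) / 2. Precision is `NA` when nothing is
#' predicted positive.
#'
#' @param truth,pred factors with levels `c("low", "high")`.
#' @return one-row tibble `precision, recall, balanced_accuracy`.
#' @export
evaluate_predictions <- function(truth, pred) {
  tp <- sum(truth == "high" & pred == "high")
  tn <- sum(truth == "low" & pred == "low")
  fp <- sum(truth == "low" & pred == "high")
  fn <- sum(truth == "high" & pred == "low")
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  tibble(precision = precision, recall = recall,
         balanced_accuracy = mean(c(sens, spec), na.rm = TRUE))
}

#' Hyperparameter grids
#'
#' The exhaustive grids searched per classifier family: SVM cost and gamma
#' over {1e-3 ... 1e3} (49 combinations), kNN k over
#' {1,2,3,4,5,6,8,10,15}, random forest trees over {5,10,50,100,200,500}
#' crossed with mtry rules {sqrt(N), log2(N), N} (18), and Gaussian naive
#' Bayes with no tuned parameter.
#'
#' @return named list of parameter tibbles.
#' @export
default_grids <- function() {
  pow <- 10^(-3:3)
  list(
    svm_rbf = tidyr::expand_grid(cost = pow, gamma = pow),
    knn = tibble(k = c(1, 2, 3, 4, 5, 6, 8, 10, 15)),
    rf = tidyr::expand_grid(ntree = c(5, 10, 50, 100, 200, 500),
                            mtry_rule = c("sqrt", "log2", "all")),
    gnb = tibble(.dummy = NA))
}

# fit one classifier family with given params; returns an object for
# predict_classifier()
fit_classifier <- function(x, y, family, params = list()) {
  obj <- switch(
    family,
    svm_rbf = e1071::svm(x, y, kernel = "radial",
                         cost = params$cost %||% 1,
                         gamma = params$gamma %||% (1 / ncol(x)),
                         scale = FALSE),
    knn = list(x = x, y = y, k = params$k %||% 5),
    rf = {
      mtry <- switch(params$mtry_rule %||% "sqrt",
                     sqrt = max(1, floor(sqrt(ncol(x)))),
                     log2 = max(1, floor(log2(ncol(x)))),
                     all = ncol(x))
      randomForest::randomForest(x, y, ntree = params$ntree %||% 100,
                                 mtry = mtry)
    },
    gnb = e1071::naiveBayes(x, y),
    stop("unknown classifier family: ", family, call. = FALSE))
  structure(list(family = family, fit = obj, params = params,
                 levels = levels(y)),
            class = "gait_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# class predictions; RF predicts by thresholding the forest's averaged
# probabilistic vote for the positive class at 0.5
predict_classifier <- function(model, x) {
  lev <- model$levels
  out <- switch(
    model$family,
    svm_rbf = as.character(predict(model$fit, x)),
    knn = as.character(class::knn(model$fit$x, x, model$fit$y,
                                  k = model$fit$k)),
    rf = {
      pr <- predict(model$fit, x, type = "prob")[, "high"]
      ifelse(pr > 0.5, "high", "low")
    },
    gnb = as.character(predict(model$fit, x)))
  factor(out, levels = lev)
}

# stratified k-fold assignment (vector of fold ids per row)
stratified_folds <- function(y, k) {
  out <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    out[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  out
}

#' Grid search with inner stratified cross-validation
#'
#' Scores every parameter combination by mean balanced accuracy over inner
#' stratified folds (combinations failing on a degenerate inner fold score 0
#' for that fold), then refits the best combination on the full training
#' split.
#'
#' @param x,y preprocessed training data.
#' @param family one of `"svm_rbf", "knn", "rf", "gnb"`.
#' @param grid parameter tibble (default from [default_grids()]).
#' @param inner_folds inner CV folds (10, reduced when a class is smaller).
#' @return list `model` (fitted on all of `x`), `params`, `cv_score`.
#' @export
grid_search_fit <- function(x, y, family, grid = NULL, inner_folds = 10) {
  if (is.null(grid)) grid <- default_grids()[[family]]
  k <- max(2, min(inner_folds, min(table(y))))
  fid <- stratified_folds(y, k)
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    params <- as.list(grid[g, , drop = FALSE])
    ba <- vapply(seq_len(k), function(f) {
      tr <- fid != f; te <- fid == f
      if (dplyr::n_distinct(y[tr]) < 2 || !any(te)) return(0)
      m <- tryCatch(fit_classifier(x[tr, , drop = FALSE], y[tr], family,
                                   params),
                    error = function(e) NULL)
      if (is.null(m)) return(0)
      p <- predict_classifier(m, x[te, , drop = FALSE])
      evaluate_predictions(y[te], p)$balanced_accuracy
    }, numeric(1))
    mean(ba)
  }, numeric(1))
  best <- which.max(scores)
  params <- as.list(grid[best, , drop = FALSE])
  list(model = fit_classifier(x, y, family, params), params = params,
       cv_score = scores[best])
}

#' Cross-validated low/high fatigue classification
#'
#' Runs the full protocol: fold construction, per-fold binarisation (for the
#' intrasubject scheme), preprocessing, per-family grid search and test-set
#' evaluation.
#'
#' @param data modelling table with `subject_id`, the score column and
#'   feature columns.
#' @param features feature column names.
#' @param score score column (`"pf_score"` or `"mf_score"`).
#' @param scheme `"intersubject"` or `"intrasubject"`.
#' @param classifiers families to evaluate.
#' @param n_folds outer folds (5).
#' @param inner_folds inner grid-search folds (10).
#' @param grids named list of parameter grids ([default_grids()]).
#' @param smote_k SMOTE neighbour count (5, auto-reduced).
#' @param seed seed driving fold shuffles, SMOTE, shuffling and the
#'   stochastic classifiers.
#' @return tibble of class `fatigue_cv`: one row per evaluated fold x
#'   classifier with metrics and chosen hyperparameters (list-column).
#'   Degenerate folds (a split lacking a class, or a training class too
#'   small for SMOTE) are skipped with a message.
#' @export
run_classification <- function(data, features, score = "pf_score",
                               scheme = c("intersubject", "intrasubject"),
                               classifiers = c("svm_rbf", "knn", "rf", "gnb"),
                               n_folds = 5, inner_folds = 10, grids = NULL,
                               smote_k = 5, seed = 1) {
  scheme <- match.arg(scheme)
  if (is.null(grids)) grids <- default_grids()
  d <- data[!is.na(data[[score]]), , drop = FALSE]
  x_all <- as.matrix(d[, features, drop = FALSE])
  scores <- d[[score]]
  folds <- make_folds(d$subject_id, scheme, n_folds, seed)
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed + 1)
  rows <- list()
  for (fd in folds) {
    if (scheme == "intersubject") {
      ytr <- binarise_labels(scores[fd$train], "intersubject")
      yte <- binarise_labels(scores[fd$test], "intersubject")
    } else {
      ytr <- binarise_labels(scores[fd$train], "intrasubject",
                             training_scores = scores[fd$train])
      yte <- binarise_labels(scores[fd$test], "intrasubject",
                             training_scores = scores[fd$train])
    }
    if (dplyr::n_distinct(ytr) < 2 || dplyr::n_distinct(yte) < 2) {
      message("fold skipped (", scheme, if (!is.na(fd$subject))
        paste0(", subject ", fd$subject) else "", ", fold ", fd$fold,
        "): not enough score range to form two classes")
      next
    }
    if (min(table(ytr)) < 2) {
      message("fold skipped: training class too small for SMOTE")
      next
    }
    prep <- preprocess_fold(x_all[fd$train, , drop = FALSE], ytr,
                            x_all[fd$test, , drop = FALSE], smote_k)
    for (family in classifiers) {
      gs <- grid_search_fit(prep$train_x, prep$train_y, family,
                            grids[[family]], inner_folds)
      pred <- predict_classifier(gs$model, prep$test_x)
      met <- evaluate_predictions(yte, pred)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble(scheme = scheme, score = score, subject = fd$subject,
               fold = fd$fold, classifier = family,
               n_train = length(fd$train), n_test = length(fd$test)),
        met,
        tibble(params = list(gs$params)))
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("fatigue_cv", class(out))
  out
}

#' @method glance fatigue_cv
#' @export
glance.fatigue_cv <- function(x, ...) {
  x %>%
    group_by(.data$scheme, .data$score, .data$classifier) %>%
    summarise(n_folds = dplyr::n(),
              mean_balanced_accuracy = mean(.data$balanced_accuracy),
              sd_balanced_accuracy = sd(.data$balanced_accuracy),
              max_balanced_accuracy = max(.data$balanced_accuracy),
              mean_precision = mean(.data$precision, na.rm = TRUE),
              mean_recall = mean(.data$recall, na.rm = TRUE),
              .groups = "drop")
}

#' @method tidy fatigue_cv
#' @export
tidy.fatigue_cv <- function(x, ...) {
  as_tibble(x)[, c("scheme", "score", "subject", "fold", "classifier",
                   "precision", "recall", "balanced_accuracy")]
}
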