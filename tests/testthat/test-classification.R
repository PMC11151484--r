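# small grids keep the unit tests fast; the full printed grids are exercised
# in the acceptance suite
small_grids <- function() {
  list(svm_rbf = tidyr::expand_grid(cost = c(0.1, 1, 10), gamma = c(0.1, 1)),
       knn = tibble::tibble(k = c(1, 3, 5)),
       rf = tidyr::expand_grid(ntree = c(50, 100), mtry_rule = c("sqrt", "all")),
       gnb = tibble::tibble(.dummy = NA))
}

test_that("binarisation rules match the published thresholds", {
  inter <- binarise_labels(0:6, "intersubject")
  expect_equal(as.character(inter),
               c("low", "low", "low", "high", "high", "high", "high"))
  intra <- binarise_labels(c(2, 3), "intrasubject",
                           training_scores = c(2, 2, 3, 2, 3))
  expect_equal(as.character(intra), c("low", "high")) # mean 2.4
  # scores equal to the training mean go to the low class
  eq <- binarise_labels(4, "intrasubject", training_scores = c(4, 4))
  expect_equal(as.character(eq), "low")
})

test_that("fold construction partitions subjects and balances window folds", {
  ids <- rep(sprintf("S%02d", 1:10), each = 7)
  folds <- make_folds(ids, "intersubject", seed = 3)
  expect_length(folds, 5)
  for (fd in folds) {
    expect_length(intersect(ids[fd$train], ids[fd$test]), 0)
    expect_equal(sort(c(fd$train, fd$test)), seq_along(ids))
    expect_length(unique(ids[fd$test]), 2) # 10 subjects over 5 folds
  }
  intra <- make_folds(ids, "intrasubject", seed = 3)
  sizes <- vapply(intra, function(f) length(f$test), integer(1))
  expect_true(max(sizes) - min(sizes) <= 1)
  expect_length(intra, 50)
  # too-few-window subjects are skipped
  expect_message(make_folds(c("A", rep("B", 6)), "intrasubject", seed = 1),
                 "skipped")
})

test_that("SMOTE reaches exact parity with interpolated minority points", {
  set.seed(8)
  x <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  y <- factor(rep(c("low", "high"), c(30, 10)), levels = c("low", "high"))
  out <- smote_balance(x, y, k = 5)
  expect_equal(as.integer(table(out$y)), c(30L, 30L))
  # synthetic points lie within the minority bounding box
  syn <- out$x[41:60, , drop = FALSE]
  mino <- x[y == "high", ]
  expect_true(all(syn[, 1] >= min(mino[, 1]) & syn[, 1] <= max(mino[, 1])))
  expect_error(smote_balance(x[1:3, ], factor(c("low", "low", "high"),
                                              levels = c("low", "high"))),
               "SMOTE")
})

test_that("fold preprocessing uses training information only", {
  set.seed(9)
  train_x <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("s2w", "vm")))
  train_x[c(3, 7), 1] <- NA
  train_y <- factor(rep(c("low", "high"), c(20, 10)),
                    levels = c("low", "high"))
  test_x <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("s2w", "vm")))
  test_x[2, 1] <- NA
  set.seed(100)
  prep <- preprocess_fold(train_x, train_y, test_x)
  med <- median(train_x[, 1], na.rm = TRUE)
  # test NA filled with the training median, then scaled
  expect_equal(prep$test_x[2, 1],
               (med - prep$params$centre[1]) / prep$params$scale[1])
  # post-SMOTE standardised training columns
  expect_equal(unname(colMeans(prep$train_x)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(prep$train_x, 2, sd)), c(1, 1), tolerance = 1e-9)
  expect_equal(as.integer(table(prep$train_y)), c(20L, 20L))

  # leakage probe: poisoning the test fold leaves training parameters alone
  poisoned <- test_x
  poisoned[, ] <- 1e6
  set.seed(100)
  prep2 <- preprocess_fold(train_x, train_y, poisoned)
  expect_identical(prep2$params, prep$params)
  expect_identical(prep2$train_x, prep$train_x)
})

test_that("metrics match the confusion-matrix arithmetic", {
  truth <- factor(rep(c("high", "low"), c(4, 6)), levels = c("low", "high"))
  pred <- factor(c("high", "high", "high", "low",
                   "high", "low", "low", "low", "low", "low"),
                 levels = c("low", "high"))
  m <- evaluate_predictions(truth, pred) # TP=3 FN=1 FP=1 TN=5
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$balanced_accuracy, 0.5 * (3 / 4 + 5 / 6), tolerance = 1e-12)

  perfect <- evaluate_predictions(truth, truth)
  expect_equal(unlist(perfect), c(precision = 1, recall = 1,
                                  balanced_accuracy = 1))
  allpos <- evaluate_predictions(
    factor(rep(c("low", "high"), 5), levels = c("low", "high")),
    factor(rep("high", 10), levels = c("low", "high")))
  expect_equal(allpos$balanced_accuracy, 0.5)
  # undefined precision when nothing is predicted positive
  nopos <- evaluate_predictions(truth,
                                factor(rep("low", 10),
                                       levels = c("low", "high")))
  expect_true(is.na(nopos$precision))
})

test_that("the printed grids have the documented sizes", {
  g <- default_grids()
  expect_equal(nrow(g$svm_rbf), 49)
  expect_equal(nrow(g$knn), 9)
  expect_equal(nrow(g$rf), 18)
  expect_equal(nrow(g$gnb), 1)
})

test_that("every family separates two well-separated Gaussian blobs", {
  tc <- toy_classes(n = 160, sep = 6, seed = 13)
  set.seed(13)
  hold <- sample(160, 40)
  for (family in c("svm_rbf", "knn", "rf", "gnb")) {
    gs <- grid_search_fit(tc$x[-hold, ], tc$y[-hold], family,
                          grid = small_grids()[[family]], inner_folds = 5)
    ba <- evaluate_predictions(
      tc$y[hold], gaitfatigue:::predict_classifier(gs$model, tc$x[hold, ]))$balanced_accuracy
    expect_gte(ba, 0.95)
  }
})

test_that("run_classification returns per-fold metrics for both schemes", {
  d <- simulate_feature_windows(10, 12, n_features = 3, coupling_beta = 2,
                                seed = 14)
  cv <- suppressMessages(
    run_classification(d, c("f1", "f2", "f3"), "pf_score", "intersubject",
                       classifiers = c("knn", "gnb"), grids = small_grids(),
                       inner_folds = 5, seed = 15))
  expect_s3_class(cv, "fatigue_cv")
  expect_true(all(cv$balanced_accuracy >= 0 & cv$balanced_accuracy <= 1))
  expect_setequal(unique(cv$classifier), c("knn", "gnb"))
  gl <- glance(cv)
  expect_true(all(c("mean_balanced_accuracy", "max_balanced_accuracy") %in%
                    names(gl)))
  cv2 <- suppressMessages(
    run_classification(d, c("f1", "f2", "f3"), "pf_score", "intrasubject",
                       classifiers = "knn", grids = small_grids(),
                       inner_folds = 3, seed = 16))
  expect_true(all(!is.na(cv2$subject)))
  expect_gt(mean(cv2$balanced_accuracy), 0.6) # strong coupling is learnable
})

test_that("folds without two classes in both splits are skipped", {
  d <- simulate_feature_windows(6, 10, n_features = 2, seed = 17)
  d$pf_score[d$subject_id == "S001"] <- 4L # constant: no class range
  expect_message(
    cv <- run_classification(d, c("f1", "f2"), "pf_score", "intrasubject",
                             classifiers = "gnb", grids = small_grids(),
                             inner_folds = 3, seed = 18),
    "not enough score range")
  expect_false("S001" %in% cv$subject)
})
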