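study <- small_study(seed = 7, vpfd = 40)
fl_table <- study$voxel_tables$FL

test_that("the stratified split is disjoint, exhaustive and reproducible", {
  sp <- split_train_test(fl_table, 0.8, seed = 2)
  expect_identical(sort(c(sp$train_idx, sp$test_idx)), seq_len(nrow(fl_table)))
  expect_length(intersect(sp$train_idx, sp$test_idx), 0L)
  # 200 rows, 5 balanced classes -> 160/40, 32/8 per class
  expect_identical(nrow(sp$train), 160L)
  expect_identical(nrow(sp$test), 40L)
  expect_true(all(table(sp$train$day) == 32L))
  expect_true(all(table(sp$test$day) == 8L))

  sp2 <- split_train_test(fl_table, 0.8, seed = 2)
  expect_identical(sp$train_idx, sp2$train_idx)

  one_row <- subset_one <- fl_table[c(1, which(fl_table$day == 3)), ]
  expect_error(split_train_test(one_row, 0.8, 1), "at least 2 rows")
})

test_that("base models fit, predict and behave on degenerate geometries", {
  # linearly separable two-class toy table
  set.seed(4)
  X <- rbind(matrix(rnorm(100, 0, 0.2), 20, 5),
             matrix(rnorm(100, 5, 0.2), 20, 5))
  toy <- new_voxel_table(
    meta = data.frame(voxel_id = as.character(1:40), fillet_id = 1,
                      species = "s", day = rep(c(1, 7), each = 20),
                      block_row = 1, block_col = 1, kept = TRUE),
    spectra = X, wavelengths = seq(438, 718, length.out = 5), mode = "FL")
  lda_m <- fit_model("LDA", toy)
  expect_identical(mean(as.character(predict(lda_m, toy)) ==
                          as.character(toy$day)), 1)

  knn1 <- fit_model(model_spec("KNN", list(k = 1)), toy)
  expect_identical(mean(as.character(predict(knn1, toy)) ==
                          as.character(toy$day)), 1)

  expect_error(fit_model("ELM", toy), "unknown model")
  expect_identical(model_spec("LR")$hyperparameters$max_iterations, 1000L)
})

test_that("permuted labels drop cross-validated accuracy to the chance band", {
  permuted <- fl_table
  set.seed(10)
  permuted$day <- sample(permuted$day)
  cv <- suppressWarnings(crossval(permuted, "LDA", k = 5, seed = 3))
  expect_lt(cv$mean_accuracy,
            null_band_upper(nrow(permuted), 5) + 0.05)
  expect_gt(cv$mean_accuracy, 0.05)
})

test_that("every classifier beats the permutation-null band on default synthetic data", {
  big <- small_study(seed = 21, vpfd = 85)$voxel_tables$FL
  sp <- split_train_test(big, 0.8, seed = 5)
  band <- null_band_upper(nrow(sp$test), 5)
  for (name in c("DT", "RF", "NB", "KNN", "LDA", "QDA", "SVC", "LR",
                 "STACKING")) {
    m <- suppressWarnings(fit_model(model_spec(name, seed = 6), sp$train))
    acc <- accuracy(evaluate_model(m, sp$test))
    expect_gt(acc, band)
  }
})

test_that("stacking has the documented architecture and does not touch test rows", {
  sp <- split_train_test(fl_table, 0.8, seed = 2)
  # warm-up fit: lazy byte-compilation of captured closures must not
  # differentiate the serialized models compared below
  invisible(suppressWarnings(fit_stacking(sp$train, seed = 3)))
  st <- suppressWarnings(fit_stacking(sp$train, seed = 3))
  expect_identical(st$meta_feature_width,
                   length(table_wavelengths(fl_table)) + 3L)
  expect_named(st$base_models, c("LR", "RF", "KNN"))

  # leakage: shuffling test labels cannot change the fitted model
  test_shuffled <- sp$test
  test_shuffled$day <- sample(test_shuffled$day)
  st2 <- suppressWarnings(fit_stacking(sp$train, seed = 3))
  expect_identical(serialize(st, NULL), serialize(st2, NULL))

  # near-separable synthetic data is classified perfectly
  acc <- accuracy(evaluate_model(st, sp$test))
  expect_identical(acc, 1)
})

test_that("appending predictions to the features outperforms predictions-only stacking", {
  noisy <- small_study(seed = 31, vpfd = 40, noise_sd = 0.35)$voxel_tables$FL
  sp <- split_train_test(noisy, 0.8, seed = 4)
  st <- suppressWarnings(fit_stacking(sp$train, seed = 5))
  acc_aug <- accuracy(evaluate_model(st, sp$test))

  # predictions-only variant, same base models; prediction columns that are
  # constant within classes (a base model reproducing its training labels)
  # give the variant's LDA nothing to work with and are unusable
  train_pred <- vapply(st$base_models, function(m)
    as.numeric(as.character(predict(m, sp$train))), numeric(nrow(sp$train)))
  test_pred <- vapply(st$base_models, function(m)
    as.numeric(as.character(predict(m, sp$test))), numeric(nrow(sp$test)))
  y <- factor(sp$train$day)
  wvar <- Reduce(`+`, lapply(split(seq_len(nrow(train_pred)), y), function(ix)
    colSums(scale(train_pred[ix, , drop = FALSE], scale = FALSE)^2)))
  usable <- wvar > 1e-12 * max(wvar, 1e-300)
  acc_only <- if (any(usable)) {
    meta_only <- MASS::lda(train_pred[, usable, drop = FALSE], grouping = y)
    mean(as.character(predict(meta_only,
                              test_pred[, usable, drop = FALSE])$class) ==
           as.character(sp$test$day))
  } else { # no informative meta-feature: majority-class verdict
    mean(as.character(sp$test$day) == names(which.max(table(y))))
  }
  expect_gte(acc_aug, acc_only)
})

test_that("cross-validation folds partition the data and score perfectly when separable", {
  cv <- suppressWarnings(crossval(fl_table, "LDA", k = 5, seed = 1))
  expect_length(cv$fold_accuracy, 5L)
  expect_identical(sort(unique(cv$folds)), 1:5)
  expect_identical(tabulate(cv$folds), rep(40L, 5))
  expect_true(all(cv$fold_accuracy >= 0 & cv$fold_accuracy <= 1))
  expect_identical(cv$mean_accuracy, 1) # clean synthetic data separates
  expect_error(crossval(fl_table, "LDA", k = 45), ">= k")
})

test_that("confusion matrices count correctly and drive all accuracy variants", {
  cm <- confusion_matrix(true = c(1, 1, 3, 3, 7), predicted = c(1, 3, 3, 3, 7),
                         class_days = c(1, 3, 7))
  expect_equal(unname(rowSums(cm)), c(2, 2, 1))
  expect_equal(accuracy(cm), 4 / 5)
  expect_error(confusion_matrix(true = 1, predicted = 9, class_days = c(1, 3)),
               "outside")

  # perfect predictions give a diagonal matrix
  sp <- split_train_test(fl_table, 0.8, seed = 2)
  m <- fit_model("LDA", sp$train)
  cmx <- evaluate_model(m, sp$test)
  expect_equal(unname(rowSums(cmx)),
               unname(as.numeric(table(sp$test$day))))
  expect_identical(sum(cmx) - sum(diag(cmx)), 0L)
})

test_that("tolerance accuracy respects day gaps and is monotone in the tolerance", {
  cm <- sablefish_fusion_confusion()
  expect_equal(tolerance_accuracy(cm, 0), accuracy(cm))
  # alternate-day classes: one-day tolerance equals exact accuracy
  expect_equal(tolerance_accuracy(cm, 1), accuracy(cm))
  accs <- vapply(0:10, function(t) tolerance_accuracy(cm, t), numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_error(tolerance_accuracy(cm, -1), "non-negative")

  # adjacent-day errors forgiven at tolerance 1 on a daily grid
  daily <- confusion_matrix(counts = matrix(c(5, 2, 0, 1, 5, 1, 0, 2, 5), 3,
                                            byrow = TRUE),
                            class_days = 1:3)
  expect_equal(tolerance_accuracy(daily, 1), 1)
})

test_that("grade grouping collapses the matrix and can only help accuracy", {
  cm <- sablefish_fusion_confusion()
  days <- c(1, 3, 7, 9, 11)
  identity_map <- setNames(as.character(days), days)
  expect_equal(grouped_accuracy(cm, identity_map), accuracy(cm))

  g2 <- grade_grouping(days, fresh_until = 5)
  expect_equal(grouped_accuracy(cm, g2), 1)
  g3 <- grade_grouping(days, fresh_until = 5, fairly_until = 7)
  expect_equal(round(100 * grouped_accuracy(cm, g3)), 96)
  expect_gte(grouped_accuracy(cm, g3), accuracy(cm))
  expect_error(grouped_accuracy(cm, g2[-1]), "missing")
})
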