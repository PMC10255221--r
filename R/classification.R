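MODEL_NAMES <- c("DT", "RF", "NB", "KNN", "LDA", "QDA", "SVC", "LR",
                 "STACKING")

#' Classifier specifications
#'
#' A thin, reproducible description of a freshness-day classifier. Models
#' run with the conventional default settings of their underlying packages,
#' pinned here so results are stable across library versions; the one
#' deliberate exception is logistic regression, which uses 1000 iterations.
#'
#' @param name One of `"DT"` (decision tree), `"RF"` (random forest),
#'   `"NB"` (naive Bayes), `"KNN"`, `"LDA"`, `"QDA"`, `"SVC"` (RBF support
#'   vector classifier), `"LR"` (multinomial logistic regression) or
#'   `"STACKING"` (see [fit_stacking()]).
#' @param hyperparameters Named list overriding defaults (`k` for KNN,
#'   `ntree` for RF, `max_iterations` for LR, ...).
#' @param seed Integer seed used when fitting stochastic models.
#' @export
model_spec <- function(name, hyperparameters = list(), seed = 1L) {
  name <- toupper(name)
  if (!name %in% MODEL_NAMES)
    stop_f("unknown model '%s' (expected one of %s)", name,
           paste(MODEL_NAMES, collapse = ", "))
  defaults <- switch(name,
    KNN = list(k = 5L),
    RF = list(ntree = 500L),
    LR = list(max_iterations = 1000L),
    list())
  structure(list(name = name,
                 hyperparameters = utils::modifyList(defaults, hyperparameters),
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Stratified train/test split of a voxel table
#'
#' Splits the rows into disjoint, exhaustive train and test sets, sampling
#' `train_frac` of each day class (stratified, so no class can fall out of
#' the training set at small sample sizes).
#'
#' @param table A `voxel_table` with a `day` column.
#' @param train_frac Training fraction (default 0.8).
#' @param seed Integer seed; identical seeds reproduce the split.
#' @return List with `train` and `test` voxel tables and the integer row
#'   indices `train_idx`, `test_idx`.
#' @export
split_train_test <- function(table, train_frac = 0.8, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) stop_f("`train_frac` must be in (0,1)")
  counts <- table(table$day)
  if (any(counts < 2L))
    stop_f("every day class needs at least 2 rows (day %s has %d)",
           names(counts)[which.min(counts)], min(counts))
  train_idx <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(table)), table$day), function(ix)
      sort(sample(ix, floor(train_frac * length(ix))))), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(nrow(table)), train_idx)
  list(train = subset_voxel_table(table, train_idx),
       test = subset_voxel_table(table, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Fit a freshness-day classifier
#'
#' Trains the classifier described by `spec` on the band columns of `train`
#' against its `day` labels. The returned object predicts day labels with
#' [predict.freshspec_model()].
#'
#' @param spec A [model_spec()] (or a model name string).
#' @param train Training `voxel_table`.
#' @return Object of class `freshspec_model`.
#' @export
fit_model <- function(spec, train) {
  if (is.character(spec)) spec <- model_spec(spec)
  if (!nrow(train)) stop_f("empty training table")
  y <- factor(train$day)
  if (nlevels(y) < 2L) stop_f("training data must contain >= 2 day classes")
  if (spec$name == "STACKING") return(fit_stacking(train, seed = spec$seed))
  X <- spectra_matrix(train)
  colnames(X) <- make.names(colnames(X))
  hp <- spec$hyperparameters
  df <- data.frame(.day = y, X, check.names = FALSE)

  fitted <- with_seed(spec$seed, switch(spec$name,
    DT = rpart::rpart(.day ~ ., data = df, method = "class"),
    RF = randomForest::randomForest(x = X, y = y, ntree = hp$ntree),
    NB = e1071::naiveBayes(x = as.data.frame(X), y = y),
    KNN = list(X = X, y = y, k = hp$k),
    LDA = MASS::lda(X, grouping = y),
    QDA = tryCatch(MASS::qda(X, grouping = y), error = function(e)
      stop_f(paste("QDA failed (%s); the within-class covariance is likely",
                   "singular - reduce dimensionality or regularize"),
             conditionMessage(e))),
    SVC = e1071::svm(x = X, y = y),
    LR = nnet::multinom(.day ~ ., data = df, maxit = hp$max_iterations,
                        MaxNWts = 1e6, trace = FALSE)
  ))
  structure(list(spec = spec, fitted = fitted, classes = levels(y),
                 features = colnames(X)),
            class = "freshspec_model")
}

#' @rdname fit_model
#' @param object A fitted `freshspec_model`.
#' @param newdata A `voxel_table` or spectra matrix.
#' @param ... Unused.
#' @export
predict.freshspec_model <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) spectra_matrix(newdata) else as.matrix(newdata)
  colnames(X) <- object$features
  f <- object$fitted
  lab <- switch(object$spec$name,
    DT = as.character(predict(f, as.data.frame(X), type = "class")),
    RF = as.character(predict(f, X)),
    NB = as.character(predict(f, as.data.frame(X))),
    # seed the vote tie-break so predictions are reproducible
    KNN = as.character(with_seed(object$spec$seed,
                                 class::knn(f$X, X, f$y, k = f$k))),
    LDA = as.character(predict(f, X)$class),
    QDA = as.character(predict(f, X)$class),
    SVC = as.character(predict(f, X)),
    LR = as.character(predict(f, as.data.frame(X)))
  )
  factor(lab, levels = object$classes)
}

#' Stacked-generalization ensemble
#'
#' The single-mode ensemble: logistic regression, random forest and KNN are
#' fitted on the training spectra as base models, their predicted day labels
#' on the training rows are appended to the original feature block as three
#' extra numeric columns, and a linear discriminant analysis meta-model is
#' trained on this augmented matrix (original bands + 3 predictions).
#' Prediction applies the same augmentation. Training the meta-model on the
#' base predictions alone is deliberately not done - appending them to the
#' original features is what preserves accuracy.
#'
#' @param train Training `voxel_table`.
#' @param seed Integer seed for the stochastic base models.
#' @return Object of class `stacked_model` (also a `freshspec_model`) with
#'   `base_models`, `meta_model` and `meta_feature_width`.
#' @export
fit_stacking <- function(train, seed = 1L) {
  y <- factor(train$day)
  if (nlevels(y) < 2L) stop_f("training data must contain >= 2 day classes")
  base_specs <- list(LR = model_spec("LR", seed = seed),
                     RF = model_spec("RF", seed = seed),
                     KNN = model_spec("KNN", seed = seed))
  base_models <- lapply(base_specs, fit_model, train = train)
  X <- spectra_matrix(train)
  aug <- augment_with_predictions(X, base_models, train)
  # columns with zero within-class variance (e.g. a base model predicting
  # the training labels perfectly) carry no discriminant information and
  # would make the LDA scatter singular; fit the meta-model without them
  wvar <- Reduce(`+`, lapply(split(seq_len(nrow(aug)), y), function(ix)
    colSums(scale(aug[ix, , drop = FALSE], scale = FALSE)^2)))
  usable <- wvar > 1e-12 * max(wvar)
  meta <- MASS::lda(aug[, usable, drop = FALSE], grouping = y)
  structure(list(spec = model_spec("STACKING", seed = seed),
                 base_models = base_models, meta_model = meta,
                 classes = levels(y),
                 features = colnames(X),
                 meta_usable = usable,
                 meta_feature_width = ncol(aug)),
            class = c("stacked_model", "freshspec_model"))
}

augment_with_predictions <- function(X, base_models, newdata) {
  preds <- vapply(base_models, function(m)
    as.numeric(as.character(predict(m, newdata))), numeric(nrow(X)))
  colnames(preds) <- paste0("pred_", tolower(names(base_models)))
  cbind(X, preds)
}

#' @export
predict.stacked_model <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) spectra_matrix(newdata) else as.matrix(newdata)
  aug <- augment_with_predictions(X, object$base_models, newdata)
  aug <- aug[, object$meta_usable, drop = FALSE]
  factor(as.character(predict(object$meta_model, aug)$class),
         levels = object$classes)
}

#' Stratified k-fold cross-validation
#'
#' Splits the rows into `k` stratified folds, refits the model (including
#' all base models of a stacker) within each training fold, and returns the
#' held-out accuracy of each fold.
#'
#' @param table A `voxel_table`.
#' @param spec A [model_spec()] or model name.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return List with `fold_accuracy` (length `k`) and `mean_accuracy`.
#' @export
crossval <- function(table, spec, k = 5L, seed = 1L) {
  if (is.character(spec)) spec <- model_spec(spec)
  if (k < 2L) stop_f("`k` must be >= 2")
  counts <- table(table$day)
  if (any(counts < k))
    stop_f("every class needs >= k rows for %d-fold CV", k)
  folds <- with_seed(seed, {
    f <- integer(nrow(table))
    for (ix in split(seq_len(nrow(table)), table$day))
      f[ix] <- sample(rep_len(seq_len(k), length(ix)))
    f
  })
  acc <- vapply(seq_len(k), function(i) {
    tr <- subset_voxel_table(table, folds != i)
    te <- subset_voxel_table(table, folds == i)
    m <- fit_model(spec, tr)
    mean(as.character(predict(m, te)) == as.character(te$day))
  }, numeric(1))
  list(fold_accuracy = acc, mean_accuracy = mean(acc), folds = folds)
}
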