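#' Confusion matrices over freshness-day classes
#'
#' `confusion_matrix()` builds a true-day x predicted-day count matrix over
#' an ordered set of day classes, either from two label vectors or from a
#' pre-tabulated count matrix. `evaluate_model()` produces one from a fitted
#' classifier and a test table.
#'
#' @param true,predicted Day labels (vectors of equal length), or `counts`
#'   given directly.
#' @param counts Square count matrix (rows = true, cols = predicted).
#' @param class_days Ordered numeric day values; default the sorted unique
#'   true labels.
#' @return Object of class `confusion_matrix`: integer matrix with
#'   `class_days` attribute.
#' @export
confusion_matrix <- function(true = NULL, predicted = NULL, counts = NULL,
                             class_days = NULL) {
  if (is.null(counts)) {
    true <- as.numeric(as.character(true))
    predicted <- as.numeric(as.character(predicted))
    if (length(true) != length(predicted)) stop_f("label length mismatch")
    class_days <- sort(class_days %||% unique(true))
    if (!all(predicted %in% class_days))
      stop_f("predicted label outside the class-day set")
    counts <- table(factor(true, levels = class_days),
                    factor(predicted, levels = class_days))
    counts <- matrix(as.integer(counts), length(class_days),
                     dimnames = dimnames(counts))
  } else {
    counts <- as.matrix(counts)
    if (nrow(counts) != ncol(counts)) stop_f("`counts` must be square")
    if (any(counts < 0)) stop_f("negative counts")
    class_days <- sort(class_days %||% as.numeric(rownames(counts)))
    if (length(class_days) != nrow(counts) || any(is.na(class_days)))
      stop_f("`class_days` must give one day per row")
    dimnames(counts) <- list(class_days, class_days)
  }
  structure(counts, class_days = as.numeric(class_days),
            class = c("confusion_matrix", class(counts)))
}

#' @rdname confusion_matrix
#' @param model A fitted `freshspec_model`.
#' @param test Test `voxel_table`.
#' @export
evaluate_model <- function(model, test) {
  if (!nrow(test)) stop_f("empty test table")
  pred <- predict(model, test)
  confusion_matrix(test$day, pred,
                   class_days = sort(unique(c(test$day,
                                              as.numeric(model$classes)))))
}

#' Accuracy metrics on a confusion matrix
#'
#' `accuracy()` is the exact-class hit rate (trace over total).
#' `tolerance_accuracy()` counts a prediction as correct when the predicted
#' day is within `tolerance_days` of the true day - the natural metric for
#' ordinal day classes; with alternate-day classes (minimum gap 2) a one-day
#' tolerance coincides with exact accuracy. `grouped_accuracy()` collapses
#' days into freshness grades (e.g. fresh / fairly fresh / spoilt) on both
#' axes and returns the hit rate of the collapsed matrix.
#'
#' @param cm A [confusion_matrix()].
#' @export
accuracy <- function(cm) sum(diag(cm)) / sum(cm)

#' @rdname accuracy
#' @param tolerance_days Non-negative day tolerance (default 1).
#' @export
tolerance_accuracy <- function(cm, tolerance_days = 1) {
  if (tolerance_days < 0) stop_f("`tolerance_days` must be non-negative")
  days <- attr(cm, "class_days")
  ok <- abs(outer(days, days, `-`)) <= tolerance_days
  sum(cm[ok]) / sum(cm)
}

#' @rdname accuracy
#' @param grouping Named character/factor vector mapping each day (names)
#'   to a grade label, e.g. `c("1"="fresh","3"="fresh","7"="spoilt",...)`.
#' @export
grouped_accuracy <- function(cm, grouping) {
  days <- attr(cm, "class_days")
  g <- grouping[as.character(days)]
  if (any(is.na(g)))
    stop_f("grouping is missing day(s): %s",
           paste(days[is.na(g)], collapse = ", "))
  grades <- unique(g)
  collapsed <- matrix(0, length(grades), length(grades),
                      dimnames = list(grades, grades))
  for (i in seq_along(days)) for (j in seq_along(days))
    collapsed[g[i], g[j]] <- collapsed[g[i], g[j]] + cm[i, j]
  sum(diag(collapsed)) / sum(collapsed)
}

#' Standard freshness-grade groupings
#'
#' Convenience constructors for the groupings used in reporting: two grades
#' (fresh = days up to `fresh_until`, spoilt after) and three grades
#' (fresh, fairly fresh, spoilt).
#'
#' @param days The day classes to cover.
#' @param fresh_until Last day still graded fresh (default 5).
#' @param fairly_until Last day graded fairly fresh in the 3-grade map
#'   (default 7).
#' @return Named character vector usable as `grouping` in
#'   [grouped_accuracy()].
#' @export
grade_grouping <- function(days, fresh_until = 5, fairly_until = NULL) {
  g <- ifelse(days <= fresh_until, "fresh",
              ifelse(!is.null(fairly_until) & days <= (fairly_until %||% -Inf),
                     "fairly_fresh", "spoilt"))
  stats::setNames(g, days)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> days {%s}, accuracy %.1f%%\n",
              paste(attr(x, "class_days"), collapse = ","),
              100 * accuracy(x)))
  print(unclass(x))
  invisible(x)
}
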