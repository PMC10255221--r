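#' Per-mode predictions ready for fusion
#'
#' Bundles the predicted and true day labels of one spectral mode's test
#' units, aligned by index across modes.
#'
#' @param mode Spectral mode tag.
#' @param predicted_day,true_day Equal-length day label vectors.
#' @param level `"voxel"` or `"fillet"`.
#' @export
mode_predictions <- function(mode, predicted_day, true_day,
                             level = c("voxel", "fillet")) {
  level <- match.arg(level)
  predicted_day <- as.numeric(as.character(predicted_day))
  true_day <- as.numeric(as.character(true_day))
  if (length(predicted_day) != length(true_day))
    stop_f("predicted/true length mismatch")
  structure(list(mode = match_mode(mode), predicted_day = predicted_day,
                 true_day = true_day, level = level),
            class = "mode_predictions")
}

#' Decision-level fusion by majority vote with SWIR tie-break
#'
#' Combines the day predictions of the three spectral modes unit by unit:
#' the fused label is the one predicted by at least two modes; when all
#' three disagree, the prediction of the tie-break mode (SWIR by default,
#' the mode with the consistently highest single-mode accuracy) is used.
#'
#' @param fl,vis,swir [mode_predictions()] of equal length with identical
#'   true labels.
#' @param tiebreak_mode Mode whose label wins three-way disagreements.
#' @return Object of class `fusion_result`: `fused_day`, `tie_break_used`
#'   (logical per unit, true only when all three modes disagree), `true_day`
#'   and `confusion`.
#' @export
fuse_votes <- function(fl, vis, swir, tiebreak_mode = "SWIR") {
  preds <- list(FL = fl, VISNIR = vis, SWIR = swir)
  n <- length(fl$predicted_day)
  if (length(vis$predicted_day) != n || length(swir$predicted_day) != n)
    stop_f("mode prediction lengths differ")
  truth <- fl$true_day
  if (!isTRUE(all.equal(truth, vis$true_day)) ||
      !isTRUE(all.equal(truth, swir$true_day)))
    stop_f("true labels differ across modes; units are not aligned")
  tiebreak_mode <- match_mode(tiebreak_mode)
  P <- cbind(fl$predicted_day, vis$predicted_day, swir$predicted_day)
  tb <- preds[[tiebreak_mode]]$predicted_day
  fused <- numeric(n)
  tie <- logical(n)
  for (i in seq_len(n)) {
    tab <- table(P[i, ])
    if (max(tab) >= 2) {
      fused[i] <- as.numeric(names(tab)[which.max(tab)])
    } else {
      fused[i] <- tb[i]
      tie[i] <- TRUE
    }
  }
  structure(list(fused_day = fused, tie_break_used = tie, true_day = truth,
                 tiebreak_mode = tiebreak_mode,
                 confusion = confusion_matrix(truth, fused,
                   class_days = sort(unique(c(truth, fused))))),
            class = "fusion_result")
}

#' Accuracy of a repeated-measurement majority vote
#'
#' The probability that the majority of `n` independent measurements, each
#' correct with probability `p`, yields the correct verdict:
#' `sum_{k > n/2} C(n,k) p^k (1-p)^(n-k)`. Three measurements at 95%
#' already exceed 99%.
#'
#' @param p Per-measurement accuracy in `[0, 1]`.
#' @param n Odd number of measurements.
#' @return Majority-vote accuracy as a fraction.
#' @export
repeat_measure_accuracy <- function(p, n = 3L) {
  assert_scalar_number(p, "p")
  if (p < 0 || p > 1) stop_f("`p` must be in [0, 1]")
  if (n < 1L || n %% 2L == 0L) stop_f("`n` must be odd and >= 1")
  k <- seq(floor(n / 2) + 1L, n)
  sum(choose(n, k) * p^k * (1 - p)^(n - k))
}

#' Per-mode and fused accuracy report
#'
#' Assembles the full accuracy surface for a test fillet: per-mode and
#' fused exact, one-day-tolerance, three-grade and two-grade accuracies,
#' with all confusion matrices, at the voxel level and aggregated to
#' fillet-day verdicts (majority over the voxels of each true day). The
#' report is a plain list; [write_report()] serialises it as JSON plus a
#' small markdown summary, byte-identically for identical inputs.
#'
#' @param mode_preds Named list of [mode_predictions()] (FL, VISNIR, SWIR).
#' @param fused A [fuse_votes()] result.
#' @param grouping2,grouping3 Day-to-grade maps for the two- and three-grade
#'   accuracies (see [grade_grouping()]).
#' @return Object of class `fillet_report`.
#' @export
fillet_report <- function(mode_preds, fused, grouping2, grouping3) {
  all_cd <- sort(unique(fused$true_day))
  metric_block <- function(true, pred) {
    cm <- confusion_matrix(true, pred,
                           class_days = sort(unique(c(all_cd, pred))))
    list(confusion = cm,
         exact = accuracy(cm),
         tolerance_1day = tolerance_accuracy(cm, 1),
         three_grade = grouped_accuracy(cm, grouping3),
         two_grade = grouped_accuracy(cm, grouping2))
  }
  per_mode <- lapply(mode_preds, function(mp)
    metric_block(mp$true_day, mp$predicted_day))
  fused_block <- metric_block(fused$true_day, fused$fused_day)

  # fillet-day aggregate: majority voxel verdict per true day
  agg <- function(true, pred) {
    vapply(split(pred, true), function(v) {
      tab <- table(v)
      as.numeric(names(tab)[which.max(tab)])
    }, numeric(1))
  }
  fillet_day <- list(
    per_mode = lapply(mode_preds, function(mp) {
      v <- agg(mp$true_day, mp$predicted_day)
      mean(v == as.numeric(names(v)))
    }),
    fused = {
      v <- agg(fused$true_day, fused$fused_day)
      mean(v == as.numeric(names(v)))
    })

  structure(list(per_mode = per_mode, fused = fused_block,
                 fillet_day_accuracy = fillet_day,
                 tie_break_rate = mean(fused$tie_break_used),
                 class_days = all_cd),
            class = "fillet_report")
}

#' @rdname fillet_report
#' @param report A `fillet_report`.
#' @param path Output path without extension; writes `<path>.json` and
#'   `<path>.md`.
#' @export
write_report <- function(report, path) {
  to_plain <- function(x) {
    if (inherits(x, "confusion_matrix")) {
      m <- unclass(x); attr(m, "class_days") <- NULL
      return(list(class_days = report$class_days,
                  counts = matrix(as.integer(m), nrow(m))))
    }
    if (is.list(x)) return(lapply(x, to_plain))
    x
  }
  jsonlite::write_json(to_plain(unclass(report)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  md <- c("# Freshness classification report", "",
          sprintf("Day classes: %s", paste(report$class_days, collapse = ", ")),
          "", "| set | exact | +/-1 day | 3-grade | 2-grade |",
          "|---|---|---|---|---|")
  fmt <- function(name, b) sprintf("| %s | %.1f%% | %.1f%% | %.1f%% | %.1f%% |",
                                   name, 100 * b$exact, 100 * b$tolerance_1day,
                                   100 * b$three_grade, 100 * b$two_grade)
  for (m in names(report$per_mode)) md <- c(md, fmt(m, report$per_mode[[m]]))
  md <- c(md, fmt("FUSED", report$fused), "",
          sprintf("Tie-break used on %.2f%% of units.",
                  100 * report$tie_break_rate))
  writeLines(md, paste0(path, ".md"))
  invisible(c(paste0(path, ".json"), paste0(path, ".md")))
}

#' @export
print.fillet_report <- function(x, ...) {
  cat(sprintf("<fillet_report> days {%s}\n",
              paste(x$class_days, collapse = ",")))
  for (m in names(x$per_mode))
    cat(sprintf("  %-6s exact %5.1f%%  3-grade %5.1f%%  2-grade %5.1f%%\n", m,
                100 * x$per_mode[[m]]$exact, 100 * x$per_mode[[m]]$three_grade,
                100 * x$per_mode[[m]]$two_grade))
  cat(sprintf("  FUSED  exact %5.1f%%  3-grade %5.1f%%  2-grade %5.1f%%\n",
              100 * x$fused$exact, 100 * x$fused$three_grade,
              100 * x$fused$two_grade))
  invisible(x)
}
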