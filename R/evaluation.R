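#' Confusion counts for binary labels
#'
#' Tallies true/false positives and negatives with +1 as the positive
#' (bioluminescent) class and -1 as the negative class.
#'
#' @param truth,predicted Vectors over \{+1, -1\} of equal length.
#' @return Object of class `confusion_counts`: named integer vector with
#'   elements `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- check_labels(truth, "truth")
  predicted <- check_labels(predicted, "predicted")
  if (length(truth) != length(predicted)) {
    stop("length mismatch: ", length(truth), " true labels vs ",
         length(predicted), " predictions", call. = FALSE)
  }
  counts <- c(TP = sum(truth == 1 & predicted == 1),
              TN = sum(truth == -1 & predicted == -1),
              FP = sum(truth == -1 & predicted == 1),
              FN = sum(truth == 1 & predicted == -1))
  structure(as.integer(counts), names = names(counts),
            class = "confusion_counts")
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' \deqn{S_n = TP/(TP+FN), \quad S_p = TN/(TN+FP),
#'   \quad ACC = (TP+TN)/(TP+TN+FP+FN)}
#' A ratio with a zero denominator (no actual positives, or no actual
#' negatives) is reported as `NA` with a warning rather than silently as 0.
#'
#' @param counts A [confusion_counts()] object or named vector with
#'   elements `TP`, `TN`, `FP`, `FN`.
#' @return Named numeric vector `c(Sn =, Sp =, ACC =)`.
#' @export
classification_metrics <- function(counts) {
  counts <- counts[c("TP", "TN", "FP", "FN")]
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("'counts' must contain non-negative TP, TN, FP, FN", call. = FALSE)
  }
  total <- sum(counts)
  if (total == 0) {
    stop("cannot compute metrics from all-zero confusion counts",
         call. = FALSE)
  }
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  sn <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("no actual positives: sensitivity undefined", call. = FALSE)
    NA_real_
  }
  sp <- if (tn + fp > 0) tn / (tn + fp) else {
    warning("no actual negatives: specificity undefined", call. = FALSE)
    NA_real_
  }
  c(Sn = sn, Sp = sp, ACC = (tp + tn) / total)
}

#' ROC curve and AUC from decision scores
#'
#' Sweeps the decision threshold over the sorted unique scores, predicting
#' positive at or above each threshold, and returns the resulting step curve
#' from (0, 0) to (1, 1) together with its trapezoidal area. Tied scores are
#' collapsed into single threshold steps, so the AUC equals the Mann-Whitney
#' U statistic normalised by `n_pos * n_neg` with ties counted one half.
#'
#' @param scores Finite numeric decision scores (larger = more positive).
#' @param truth Labels over \{+1, -1\}; both classes must be present.
#' @return List with `points` (data frame of `threshold`, `fpr`, `tpr`,
#'   starting at (0, 0)) and `auc`.
#' @export
roc_curve <- function(scores, truth) {
  truth <- check_labels(truth, "truth")
  if (length(scores) != length(truth)) {
    stop("length mismatch between scores and labels", call. = FALSE)
  }
  if (!all(is.finite(scores))) {
    stop("'scores' must be finite", call. = FALSE)
  }
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == -1)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC requires both classes in 'truth' (got ", n_pos,
         " positives, ", n_neg, " negatives)", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- truth[ord]
  # one step per unique score value (ties collapsed)
  last_of_group <- c(s[-length(s)] != s[-1L], TRUE)
  tp <- cumsum(y == 1)[last_of_group]
  fp <- cumsum(y == -1)[last_of_group]
  points <- data.frame(threshold = c(Inf, s[last_of_group]),
                       fpr = c(0, fp / n_neg),
                       tpr = c(0, tp / n_pos))
  auc <- sum(diff(points$fpr) * (points$tpr[-1L] + points$tpr[-nrow(points)]) / 2)
  list(points = points, auc = auc)
}

#' Assemble an evaluation report
#'
#' Bundles pooled confusion counts, Sn/Sp/ACC, the ROC curve with its AUC,
#' and (for cross-validation runs) the per-fold accuracy vector whose mean
#' is the headline accuracy. When the evaluated set contains a single class
#' the ROC is recorded as `NA` with a warning instead of failing, so
#' degenerate independent test sets still produce counts and metrics.
#'
#' @param truth,predicted Labels over \{+1, -1\}.
#' @param scores Decision scores aligned with `truth`, or `NULL`.
#' @param fold_accuracy Optional numeric vector of per-fold accuracies.
#' @return Object of class `eval_report`.
#' @export
eval_report <- function(truth, predicted, scores = NULL,
                        fold_accuracy = NULL) {
  counts <- confusion_counts(truth, predicted)
  metrics <- classification_metrics(counts)
  roc <- NULL
  auc <- NA_real_
  if (!is.null(scores)) {
    if (sum(truth == 1) > 0 && sum(truth == -1) > 0) {
      roc <- roc_curve(scores, truth)
      auc <- roc$auc
      roc <- roc$points
    } else {
      warning("single-class evaluation set: ROC/AUC not computed",
              call. = FALSE)
    }
  }
  structure(list(counts = counts,
                 Sn = metrics[["Sn"]], Sp = metrics[["Sp"]],
                 ACC = metrics[["ACC"]],
                 roc = roc, auc = auc,
                 fold_accuracy = fold_accuracy,
                 mean_fold_accuracy = if (is.null(fold_accuracy)) NA_real_
                                      else mean(fold_accuracy)),
            class = "eval_report")
}

#' @export
#' @method print eval_report
print.eval_report <- function(x, digits = 4, ...) {
  cat("Evaluation report (", sum(x$counts), " instances)\n", sep = "")
  cat(sprintf("  TP %d  TN %d  FP %d  FN %d\n",
              x$counts[["TP"]], x$counts[["TN"]],
              x$counts[["FP"]], x$counts[["FN"]]))
  cat(sprintf("  Sn %s  Sp %s  ACC %s  AUC %s\n",
              format(x$Sn, digits = digits), format(x$Sp, digits = digits),
              format(x$ACC, digits = digits), format(x$auc, digits = digits)))
  if (!is.null(x$fold_accuracy)) {
    cat(sprintf("  mean per-fold accuracy %s over %d folds\n",
                format(x$mean_fold_accuracy, digits = digits),
                length(x$fold_accuracy)))
  }
  invisible(x)
}

#' @export
#' @method plot eval_report
plot.eval_report <- function(x, add = FALSE, col = "steelblue", ...) {
  if (is.null(x$roc)) stop("report carries no ROC curve", call. = FALSE)
  if (!add) {
    graphics::plot(x$roc$fpr, x$roc$tpr, type = "s", col = col,
                   xlab = "False positive rate (1 - Sp)",
                   ylab = "True positive rate (Sn)",
                   xlim = c(0, 1), ylim = c(0, 1), ...)
    graphics::abline(0, 1, lty = 3, col = "grey50")
  } else {
    graphics::lines(x$roc$fpr, x$roc$tpr, type = "s", col = col, ...)
  }
  invisible(x)
}

#' Serialise an evaluation report
#'
#' Writes counts, metrics, AUC and the per-fold accuracy vector as JSON, and
#' optionally the ROC points as a TSV beside it.
#'
#' @param report An [eval_report()].
#' @param path Output JSON path.
#' @param roc_path Optional TSV path for the ROC points.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, roc_path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  payload <- list(counts = as.list(unclass(report$counts)),
                  Sn = report$Sn, Sp = report$Sp, ACC = report$ACC,
                  auc = report$auc,
                  fold_accuracy = report$fold_accuracy,
                  mean_fold_accuracy = report$mean_fold_accuracy)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(roc_path) && !is.null(report$roc)) {
    utils::write.table(report$roc, roc_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

# Coerce labels to a plain +1/-1 integer-valued vector, accepting numeric,
# factor or character renderings of the two classes.
check_labels <- function(labels, what = "labels") {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) labels <- suppressWarnings(as.numeric(labels))
  if (!is.numeric(labels) || any(is.na(labels)) ||
      !all(labels %in% c(-1, 1))) {
    stop("'", what, "' must be coded over {+1, -1}", call. = FALSE)
  }
  as.vector(labels)
}
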