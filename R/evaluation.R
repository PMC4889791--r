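# Classifier assessment: confusion matrices, the accuracy /
# precision / recall / F-measure quartet, and ROC curves with AUC for the
# level-2 probabilistic classifier.

#' Confusion matrix
#'
#' K x K counts with rows indexing the true class and columns the
#' predicted class, over the union of the two label sets (or an explicit
#' `classes` ordering).
#'
#' @param truth,predicted equal-length label vectors/factors.
#' @param classes optional class ordering.
#' @return Integer matrix with dimnames `truth` x `predicted`.
#' @export
confusionCounts <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted))
    stop("'truth' and 'predicted' must have equal length")
  if (is.null(classes))
    classes <- union(levels(factor(truth)), levels(factor(predicted)))
  t <- factor(truth, levels = classes)
  p <- factor(predicted, levels = classes)
  cm <- table(truth = t, predicted = p)
  matrix(as.integer(cm), nrow(cm), ncol(cm),
         dimnames = list(truth = classes, predicted = classes))
}

#' Row-normalized confusion percentages
#'
#' Each row (true class) is scaled to sum to 100.
#'
#' @param cm a confusion matrix from [confusionCounts()].
#' @return Numeric matrix of row percentages.
#' @export
confusionPercent <- function(cm) {
  sweep(cm, 1L, pmax(rowSums(cm), 1L), "/") * 100
}

#' Classification accuracy
#'
#' Trace over total of a confusion matrix: the fraction of samples whose
#' predicted class equals the true class (`(TP + TN) / total` in the
#' binary case).
#'
#' @param cm a square confusion matrix.
#' @return Accuracy in \[0, 1\].
#' @examples
#' classificationAccuracy(matrix(c(19237, 763, 0, 0), 2, 2))  # 0.97185
#' @export
classificationAccuracy <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix")
  sum(diag(cm)) / sum(cm)
}

#' Precision, recall and F-measure
#'
#' One-vs-rest for each class of a multiclass confusion matrix:
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)` and
#' `F = (alpha^2 + 1) * precision * recall / (alpha^2 * precision +
#' recall)` (the harmonic mean when `alpha = 1`). A class with no
#' predicted (or no true) samples gets `NA` with a warning.
#'
#' @param cm a square confusion matrix (truth rows, prediction columns).
#' @param alpha positive F-measure weight, default 1.
#' @return Data frame with one row per class: `class`, `precision`,
#'   `recall`, `F`.
#' @export
precisionRecallF <- function(cm, alpha = 1) {
  if (alpha <= 0) stop("'alpha' must be > 0")
  classes <- rownames(cm)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(cm)))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  if (anyNA(prec) || anyNA(rec))
    warning("precision/recall undefined for some class (no samples)")
  f <- (alpha^2 + 1) * prec * rec / (alpha^2 * prec + rec)
  data.frame(class = classes, precision = prec, recall = rec, F = f,
             row.names = NULL)
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold over all distinct scores (tied scores
#' share a single step), accumulating true- and false-positive rates from
#' (0, 0) to (1, 1); the area is computed by the trapezoidal rule, which
#' for tied scores equals Mann-Whitney pair counting with 1/2 credit for
#' ties.
#'
#' @param scores numeric scores, larger meaning more positive.
#' @param labels binary labels; `positive` names the positive class
#'   (default: the larger/second factor level).
#' @param positive the positive label.
#' @return List with `points` (data frame `fpr`, `tpr` in threshold
#'   order) and `auc`.
#' @export
rocAuc <- function(scores, labels, positive = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("'labels' must contain exactly two classes")
  if (is.null(positive)) positive <- levels(labels)[2L]
  y <- labels == positive
  nP <- sum(y); nN <- sum(!y)
  if (nP == 0L || nN == 0L) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  lastOfGroup <- c(ss[-length(ss)] != ss[-1L], TRUE)
  tp <- cumsum(ys)[lastOfGroup]
  fpos <- cumsum(!ys)[lastOfGroup]
  tpr <- c(0, tp / nP)
  fpr <- c(0, fpos / nN)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Assemble an evaluation report
#'
#' Bundles the level-1 confusion matrix and metrics, the level-2 metrics
#' and ROC, the end-to-end cascade confusion, and the composed stage
#' rates into a printable object (see [composeRates()]).
#'
#' @param level1 list with `confusion`, `accuracy`, `perClass`.
#' @param level2 list with `confusion`, `accuracy`, `roc`.
#' @param cascade list with `confusion`, `accuracy`, `abnormalRecall`,
#'   `flatAccuracy`.
#' @return An `evaluationReport` list.
#' @export
evaluationReport <- function(level1, level2, cascade) {
  composed <- composeRates(level1$accuracy, level2$accuracy)
  structure(list(level1 = level1, level2 = level2, cascade = cascade,
                 composedAccuracy = composed),
            class = "evaluationReport")
}

#' @export
print.evaluationReport <- function(x, ...) {
  cat("Two-level cascade evaluation\n")
  cat(sprintf("  level 1 (rough, 4-class) accuracy: %7.3f%%\n",
              100 * x$level1$accuracy))
  cat(sprintf("  level 2 (normal/abnormal) accuracy: %6.3f%%  AUC: %.3f\n",
              100 * x$level2$accuracy, x$level2$roc$auc))
  cat(sprintf("  composed stage rate (product):     %7.3f%%\n",
              100 * x$composedAccuracy))
  cat(sprintf("  cascade end-to-end 5-way accuracy: %7.3f%%\n",
              100 * x$cascade$accuracy))
  cat(sprintf("  abnormal-epithelial recall:        %7.3f%%\n",
              100 * x$cascade$abnormalRecall))
  if (!is.null(x$cascade$flatAccuracy))
    cat(sprintf("  flat 5-class baseline accuracy:    %7.3f%%\n",
                100 * x$cascade$flatAccuracy))
  invisible(x)
}

#' Write an evaluation report to JSON (plus ROC points as CSV)
#'
#' @param report an `evaluationReport`.
#' @param path JSON output path.
#' @param rocPath optional CSV path for the ROC points.
#' @export
writeEvaluationReport <- function(report, path, rocPath = NULL) {
  doc <- list(
    level1 = list(accuracy = report$level1$accuracy,
                  confusion = report$level1$confusion,
                  perClass = report$level1$perClass),
    level2 = list(accuracy = report$level2$accuracy,
                  auc = report$level2$roc$auc),
    cascade = list(accuracy = report$cascade$accuracy,
                   abnormalRecall = report$cascade$abnormalRecall,
                   flatAccuracy = report$cascade$flatAccuracy),
    composedAccuracy = report$composedAccuracy)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(rocPath))
    utils::write.csv(report$level2$roc$points, rocPath, row.names = FALSE)
  invisible(path)
}
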