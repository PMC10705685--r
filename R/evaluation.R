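# Macro-averaged evaluation.
#
# Multi-class performance is summarized by the arithmetic mean over classes
# of one-vs-rest binary metrics: macro binary accuracy (mean over classes of
# (TP+TN)/n), macro precision, macro recall, and an F1 computed from the
# macro precision and recall (2PR/(P+R)). Plain multiclass accuracy
# (trace / n) is reported alongside, since "accuracy" in this literature can
# denote either. One-vs-rest PR and ROC curves with areas complete the
# report.

#' Confusion matrix and macro-averaged metrics
#'
#' @param y_true,y_pred equal-length label vectors (factor, character or
#'   0-based/1-based integer codes consistent with `levels`).
#' @param levels optional class levels; defaults to the sorted union of the
#'   observed labels.
#' @return an object of class `eval_report`: list(confusion (true rows x
#'   predicted columns), per_class (TP/TN/FP/FN and per-class P/R/F1),
#'   accuracy_macro, precision_macro, recall_macro, f1_macro,
#'   plain_accuracy, n).
#' @export
compute_metrics <- function(y_true, y_pred, levels = NULL) {
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (is.null(levels)) levels <- sort(unique(c(y_true, y_pred)))
  bad <- setdiff(unique(c(y_true, y_pred)), levels)
  if (length(bad)) stop("labels outside the declared classes: ",
                        paste(bad, collapse = ", "))
  n <- length(y_true)
  confusion <- table(factor(y_true, levels), factor(y_pred, levels),
                     dnn = c("true", "predicted"))
  confusion <- unclass(confusion)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  tn <- n - tp - fp - fn
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1c <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  P <- mean(prec); R <- mean(rec)
  structure(list(
    confusion = confusion,
    per_class = data.frame(class = levels, TP = tp, TN = tn, FP = fp, FN = fn,
                           precision = prec, recall = rec, f1 = f1c,
                           row.names = NULL),
    accuracy_macro = mean((tp + tn) / n),
    precision_macro = P, recall_macro = R,
    f1_macro = if (P + R > 0) 2 * P * R / (P + R) else 0,
    plain_accuracy = sum(tp) / n, n = n), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("eval_report over %d samples, %d classes\n",
                     "  plain accuracy : %.4f\n  macro accuracy : %.4f\n",
                     "  macro precision: %.4f\n  macro recall   : %.4f\n",
                     "  macro F1       : %.4f\n"),
              x$n, nrow(x$confusion), x$plain_accuracy, x$accuracy_macro,
              x$precision_macro, x$recall_macro, x$f1_macro))
  invisible(x)
}

# One-class ROC curve (trapezoid AUC) from binary truth + scores.
.roc_one <- function(truth, score) {
  o <- order(score, decreasing = TRUE)
  truth <- truth[o]; score <- score[o]
  # collapse score ties
  grp <- cumsum(!duplicated(score))
  tp <- cumsum(truth); fp <- cumsum(!truth)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(truth))
  fpr <- c(0, fp[last] / sum(!truth))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

# One-class PR curve; area is the step-interpolated average precision.
.pr_one <- function(truth, score) {
  o <- order(score, decreasing = TRUE)
  truth <- truth[o]; score <- score[o]
  grp <- cumsum(!duplicated(score))
  tp <- cumsum(truth); fpos <- cumsum(!truth)
  last <- !duplicated(grp, fromLast = TRUE)
  prec <- tp[last] / (tp[last] + fpos[last])
  rec <- tp[last] / sum(truth)
  ap <- sum(diff(c(0, rec)) * prec)
  list(curve = data.frame(recall = c(0, rec), precision = c(1, prec)), auc = ap)
}

#' One-vs-rest PR and ROC curves with areas
#'
#' For every class, thresholds its score column against the one-vs-rest
#' binary truth; the ROC area uses trapezoidal integration and the PR area
#' is the step-wise average precision (no optimistic interpolation). Classes
#' absent from `y_true` get `NA` areas, are flagged, and are excluded from
#' the macro averages.
#'
#' @param y_true label vector.
#' @param scores n x K score matrix with class names as columns.
#' @return list(per_class = named list with `roc`, `pr`, `auc_roc`,
#'   `auc_pr`, `defined`; macro_auc_roc; macro_auc_pr).
#' @export
pr_roc_curves <- function(y_true, scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) != length(y_true)) stop("score rows must match labels")
  classes <- colnames(scores)
  if (is.null(classes)) stop("scores must have class names as columns")
  y_true <- as.character(y_true)
  per <- lapply(classes, function(cl) {
    truth <- y_true == cl
    if (!any(truth) || all(truth))
      return(list(roc = NULL, pr = NULL, auc_roc = NA_real_,
                  auc_pr = NA_real_, defined = FALSE))
    r <- .roc_one(truth, scores[, cl])
    p <- .pr_one(truth, scores[, cl])
    list(roc = r$curve, pr = p$curve, auc_roc = r$auc, auc_pr = p$auc,
         defined = TRUE)
  })
  names(per) <- classes
  aucs_roc <- vapply(per, `[[`, 0, "auc_roc")
  aucs_pr <- vapply(per, `[[`, 0, "auc_pr")
  list(per_class = per,
       macro_auc_roc = mean(aucs_roc, na.rm = TRUE),
       macro_auc_pr = mean(aucs_pr, na.rm = TRUE))
}

#' Plot one-vs-rest PR and ROC curves
#'
#' @param curves output of [pr_roc_curves()].
#' @param which "roc" or "pr".
#' @return a ggplot object.
#' @export
plot_curves <- function(curves, which = c("roc", "pr")) {
  which <- match.arg(which)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  dfs <- lapply(names(curves$per_class), function(cl) {
    pc <- curves$per_class[[cl]]
    if (!pc$defined) return(NULL)
    d <- if (which == "roc") pc$roc else pc$pr
    d$class <- sprintf("%s (AUC %.3f)", cl,
                       if (which == "roc") pc$auc_roc else pc$auc_pr)
    d
  })
  d <- do.call(rbind, dfs)
  if (which == "roc")
    ggplot2::ggplot(d, ggplot2::aes(x = fpr, y = tpr, color = class)) +
      ggplot2::geom_line() +
      ggplot2::geom_abline(linetype = 3) +
      ggplot2::labs(x = "False positive rate", y = "True positive rate")
  else
    ggplot2::ggplot(d, ggplot2::aes(x = recall, y = precision, color = class)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Recall", y = "Precision")
}
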