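#' Match detections to ground truth by rotated IoU
#'
#' Greedy matching in descending confidence order (ties broken by lower
#' detection index): each detection claims the still-unmatched ground-truth
#' box with the highest rotated IoU, and counts as a true positive when that
#' IoU reaches the threshold. Each ground truth can be matched at most once;
#' remaining detections are false positives and remaining ground truths false
#' negatives. True negatives are identically zero in detection and kept only
#' for completeness.
#'
#' @param dets list of detections (`box` + `score`).
#' @param gts list of [rotated_box()]es.
#' @param iou_threshold minimum rotated IoU for a true positive (default 0.5).
#' @return A list of class `eval_counts` with `TP`, `FP`, `FN`, `TN` and the
#'   threshold used.
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  nd <- length(dets); ng <- length(gts)
  if (nd == 0)
    return(structure(list(TP = 0L, FP = 0L, FN = ng, TN = 0L,
                          iou_threshold = iou_threshold), class = "eval_counts"))
  scores <- vapply(dets, function(d) d$score, numeric(1))
  ord <- order(-scores, seq_along(scores))
  used <- logical(ng)
  tp <- 0L
  for (i in ord) {
    if (ng == 0) break
    ious <- vapply(seq_len(ng), function(j)
      if (used[j]) -1 else rotated_iou(dets[[i]]$box, gts[[j]]), numeric(1))
    j <- which.max(ious)
    if (length(j) && ious[j] >= iou_threshold) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  structure(list(TP = tp, FP = nd - tp, FN = ng - tp, TN = 0L,
                 iou_threshold = iou_threshold), class = "eval_counts")
}

#' Precision, recall and F1 score
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`, `F1 = 2PR / (P + R)`; any
#' 0/0 is reported as 0 by convention.
#'
#' @param counts an `eval_counts` (or any list with `TP`, `FP`, `FN`).
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Regression diagnostics for conductance fits
#'
#' Mean squared error and coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot` between predicted and true per-image gsmax.
#' A constant truth leaves `R^2` undefined (returned as `NaN` with a
#' warning).
#'
#' @param predicted,truth equal-length numeric vectors, `n >= 2`.
#' @return Named numeric vector `c(mse, r_squared)`.
#' @export
regression_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) < 2)
    stop("regression_metrics: need equal-length vectors with n >= 2")
  mse <- mean((predicted - truth)^2)
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) {
    warning("regression_metrics: constant truth, R^2 undefined")
    r2 <- NaN
  } else {
    r2 <- 1 - sum((predicted - truth)^2) / ss_tot
  }
  c(mse = mse, r_squared = r2)
}

#' Evaluate detections over a set of images
#'
#' Pools matching counts across images and reports the summary the pipeline
#' logs per epoch.
#'
#' @param det_list list (per image) of detection lists.
#' @param gt_list list (per image) of ground-truth box lists.
#' @param iou_threshold rotated-IoU threshold.
#' @return A list with `precision`, `recall`, `f1`, `tp`, `fp`, `fn`,
#'   `iou_threshold`.
#' @export
evaluate_detections <- function(det_list, gt_list, iou_threshold = 0.5) {
  stopifnot(length(det_list) == length(gt_list))
  tp <- fp <- fn <- 0L
  for (i in seq_along(det_list)) {
    c0 <- match_detections(det_list[[i]], gt_list[[i]], iou_threshold)
    tp <- tp + c0$TP; fp <- fp + c0$FP; fn <- fn + c0$FN
  }
  prf <- precision_recall_f1(list(TP = tp, FP = fp, FN = fn))
  list(precision = unname(prf["precision"]), recall = unname(prf["recall"]),
       f1 = unname(prf["f1"]), tp = tp, fp = fp, fn = fn,
       iou_threshold = iou_threshold)
}
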