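# Pixel-classification metrics and connected-component post-processing.

as_binary_matrix <- function(x, what) {
  if (length(dim(x)) == 3L && dim(x)[1] == 1L) x <- x[1, , ]
  if (!all(x %in% c(0, 1)))
    stop(what, " must be binary (0/1); threshold soft predictions first")
  x
}

#' Pixel confusion counts of a binary prediction against a mask
#'
#' @param pred_binary binary (H, W) prediction.
#' @param mask binary (H, W) reference, congruent with `pred_binary`.
#' @return a list of class `confusion_counts` with integer `tp`, `fp`,
#'   `tn`, `fn` summing to the pixel count.
#' @export
confusion_counts <- function(pred_binary, mask) {
  p <- as_binary_matrix(pred_binary, "pred_binary")
  m <- as_binary_matrix(mask, "mask")
  stopifnot(all(dim(p) == dim(m)))
  structure(list(tp = sum(p == 1 & m == 1), fp = sum(p == 1 & m == 0),
                 tn = sum(p == 0 & m == 0), fn = sum(p == 0 & m == 1)),
            class = "confusion_counts")
}

undef <- function() structure(NA_real_, undefined = TRUE)

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `SE = TP/(TP+FN)`, `SP = TN/(FP+TN)`, `ACC = (TP+TN)/N`.  A zero
#' denominator yields a flagged undefined value (`NA` with attribute
#' `undefined`), never a silent 0.
#'
#' @param counts a [confusion_counts()] result.
#' @return a list with `sensitivity`, `specificity`, `accuracy`.
#' @export
metric_suite <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, list(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else undef(),
    specificity = if (fp + tn > 0) tn / (fp + tn) else undef(),
    accuracy = (tp + tn) / (tp + fp + tn + fn)
  ))
}

#' Dice coefficient
#'
#' `2*sum(pq) / (sum(p^2) + sum(q^2))`, valid for soft predictions; for
#' binary inputs this is the familiar `2TP / (2TP + FP + FN)`.
#'
#' @param pred (H, W) prediction in \[0, 1\] (soft allowed).
#' @param mask (H, W) reference labels.
#' @return value in \[0, 1\]; two empty masks score a perfect 1.
#' @export
dice_coefficient <- function(pred, mask) {
  stopifnot(all(dim(pred) == dim(mask)))
  den <- sum(pred^2) + sum(mask^2)
  if (den == 0) return(1)
  2 * sum(pred * mask) / den
}

#' Mean intersection-over-union over classes
#'
#' Per class `i`, `IoU_i = p_ii / (sum_j p_ij + sum_j p_ji - p_ii)` from the
#' class confusion matrix; the mean runs over the `k` classes.  A class
#' absent from both prediction and reference is excluded from the mean with a
#' warning.
#'
#' @param pred (H, W) hard labels in `0..k-1` (binary: 0 background,
#'   1 vessel).
#' @param mask (H, W) reference labels in `0..k-1`.
#' @param k number of classes (2 for binary vessel masks).
#' @return mean IoU in \[0, 1\].
#' @export
mean_iou <- function(pred, mask, k = 2L) {
  stopifnot(all(dim(pred) == dim(mask)))
  cm <- matrix(0, k, k)  # cm[i, j]: true class i predicted as j (1-based)
  for (i in seq_len(k)) for (j in seq_len(k))
    cm[i, j] <- sum(mask == (i - 1L) & pred == (j - 1L))
  ious <- numeric(0)
  for (i in seq_len(k)) {
    den <- sum(cm[i, ]) + sum(cm[, i]) - cm[i, i]
    if (den == 0) {
      warning("class ", i - 1L, " absent from prediction and reference; ",
              "excluded from the mean IoU")
      next
    }
    ious <- c(ious, cm[i, i] / den)
  }
  mean(ious)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic (the probability a random vessel
#' pixel scores above a random background pixel, ties counted half), which
#' equals trapezoidal integration of the ROC curve over all unique score
#' thresholds.
#'
#' @param pred_soft (H, W) scores in \[0, 1\].
#' @param mask binary (H, W) reference containing both classes.
#' @return AUC in \[0, 1\]; flagged undefined if only one class is present.
#' @export
roc_auc <- function(pred_soft, mask) {
  m <- as_binary_matrix(mask, "mask")
  stopifnot(all(dim(pred_soft) == dim(m)))
  n1 <- sum(m == 1); n0 <- sum(m == 0)
  if (n1 == 0 || n0 == 0) {
    warning("single-class mask: AUC undefined")
    return(undef())
  }
  r <- rank(as.vector(pred_soft))
  (sum(r[m == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve coordinates
#'
#' @inheritParams roc_auc
#' @return a data.frame with `threshold`, `tpr`, `fpr`, one row per unique
#'   score (thresholds descending), suitable for CSV export.
#' @export
roc_curve <- function(pred_soft, mask) {
  m <- as_binary_matrix(mask, "mask")
  s <- as.vector(pred_soft)
  th <- sort(unique(s), decreasing = TRUE)
  n1 <- sum(m == 1); n0 <- sum(m == 0)
  tpr <- vapply(th, function(t) sum(s >= t & m == 1) / max(n1, 1), 0)
  fpr <- vapply(th, function(t) sum(s >= t & m == 0) / max(n0, 1), 0)
  data.frame(threshold = th, tpr = tpr, fpr = fpr)
}

#' Remove small connected components from a binary mask
#'
#' Deletes every connected component whose pixel count is below
#' `fraction` of the total foreground (default 0.03%), the post-processing
#' rule used to strip isolated mis-segmented islands that cannot belong to a
#' connected vascular tree.  Idempotent: surviving components still pass the
#' (smaller) threshold recomputed on the filtered mask.
#'
#' @param mask binary (H, W) matrix.
#' @param fraction minimum component size as a fraction of total foreground.
#' @param connectivity 8 (default; vessels are thin diagonals) or 4.
#' @return the filtered binary mask.
#' @export
remove_small_components <- function(mask, fraction = 0.0003, connectivity = 8L) {
  m <- as_binary_matrix(mask, "mask")
  total <- sum(m)
  if (total == 0) return(m)
  lab <- label_components_cpp(matrix(as.integer(m), nrow(m), ncol(m)),
                              as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= fraction * total)
  out <- matrix(0, nrow(m), ncol(m))
  out[lab %in% keep] <- 1
  out
}

#' Full metrics report for a prediction/mask pair
#'
#' @param pred_soft (H, W) probability map.
#' @param mask binary (H, W) reference.
#' @param threshold binarisation threshold for the hard metrics.
#' @return a list with `dice_soft`, `dice`, `mean_iou`, `sensitivity`,
#'   `specificity`, `accuracy`, `auc`.
#' @export
metrics_report <- function(pred_soft, mask, threshold = 0.5) {
  m <- as_binary_matrix(mask, "mask")
  hard <- (pred_soft >= threshold) * 1
  ms <- metric_suite(confusion_counts(hard, m))
  list(dice_soft = dice_coefficient(pred_soft, m),
       dice = dice_coefficient(hard, m),
       mean_iou = mean_iou(hard, m),
       sensitivity = ms$sensitivity,
       specificity = ms$specificity,
       accuracy = ms$accuracy,
       auc = roc_auc(pred_soft, m))
}
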