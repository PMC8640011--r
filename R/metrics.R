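#' Dice and IoU overlap scores
#'
#' Soft-compatible overlap scores between a prediction and a binary ground
#' truth. With binary inputs and `smooth = 0` these are the exact set
#' overlap measures Dice(A, B) = 2|A∩B| / (|A| + |B|) and IoU(A, B) =
#' |A∩B| / |A∪B| (Jaccard); with a soft prediction they are the
#' differentiable relaxations used for training, stabilized by `smooth` in
#' numerator and denominator. When both sets are empty the scores are 1
#' (both-empty convention).
#'
#' @param pred prediction in `[0, 1]`, same shape as `truth`.
#' @param truth binary ground truth.
#' @param smooth non-negative stabilizer; 0 for exact evaluation, 1 is the
#'   training default.
#' @return a fraction in `[0, 1]`.
#' @examples
#' a <- matrix(0, 10, 20); a[1:10, 1:10] <- 1   # two 10x10 squares ...
#' b <- matrix(0, 10, 20); b[1:10, 6:15] <- 1   # ... overlapping in a 5x10 strip
#' dice_score(a, b)  # 2*50/200 = 0.5
#' iou_score(a, b)   # 50/150 = 1/3
#' @export
dice_score <- function(pred, truth, smooth = 0) {
  if (!identical(dim(pred), dim(truth))) {
    stopf("pred and truth must have identical shapes")
  }
  inter <- sum(pred * truth)
  denom <- sum(pred) + sum(truth)
  if (smooth == 0 && denom == 0) return(1)
  (2 * inter + smooth) / (denom + smooth)
}

#' @rdname dice_score
#' @export
iou_score <- function(pred, truth, smooth = 0) {
  if (!identical(dim(pred), dim(truth))) {
    stopf("pred and truth must have identical shapes")
  }
  inter <- sum(pred * truth)
  union <- sum(pred) + sum(truth) - inter
  if (smooth == 0 && union == 0) return(1)
  (inter + smooth) / (union + smooth)
}

#' Loss weights for the combined segmentation loss
#'
#' The segmentation loss is a weighted sum of Dice and IoU losses; the
#' weights default to 0.4 (Dice) and 0.6 (IoU) and must sum to 1.
#'
#' @param w_dice,w_iou non-negative weights summing to 1.
#' @return object of class `loss_weights`.
#' @export
loss_weights <- function(w_dice = 0.4, w_iou = 0.6) {
  if (abs(w_dice + w_iou - 1) > 1e-9 || w_dice < 0 || w_iou < 0) {
    config_error("loss weights must be non-negative and sum to 1")
  }
  structure(list(w_dice = w_dice, w_iou = w_iou), class = "loss_weights")
}

#' Combined Dice/IoU segmentation loss
#'
#' `-(w_dice * Dice + w_iou * IoU)`, ranging over `[-1, 0]` and minimized
#' at perfect overlap.
#'
#' @inheritParams dice_score
#' @param weights a [loss_weights()].
#' @return scalar loss value.
#' @export
segmentation_loss <- function(pred, truth, weights = loss_weights(), smooth = 1) {
  stopifnot(inherits(weights, "loss_weights"))
  -(weights$w_dice * dice_score(pred, truth, smooth) +
      weights$w_iou * iou_score(pred, truth, smooth))
}

# Training loss over a mini-batch plus its analytic gradient wrt pred,
# used as the backward seed of the training pass. Follows the flattened
# convention of this loss family's reference implementations: the batch is
# pooled into one pixel set before the overlap ratios are formed, so the
# gradient scale does not explode for ROIs with very small masses (which
# otherwise overshoot into saturated all-foreground predictions).
seg_loss_batch <- function(pred, truth, weights, smooth = 1) {
  I <- sum(pred * truth)
  P <- sum(pred)
  Tt <- sum(truth)
  dden <- P + Tt + smooth
  U <- P + Tt - I
  loss <- -(weights$w_dice * (2 * I + smooth) / dden +
              weights$w_iou * (I + smooth) / (U + smooth))
  grad <- -(weights$w_dice * (2 * truth * dden - (2 * I + smooth)) / dden^2 +
              weights$w_iou * (truth * (U + smooth) - (I + smooth) * (1 - truth)) /
              (U + smooth)^2)
  dim(grad) <- dim(pred)
  list(loss = loss, grad = grad)
}

#' Mean IoU over well-segmented ROIs (IoU_90)
#'
#' Mean of the per-ROI IoU percentages over ROIs whose IoU is at least 90%
#' (inclusive threshold). When no ROI qualifies the measure is not
#' applicable and `NA` is returned.
#'
#' @param per_roi_ious numeric vector of per-ROI IoU percentages in
#'   `[0, 100]`.
#' @return mean percentage, or `NA_real_` when no ROI reaches 90%.
#' @examples
#' iou_90(c(95, 91, 89))  # (95 + 91) / 2
#' @export
iou_90 <- function(per_roi_ious) {
  if (length(per_roi_ious) == 0L) return(NA_real_)
  if (any(per_roi_ious < 0 | per_roi_ious > 100, na.rm = TRUE)) {
    stopf("per-ROI IoU values must be percentages in [0, 100]")
  }
  q <- per_roi_ious[!is.na(per_roi_ious) & per_roi_ious >= 90]
  if (length(q) == 0L) return(NA_real_)
  mean(q)
}

#' End-to-end final segmentation accuracy
#'
#' Combines the upstream detector's accuracy rate with the segmentation
#' stage's IoU_90 score: `detection_rate * iou_90 / 100`, reported to two
#' decimals (half-up).
#'
#' @param detection_rate detection accuracy rate of the upstream
#'   mass-localization stage, in percent.
#' @param iou_90 IoU_90 score in percent (see [iou_90()]); `NA` propagates.
#' @return percentage rounded to 2 decimals, or `NA_real_`.
#' @examples
#' final_segmentation_accuracy(95.7, 90.82)  # 86.91
#' @export
final_segmentation_accuracy <- function(detection_rate, iou_90) {
  if (is.na(detection_rate) || is.na(iou_90)) return(NA_real_)
  if (detection_rate < 0 || detection_rate > 100 || iou_90 < 0 || iou_90 > 100) {
    stopf("detection_rate and iou_90 must be percentages in [0, 100]")
  }
  round_half_up(detection_rate * iou_90 / 100, 2)
}

#' Pixel-wise ROC curve and AUC
#'
#' Pools every pixel of the paired prediction/truth sets, min-max normalizes
#' the predicted scores to `[0, 1]`, and treats the task as binary pixel
#' classification: TPR/FPR are traced over all score thresholds and the AUC
#' is the trapezoidal area under the resulting curve.
#'
#' @param preds list of soft prediction grids (or a single grid).
#' @param truths list of binary truth grids, pairwise same shapes.
#' @return list with `curve` (data.frame of `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
pixel_roc_auc <- function(preds, truths) {
  if (!is.list(preds)) preds <- list(preds)
  if (!is.list(truths)) truths <- list(truths)
  if (length(preds) != length(truths)) stopf("preds and truths must be paired")
  for (i in seq_along(preds)) {
    if (!identical(dim(preds[[i]]), dim(truths[[i]]))) {
      stopf("shape mismatch between prediction and truth %d", i)
    }
  }
  s <- unlist(lapply(preds, as.vector), use.names = FALSE)
  y <- unlist(lapply(truths, as.vector), use.names = FALSE)
  if (!all(y %in% c(0, 1))) stopf("ground-truth grids must be binary")
  npos <- sum(y == 1)
  nneg <- sum(y == 0)
  if (npos == 0L || nneg == 0L) {
    stopf("AUC undefined: pooled ground truth contains a single class")
  }
  rng <- range(s)
  s <- if (rng[1L] == rng[2L]) rep(0.5, length(s)) else (s - rng[1L]) / (rng[2L] - rng[1L])
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; y <- y[ord]
  # group tied scores so each threshold is a single ROC vertex
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- which(!duplicated(s, fromLast = TRUE))
  tpr <- c(0, tp[last] / npos)
  fpr <- c(0, fp[last] / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(threshold = c(Inf, s[last]), fpr = fpr, tpr = tpr),
       auc = auc)
}
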