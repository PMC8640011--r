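#' Evaluate predicted segmentations against ground truth
#'
#' Computes the per-ROI Dice and IoU (exact set overlap on binarized,
#' optionally post-processed masks), their means, the pooled pixel-wise
#' ROC AUC from the soft maps, the IoU_90 score, and, when an upstream
#' detection accuracy rate is supplied, the end-to-end final segmentation
#' accuracy. Percentages are reported half-up to two decimals.
#'
#' @param preds list of soft prediction matrices in `[0, 1]` (or binary
#'   masks).
#' @param truths list of binary ground-truth matrices, paired with `preds`.
#' @param sample_ids optional character ids, one per ROI.
#' @param detection_rate external detection accuracy rate in percent
#'   (`NA` to skip the end-to-end measure).
#' @param threshold binarization threshold for the evaluation masks.
#' @param postprocess apply [largest_component_mask()] before scoring.
#' @return object of class `evaluation_report`: `per_roi` data.frame
#'   (`sample_id`, `dice`, `iou`, in percent), `mean_dice`, `mean_iou`,
#'   `pixel_auc`, `iou_90`, `detection_rate`, `final_accuracy`, `n_roi`.
#' @export
evaluate_predictions <- function(preds, truths, sample_ids = NULL,
                                 detection_rate = NA_real_,
                                 threshold = 0.5, postprocess = TRUE) {
  if (!is.list(preds)) preds <- list(preds)
  if (!is.list(truths)) truths <- list(truths)
  if (length(preds) != length(truths) || length(preds) == 0L) {
    stopf("preds and truths must be non-empty paired lists")
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("roi_%04d", seq_along(preds))
  dice <- iou <- numeric(length(preds))
  for (i in seq_along(preds)) {
    m <- (preds[[i]] >= threshold) * 1
    if (postprocess) m <- largest_component_mask(m, soft = preds[[i]])
    dice[i] <- 100 * dice_score(m, truths[[i]])
    iou[i] <- 100 * iou_score(m, truths[[i]])
  }
  auc <- tryCatch(pixel_roc_auc(preds, truths)$auc, error = function(e) NA_real_)
  i90 <- iou_90(iou)
  report <- list(
    per_roi = data.frame(sample_id = sample_ids,
                         dice = round_half_up(dice, 2),
                         iou = round_half_up(iou, 2),
                         stringsAsFactors = FALSE),
    mean_dice = round_half_up(mean(dice), 2),
    mean_iou = round_half_up(mean(iou), 2),
    pixel_auc = auc,
    iou_90 = if (is.na(i90)) NA_real_ else round_half_up(i90, 2),
    detection_rate = detection_rate,
    final_accuracy = final_segmentation_accuracy(
      detection_rate, if (is.na(i90)) NA_real_ else round_half_up(i90, 2)),
    n_roi = length(preds)
  )
  class(report) <- "evaluation_report"
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d ROIs\n", x$n_roi))
  cat(sprintf("  mean Dice %.2f%% | mean IoU %.2f%% | pixel AUC %s\n",
              x$mean_dice, x$mean_iou,
              if (is.na(x$pixel_auc)) "NA" else sprintf("%.4f", x$pixel_auc)))
  cat(sprintf("  IoU_90 %s | detection rate %s | final accuracy %s\n",
              if (is.na(x$iou_90)) "not applicable" else sprintf("%.2f%%", x$iou_90),
              if (is.na(x$detection_rate)) "NA" else sprintf("%.2f%%", x$detection_rate),
              if (is.na(x$final_accuracy)) "NA" else sprintf("%.2f%%", x$final_accuracy)))
  invisible(x)
}

#' Serialize / restore an evaluation report
#'
#' `write_report()` writes `<prefix>.json` (aggregates plus per-ROI table)
#' and `<prefix>_per_roi.csv`; `read_report()` restores the report from the
#' JSON.
#'
#' @param report an `evaluation_report`.
#' @param prefix output path prefix.
#' @return `read_report` returns the restored `evaluation_report`.
#' @export
write_report <- function(report, prefix) {
  stopifnot(inherits(report, "evaluation_report"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  write.csv(report$per_roi, paste0(prefix, "_per_roi.csv"), row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_report
#' @param path path to a report JSON written by `write_report()`.
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$per_roi <- as.data.frame(obj$per_roi, stringsAsFactors = FALSE)
  for (f in c("mean_dice", "mean_iou", "pixel_auc", "iou_90",
              "detection_rate", "final_accuracy")) {
    obj[[f]] <- if (is.null(obj[[f]])) NA_real_ else as.numeric(obj[[f]])
  }
  obj$n_roi <- as.integer(obj$n_roi)
  class(obj) <- "evaluation_report"
  obj
}
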