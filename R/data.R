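#' End-to-end accuracy worked examples
#'
#' Published operating points of the two-stage mammography pipeline on the
#' three mammography collections (CBIS-DDSM, INbreast, and a private
#' clinical set): the upstream YOLO-based detector's mass detection
#' accuracy rate, the segmentation stage's IoU_90 score for each connected
#' architecture, and the resulting final segmentation accuracy. These are
#' external scalar inputs to [final_segmentation_accuracy()] — the
#' detection stage itself is out of scope — and serve as worked examples
#' for the end-to-end bookkeeping.
#'
#' @return data.frame with columns `dataset`, `architecture`,
#'   `detection_rate`, `iou_90`, `final_accuracy` (all rates in percent).
#' @examples
#' ex <- final_accuracy_inputs()
#' with(ex, final_segmentation_accuracy(detection_rate[1], iou_90[1]))
#' @export
final_accuracy_inputs <- function() {
  read.csv(system.file("extdata", "final_accuracy_inputs.csv",
                       package = "mammoseg"),
           stringsAsFactors = FALSE)
}
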