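# Pixel-level segmentation evaluation: confusion counts and the four
# standard overlap metrics, with per-image (macro) dataset aggregation.

#' Pixel confusion counts
#'
#' @param pred_mask,truth binary matrices of identical shape.
#' @return named integer vector `(TP, FP, FN, TN)`.
#' @export
confusion_counts <- function(pred_mask, truth) {
  if (!all(dim(pred_mask) == dim(truth)))
    stop("confusion_counts: shape mismatch")
  if (!all(pred_mask %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("confusion_counts: inputs must be binary")
  tp <- sum(pred_mask == 1 & truth == 1)
  fp <- sum(pred_mask == 1 & truth == 0)
  fn <- sum(pred_mask == 0 & truth == 1)
  tn <- sum(pred_mask == 0 & truth == 0)
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

#' Segmentation metrics from confusion counts
#'
#' IoU = TP/(TP+FP+FN), DSC = 2TP/(2TP+FP+FN), SEN = TP/(TP+FN),
#' PRE = TP/(TP+FP). Degenerate images: an empty truth with an empty
#' prediction scores 1 on all metrics; an empty truth with a nonempty
#' prediction reports SEN = 0 and sets the `degenerate` flag.
#'
#' @param counts named vector from [confusion_counts()].
#' @return a `metrics_report` list with `iou`, `dsc`, `sen`, `pre`,
#'   `counts` and `degenerate`.
#' @export
segmentation_metrics <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  degenerate <- FALSE
  if (tp + fp + fn == 0) {
    iou <- dsc <- sen <- pre <- 1
  } else {
    iou <- tp / (tp + fp + fn)
    dsc <- 2 * tp / (2 * tp + fp + fn)
    sen <- if (tp + fn > 0) tp / (tp + fn) else { degenerate <- TRUE; 0 }
    pre <- if (tp + fp > 0) tp / (tp + fp) else 0
  }
  structure(list(iou = iou, dsc = dsc, sen = sen, pre = pre,
                 counts = counts, degenerate = degenerate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("IoU %.4f  DSC %.4f  SEN %.4f  PRE %.4f\n",
              x$iou, x$dsc, x$sen, x$pre))
  invisible(x)
}

#' Evaluate predicted masks against ground truth
#'
#' @param pred_masks,truths lists of binary matrices (or single matrices).
#' @param aggregate `"macro"` (mean of per-image metrics, the reporting
#'   convention used here) or `"micro"` (metrics of pooled pixel counts).
#' @return list with `per_image` (data frame) and `summary`
#'   (a `metrics_report`).
#' @export
evaluate_masks <- function(pred_masks, truths,
                           aggregate = c("macro", "micro")) {
  aggregate <- match.arg(aggregate)
  if (is.matrix(pred_masks)) pred_masks <- list(pred_masks)
  if (is.matrix(truths)) truths <- list(truths)
  stopifnot(length(pred_masks) == length(truths))
  reps <- Map(function(p, y) segmentation_metrics(confusion_counts(p, y)),
              pred_masks, truths)
  per <- data.frame(
    image = seq_along(reps),
    iou = vapply(reps, `[[`, numeric(1), "iou"),
    dsc = vapply(reps, `[[`, numeric(1), "dsc"),
    sen = vapply(reps, `[[`, numeric(1), "sen"),
    pre = vapply(reps, `[[`, numeric(1), "pre"))
  if (aggregate == "macro") {
    summary <- structure(list(iou = mean(per$iou), dsc = mean(per$dsc),
                              sen = mean(per$sen), pre = mean(per$pre),
                              counts = NULL, degenerate = FALSE),
                         class = "metrics_report")
  } else {
    pooled <- Reduce(`+`, Map(confusion_counts, pred_masks, truths))
    summary <- segmentation_metrics(pooled)
  }
  list(per_image = per, summary = summary, n_images = length(reps))
}
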