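#' Intersection over union of two binary masks
#'
#' `|X intersect Y| / |X union Y|`. When both masks are empty the score is 1,
#' mirroring the competition's Dice convention, so threshold tuning does not
#' penalize correct negatives.
#'
#' @param pred,truth Binary matrices of equal shape.
#' @return Scalar in \[0, 1\].
#' @export
iou <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  p <- pred != 0; y <- truth != 0
  u <- sum(p | y)
  if (u == 0) return(1)
  sum(p & y) / u
}

#' Pixel confusion counts and derived rates
#'
#' Pixel-pooled (micro) aggregation: counts are summed over all supplied
#' mask pairs, then accuracy `(TP+TN)/(TP+FP+FN+TN)`, precision `TP/(TP+FP)`,
#' recall `TP/(TP+FN)` and F-measure `2TP/(2TP+FP+FN)` are computed from the
#' pooled counts. Precision/recall/F-measure return 0 when their denominator
#' is 0.
#'
#' @param pred,truth A binary matrix each, or equal-length lists of matrices.
#' @return List with `tp`, `fp`, `fn`, `tn`, `accuracy`, `precision`,
#'   `recall`, `f_measure`.
#' @export
confusion <- function(pred, truth) {
  if (is.matrix(pred)) pred <- list(pred)
  if (is.matrix(truth)) truth <- list(truth)
  stopifnot(length(pred) == length(truth))
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(pred)) {
    if (!identical(dim(pred[[i]]), dim(truth[[i]]))) stop("shape mismatch")
    p <- pred[[i]] != 0; y <- truth[[i]] != 0
    tp <- tp + sum(p & y)
    fp <- fp + sum(p & !y)
    fn <- fn + sum(!p & y)
    tn <- tn + sum(!p & !y)
  }
  sdiv <- function(a, b) if (b == 0) 0 else a / b
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       accuracy = sdiv(tp + tn, tp + fp + fn + tn),
       precision = sdiv(tp, tp + fp),
       recall = sdiv(tp, tp + fn),
       f_measure = sdiv(2 * tp, 2 * tp + fp + fn))
}

#' Peak signal-to-noise ratio between two binary masks, in dB
#'
#' Masks are rescaled to \{0, 255\} and compared via
#' `20 * log10(255 / sqrt(MSE))`. Identical masks (MSE 0) return `cap`
#' (default `Inf`).
#'
#' @param pred,truth Binary matrices of equal shape.
#' @param cap Value returned for identical masks.
#' @return PSNR in dB.
#' @export
psnr_db <- function(pred, truth, cap = Inf) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  d <- (pred - truth) * 255
  mse <- mean(d * d)
  if (mse == 0) return(cap)
  20 * log10(255 / sqrt(mse))
}

#' Per-image Dice similarity coefficient
#'
#' `2|X intersect Y| / (|X| + |Y|)`, defined to be 1 when both X and Y are
#' empty (the competition convention).
#'
#' @param pred,truth Binary matrices of equal shape.
#' @return Scalar in \[0, 1\].
#' @export
dsc <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  p <- pred != 0; y <- truth != 0
  den <- sum(p) + sum(y)
  if (den == 0) return(1)
  2 * sum(p & y) / den
}

#' Mean Dice over an image set (macro aggregation)
#'
#' @param preds,truths Equal-length lists of shape-matched binary masks.
#' @return Mean of the per-image DSC.
#' @export
mean_dsc <- function(preds, truths) {
  if (length(preds) != length(truths)) stop("length mismatch")
  mean(mapply(dsc, preds, truths))
}

#' Full metric report over an image set
#'
#' Macro (per-image mean) IoU, DSC and PSNR; micro (pixel-pooled) confusion
#' rates — the two aggregation styles used when reporting segmentation
#' results per model and per pixel.
#'
#' @param preds,truths Equal-length lists of shape-matched binary masks.
#' @param psnr_cap Sentinel for identical masks (default `Inf`).
#' @return A `metric_report` list: `iou`, `mean_dsc`, `accuracy`, `precision`,
#'   `recall`, `f_measure`, `psnr_db`, `n_images`.
#' @export
metric_report <- function(preds, truths, psnr_cap = Inf) {
  if (length(preds) != length(truths)) stop("length mismatch")
  cm <- confusion(preds, truths)
  structure(list(
    iou = mean(mapply(iou, preds, truths)),
    mean_dsc = mean_dsc(preds, truths),
    accuracy = cm$accuracy, precision = cm$precision,
    recall = cm$recall, f_measure = cm$f_measure,
    psnr_db = mean(mapply(psnr_db, preds, truths, MoreArgs = list(cap = psnr_cap))),
    n_images = length(preds)), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "metric_report (%d images): IoU %.4f | DSC %.4f | acc %.4f | prec %.4f | rec %.4f | F %.4f | PSNR %.2f dB\n",
    x$n_images, x$iou, x$mean_dsc, x$accuracy, x$precision, x$recall,
    x$f_measure, x$psnr_db))
  invisible(x)
}
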