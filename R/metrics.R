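# 2D segmentation metrics.

.asClassMatrix <- function(x, scheme) {
  if (length(dim(x)) == 3L) decodeLabelImage(x, scheme) else x
}

#' Per-image 2D segmentation metrics
#'
#' Per-class intersection over union
#' \code{IoU_c = |pred == c AND true == c| / |pred == c OR true == c|},
#' summed over pixels; pixel accuracy; precision (macro average over
#' predicted classes of correctly-detected over predicted pixels); mean
#' IoU over classes present in the ground truth or the prediction (classes
#' absent from both are undefined and excluded); and the adult-teeth mean
#' IoU, the same mean restricted to permanent tooth classes (third molars,
#' primary teeth, rugae and background excluded).
#'
#' @param pred,truth integer class-id matrices of equal size, or H x W x 3
#'   palette rasters in [0,1].
#' @param scheme a [LabelScheme-class].
#' @return list with \code{perClassIoU} (named, NA = class absent from
#'   both), \code{pixelAccuracy}, \code{precision}, \code{meanIoU},
#'   \code{adultTeethMeanIoU}.
#' @export
metrics2D <- function(pred, truth, scheme = defaultLabelScheme()) {
  pred <- .asClassMatrix(pred, scheme)
  truth <- .asClassMatrix(truth, scheme)
  if (!all(dim(pred) == dim(truth))) stop("image sizes differ")
  ids <- scheme@entries$id
  iou <- stats::setNames(rep(NA_real_, length(ids)), scheme@entries$name)
  prec <- rep(NA_real_, length(ids))
  for (k in seq_along(ids)) {
    p <- pred == ids[k]
    t <- truth == ids[k]
    u <- sum(p | t)
    if (u > 0) iou[k] <- sum(p & t) / u
    np <- sum(p)
    if (np > 0) prec[k] <- sum(p & t) / np
  }
  adult <- scheme@entries$role == "permanent-tooth"
  list(perClassIoU = iou,
       pixelAccuracy = mean(pred == truth),
       precision = mean(prec, na.rm = TRUE),
       meanIoU = mean(iou, na.rm = TRUE),
       adultTeethMeanIoU = if (all(is.na(iou[adult]))) NA_real_
                           else mean(iou[adult], na.rm = TRUE))
}

#' Dataset-level metrics: the average of per-image means
#'
#' Evaluates [metrics2D()] per image pair and averages the per-image
#' summaries over images (the average of means -- not pixel-pooled, so an
#' image with small class areas weighs the same as one with large areas).
#' Per-class IoUs are averaged per class over the images where the class
#' is defined.
#'
#' @param pairs list of \code{list(pred = , truth = )} image pairs
#'   (class-id matrices or palette rasters).
#' @param scheme a [LabelScheme-class].
#' @return list with \code{perClassIoU}, \code{pixelAccuracy},
#'   \code{precision}, \code{meanIoU} (average of per-image mean IoUs),
#'   \code{adultTeethMeanIoU}, and \code{perImage} (data.frame).
#' @export
datasetMetrics <- function(pairs, scheme = defaultLabelScheme()) {
  if (length(pairs) == 0L) stop("empty test set")
  per <- lapply(pairs, function(p) metrics2D(p$pred, p$truth, scheme))
  iouMat <- do.call(rbind, lapply(per, `[[`, "perClassIoU"))
  perImage <- data.frame(
    pixelAccuracy = vapply(per, `[[`, 0, "pixelAccuracy"),
    precision = vapply(per, `[[`, 0, "precision"),
    meanIoU = vapply(per, `[[`, 0, "meanIoU"),
    adultTeethMeanIoU = vapply(per, function(x)
      if (is.na(x$adultTeethMeanIoU)) NA_real_ else x$adultTeethMeanIoU, 0)
  )
  list(perClassIoU = colMeans(iouMat, na.rm = TRUE),
       pixelAccuracy = mean(perImage$pixelAccuracy),
       precision = mean(perImage$precision),
       meanIoU = mean(perImage$meanIoU),
       adultTeethMeanIoU = mean(perImage$adultTeethMeanIoU, na.rm = TRUE),
       perImage = perImage)
}

#' Write per-class IoU scores as a CSV table
#'
#' One row per class in scheme order plus summary rows, mirroring the
#' usual per-class score table layout; undefined classes print as "-".
#' @param metrics result of [metrics2D()] or [datasetMetrics()].
#' @param path output path.
#' @export
writeMetricsCSV <- function(metrics, path) {
  iou <- metrics$perClassIoU
  rows <- data.frame(
    class = c(names(iou), "Average Accuracy", "Average Precision",
              "Average mean IoU", "Adult Teeth Average Mean IoU"),
    score = c(ifelse(is.na(iou), "-", sprintf("%.4f", iou)),
              sprintf("%.4f", metrics$pixelAccuracy),
              sprintf("%.4f", metrics$precision),
              sprintf("%.4f", metrics$meanIoU),
              sprintf("%.4f", metrics$adultTeethMeanIoU)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
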