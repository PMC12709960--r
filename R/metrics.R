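# Pooled mean intersection-over-union and canopy-coverage statistics.
# Pooling order matters: intersections and unions are summed across all
# images of a set before dividing, then averaged over the two classes, so
# large images and frequent classes weigh in proportion to their pixels.

pooledClassIoU <- function(pred, gt) {
  interFg <- 0; unionFg <- 0; interBg <- 0; unionBg <- 0
  for (k in seq_along(pred)) {
    p <- pixelValues(pred[[k]]); g <- pixelValues(gt[[k]])
    interFg <- interFg + sum(p == 1 & g == 1)
    unionFg <- unionFg + sum(p == 1 | g == 1)
    interBg <- interBg + sum(p == 0 & g == 0)
    unionBg <- unionBg + sum(p == 0 | g == 0)
  }
  # a class absent from every prediction and every ground truth is scored
  # as perfectly segmented (union zero)
  c(background = if (unionBg == 0) 1 else interBg / unionBg,
    crop = if (unionFg == 0) 1 else interFg / unionFg)
}

#' Pooled mIoU over a set of mask pairs
#'
#' For each class c (background, crop) the pooled IoU is
#' \deqn{IoU_c = \sum_n |M_n(c) \cap M^{gt}_n(c)| \;/\;
#' \sum_n |M_n(c) \cup M^{gt}_n(c)|,} and mIoU is the mean over the two
#' classes. When \code{groups} is supplied a per-group breakdown is
#' computed the same way on the subsets; the overall numbers always equal
#' the ungrouped pooled computation.
#'
#' @param pred list of predicted \code{CropMask}s
#' @param gt list of ground-truth \code{CropMask}s, pairwise same shapes
#' @param groups optional character vector of group labels per pair
#' @return an \code{\linkS4class{EvalReport}}
#' @examples
#' gt <- CropMask(rbind(c(1,1,0,0), c(1,1,0,0), c(0,0,0,0), c(0,0,0,0)))
#' pr <- CropMask(rbind(c(0,1,1,0), c(0,1,1,0), c(0,0,0,0), c(0,0,0,0)))
#' miou(list(pr), list(gt))@miou  # 11/21
#' @export
miou <- function(pred, gt, groups = NULL) {
  if (!is.list(pred)) pred <- list(pred)
  if (!is.list(gt)) gt <- list(gt)
  stopDim(length(pred) == length(gt), "pred and gt lists must match")
  if (length(pred) == 0L) stop("no mask pairs to evaluate", call. = FALSE)
  for (k in seq_along(pred))
    stopDim(all(dim(pred[[k]]) == dim(gt[[k]])),
            sprintf("mask pair %d shapes differ", k))
  cls <- pooledClassIoU(pred, gt)
  perGroup <- data.frame(group = character(0), iouBackground = numeric(0),
                         iouCrop = numeric(0), miou = numeric(0),
                         n = integer(0), stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    stopDim(length(groups) == length(pred), "groups length must match")
    for (gname in unique(groups)) {
      sel <- which(groups == gname)
      gcls <- pooledClassIoU(pred[sel], gt[sel])
      perGroup <- rbind(perGroup, data.frame(
        group = gname, iouBackground = gcls[["background"]],
        iouCrop = gcls[["crop"]], miou = mean(gcls),
        n = length(sel), stringsAsFactors = FALSE))
    }
  }
  new("EvalReport", classIoU = cls, miou = mean(cls), perGroup = perGroup,
      n = length(pred))
}

#' Canopy coverage of a mask
#'
#' The fraction of image pixels labeled crop. High-coverage scenes (dense
#' canopies) are the known hard case for depth-based thresholding, since
#' the ground plane all but disappears from the histogram.
#'
#' @param mask a \code{CropMask}
#' @return real in \[0, 1\]
#' @export
canopyCoverage <- function(mask) {
  stopifnot(is(mask, "CropMask"))
  mean(pixelValues(mask) == 1)
}

#' Histogram of canopy coverages
#'
#' Bins are half-open \[lo, hi) with the last bin closed, so a coverage
#' exactly on an interior breakpoint counts toward the upper bin.
#'
#' @param masks list of \code{CropMask}s (or a numeric vector of coverages)
#' @param breaks strictly increasing breakpoints spanning \[0, 1\]
#' @return integer vector of counts, one per bin; sums to the mask count
#' @export
coverageHistogram <- function(masks, breaks = seq(0, 1, by = 0.2)) {
  if (any(diff(breaks) <= 0) || breaks[1] < 0 ||
      breaks[length(breaks)] > 1 || length(breaks) < 2L)
    stop("breaks must be strictly increasing within [0, 1]", call. = FALSE)
  cov <- if (is.numeric(masks)) masks
         else vapply(masks, canopyCoverage, numeric(1))
  if (length(cov) == 0L) return(integer(length(breaks) - 1L))
  bin <- findInterval(cov, breaks, rightmost.closed = TRUE)
  if (any(bin < 1L | bin > length(breaks) - 1L))
    stop("coverage values outside the binned range", call. = FALSE)
  tabulate(bin, nbins = length(breaks) - 1L)
}
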