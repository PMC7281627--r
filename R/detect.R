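# Nucleus segmentation from the hematoxylin concentration map:
# Gaussian smoothing, OD threshold, hole filling, distance-transform
# watershed, then an area filter. EBImage supplies the image primitives.

#' Construct segmentation parameters
#'
#' Defaults were fixed against the synthetic generator's default geometry:
#' an OD threshold of 0.15 on the hematoxylin map, 1.5 px Gaussian
#' smoothing, admissible areas 30-4000 px^2, and a 7 px minimum watershed
#' seed spacing.
#'
#' @param odThreshold foreground threshold (OD units).
#' @param minArea,maxArea admissible nucleus area (px^2).
#' @param smoothingSigma Gaussian pre-smoothing sigma (px); 0 disables.
#' @param minPeakDistance minimum distance between watershed seeds (px).
#' @param fillHoles fill holes in the binary mask.
#' @return a \code{\linkS4class{SegmentationParams}}.
#' @export
segmentationParams <- function(odThreshold = 0.15, minArea = 30,
                               maxArea = 4000, smoothingSigma = 1.5,
                               minPeakDistance = 7, fillHoles = TRUE) {
  new("SegmentationParams", odThreshold = odThreshold, minArea = minArea,
      maxArea = maxArea, smoothingSigma = smoothingSigma,
      minPeakDistance = minPeakDistance, fillHoles = fillHoles)
}

# Relabel a label matrix so labels are consecutive from 1, in raster order
# of first appearance.
.relabel <- function(mask) {
  labs <- unique(as.integer(mask[mask > 0]))
  if (!length(labs)) return(matrix(0L, nrow(mask), ncol(mask)))
  remap <- integer(max(labs))
  remap[labs] <- seq_along(labs)
  out <- matrix(0L, nrow(mask), ncol(mask))
  nz <- mask > 0
  out[nz] <- remap[as.integer(mask[nz])]
  out
}

#' Detect nuclei on a hematoxylin map
#'
#' Pipeline: Gaussian smooth, threshold at \code{odThreshold}, fill holes,
#' distance-transform watershed with seed maxima at least
#' \code{minPeakDistance} apart, discard components outside
#' [\code{minArea}, \code{maxArea}], relabel consecutively. An empty mask
#' is a valid result.
#'
#' @param hematoxylinMap non-negative numeric matrix (OD-equivalent
#'   concentration, e.g. from \code{\link{deconvolve}}).
#' @param params a \code{\linkS4class{SegmentationParams}}.
#' @return integer label matrix (0 background, labels consecutive from 1).
#' @export
detectNuclei <- function(hematoxylinMap, params = segmentationParams()) {
  if (min(hematoxylinMap) < 0)
    stop("hematoxylin map must be non-negative")
  x <- EBImage::Image(hematoxylinMap)
  if (params@smoothingSigma > 0)
    x <- EBImage::gblur(x, sigma = params@smoothingSigma)
  mask <- x > params@odThreshold
  if (!any(mask)) return(matrix(0L, nrow(hematoxylinMap),
                                ncol(hematoxylinMap)))
  if (params@fillHoles) mask <- EBImage::fillHull(mask)
  dm <- EBImage::distmap(mask)
  # seed-detection neighborhood radius = half the minimum seed spacing:
  # two distance-map maxima closer than minPeakDistance share a window
  ws <- EBImage::watershed(dm, tolerance = 1,
                           ext = max(1L, as.integer(
                             ceiling(params@minPeakDistance / 2))))
  lab <- matrix(as.integer(EBImage::imageData(ws)),
                nrow(hematoxylinMap), ncol(hematoxylinMap))
  sizes <- tabulate(lab[lab > 0])
  bad <- which(sizes < params@minArea | sizes > params@maxArea)
  if (length(bad)) lab[lab %in% bad] <- 0L
  .relabel(lab)
}

#' Match a predicted label mask to ground truth
#'
#' Greedy intersection-over-union matching: candidate (predicted, truth)
#' pairs are ranked by IoU and accepted while both sides are unmatched and
#' IoU >= \code{iouThreshold}. A truth nucleus with an accepted match is
#' "detected"; the rest are "missed"; unmatched predictions are "spurious".
#'
#' @param mask predicted integer label matrix.
#' @param truthMask ground-truth label matrix of the same shape (e.g.
#'   \code{coreLabelMask} of a \code{\linkS4class{SyntheticCore}}).
#' @param iouThreshold minimum IoU to count as detected (default 0.5).
#' @return list with \code{detected}, \code{missed}, \code{spurious}
#'   counts, \code{recall}, \code{precision}, and a \code{pairs}
#'   data.frame (pred_label, truth_label, iou).
#' @export
matchToTruth <- function(mask, truthMask, iouThreshold = 0.5) {
  if (!identical(dim(mask), dim(truthMask)))
    stop("mask and truth mask must share the same shape")
  nP <- max(mask, 0L); nT <- max(truthMask, 0L)
  areaP <- tabulate(mask[mask > 0], nbins = max(nP, 1))
  areaT <- tabulate(truthMask[truthMask > 0], nbins = max(nT, 1))
  both <- mask > 0 & truthMask > 0
  pairs <- data.frame(pred_label = integer(0), truth_label = integer(0),
                      iou = numeric(0))
  if (any(both)) {
    key <- paste(mask[both], truthMask[both])
    tab <- table(key)
    ij <- do.call(rbind, strsplit(names(tab), " "))
    p <- as.integer(ij[, 1]); t <- as.integer(ij[, 2])
    inter <- as.integer(tab)
    iou <- inter / (areaP[p] + areaT[t] - inter)
    ord <- order(-iou)
    usedP <- logical(nP); usedT <- logical(nT)
    keep <- logical(length(ord))
    for (k in ord) {
      if (iou[k] < iouThreshold) break
      if (!usedP[p[k]] && !usedT[t[k]]) {
        usedP[p[k]] <- TRUE; usedT[t[k]] <- TRUE; keep[k] <- TRUE
      }
    }
    pairs <- data.frame(pred_label = p[keep], truth_label = t[keep],
                        iou = iou[keep])
  }
  detected <- nrow(pairs)
  list(detected = detected,
       missed = nT - detected,
       spurious = nP - detected,
       recall = if (nT > 0) detected / nT else NA_real_,
       precision = if (nP > 0) detected / nP else NA_real_,
       pairs = pairs)
}
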