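#' @include AllClasses.R
NULL

# Masked local mean: mean of tendon pixels inside the w x w window centred
# on each pixel. Pixels outside the tendon ROI contribute nothing.
.maskedLocalMean <- function(pixels, mask, w) {
  num <- boxSum(pixels * mask, w)
  den <- boxSum(mask * 1.0, w)
  out <- num / pmax(den, 1e-12)
  out[den == 0] <- NA_real_
  out
}

#' Locally adaptive lesion segmentation inside the SDFT ROI
#'
#' Labels a tendon pixel as lesion when its intensity exceeds the local mean
#' over a `filterWidthPx`-wide square window — computed over SDFT pixels
#' only, so tissue outside the tendon cannot suppress detection — by more
#' than the offset margin (see [AdaptiveSegParams-class] for the relative /
#' absolute offset modes). Components smaller than `minLesionPx` are
#' removed; by default only the largest surviving component is kept.
#'
#' The returned mask is always a subset of the SDFT mask. A uniform tendon
#' yields an empty mask for any positive offset (in relative mode a uniform
#' tendon has zero robust SD, and no pixel strictly exceeds its own local
#' mean).
#'
#' @param slice An [MriSlice-class].
#' @param sdft Non-empty SDFT [RoiMask-class].
#' @param params An [AdaptiveSegParams-class].
#' @return Lesion [RoiMask-class] (role `lesion_auto`).
#' @export
localAdaptiveSegment <- function(slice, sdft, params = AdaptiveSegParams()) {
  validObject(params)
  if (!any(sdft@mask)) stop("SDFT mask is empty")
  px <- slice@pixels
  if (!identical(dim(px), dim(sdft@mask)))
    stop("SDFT mask grid does not match the slice grid")
  if (params@filterWidthPx > nrow(px))
    stop("filter width exceeds the image size")
  offset <- if (params@offsetMode == "relative") {
    params@offset * stats::mad(px[sdft@mask])
  } else params@offset
  localMean <- .maskedLocalMean(px, sdft@mask, params@filterWidthPx)
  cand <- sdft@mask & !is.na(localMean) & (px > localMean + offset)
  if (any(cand)) {
    labels <- connectedComponents(cand, params@connectivity)
    sizes <- tabulate(labels[labels > 0L])
    keep <- which(sizes >= params@minLesionPx)
    if (length(keep) > 0L && !params@keepAllComponents)
      keep <- keep[which.max(sizes[keep])]
    cand <- matrix(labels %in% keep, nrow(cand), ncol(cand)) & cand
  }
  RoiMask(mask = cand, role = "lesion_auto")
}

#' Binary lesion detection from an automated mask
#'
#' @param mask Lesion mask from [localAdaptiveSegment()].
#' @param params An [AdaptiveSegParams-class]; detection requires at least
#'   `minLesionPx` surviving pixels (boundary inclusive).
#' @return `TRUE` if a lesion is detected.
#' @export
detectLesion <- function(mask, params = AdaptiveSegParams()) {
  sum(mask@mask) >= params@minLesionPx
}

#' Automated lesion measurement on one slice
#'
#' Runs [localAdaptiveSegment()] and measures CSA and SI on the resulting
#' mask. When no lesion is detected the record carries zero CSA and an
#' absent (`NA`) SI.
#'
#' @param slice An [MriSlice-class].
#' @param sdft SDFT [RoiMask-class].
#' @param params An [AdaptiveSegParams-class].
#' @param geometry An [MriGeometry-class].
#' @return One-row data.frame: `levelIndex`, `detected`, `csaMm2`,
#'   `meanSi`, `sdSi`, `nPixels`.
#' @export
automatedMeasurement <- function(slice, sdft, params = AdaptiveSegParams(),
                                 geometry = MriGeometry()) {
  mask <- localAdaptiveSegment(slice, sdft, params)
  detected <- detectLesion(mask, params)
  if (detected) {
    si <- measureSi(slice, mask)
    data.frame(levelIndex = slice@levelIndex, detected = TRUE,
               csaMm2 = roiAreaMm2(mask, geometry),
               meanSi = meanSi(si), sdSi = sdSi(si), nPixels = nPixels(si))
  } else {
    data.frame(levelIndex = slice@levelIndex, detected = FALSE,
               csaMm2 = 0, meanSi = NA_real_, sdSi = NA_real_, nPixels = 0L)
  }
}
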