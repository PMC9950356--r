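#' @include AllClasses.R
NULL

#' Build per-slice lesion records from masks
#'
#' @param stack An [MriStack-class].
#' @param lesionMasks Per-slice lesion [RoiMask-class] list (stack order),
#'   e.g. ground truth or automated masks.
#' @return data.frame: `levelIndex`, `csaMm2`, `meanSi`, `sdSi`, `nPixels`
#'   (SI columns `NA` where the lesion mask is empty).
#' @export
lesionSliceRecords <- function(stack, lesionMasks) {
  stopifnot(length(lesionMasks) == length(stack))
  g <- geometry(stack)
  do.call(rbind, lapply(seq_along(lesionMasks), function(i) {
    mk <- lesionMasks[[i]]
    sl <- stack[[i]]
    if (any(mk@mask)) {
      si <- measureSi(sl, mk)
      data.frame(levelIndex = levelIndex(sl), csaMm2 = roiAreaMm2(mk, g),
                 meanSi = meanSi(si), sdSi = sdSi(si), nPixels = nPixels(si))
    } else {
      data.frame(levelIndex = levelIndex(sl), csaMm2 = 0,
                 meanSi = NA_real_, sdSi = NA_real_, nPixels = 0L)
    }
  }))
}

#' Level of maximum lesion cross-sectional area
#'
#' Ties are broken toward proximal (the smaller level index). When every
#' CSA is zero there is no lesion: `lesionPresent` is `FALSE` and the level
#' is `NA` (a signal distinct from an error).
#'
#' @param records data.frame with `levelIndex` and `csaMm2` columns.
#' @return List: `levelIndex`, `csaMm2`, `lesionPresent`.
#' @export
maxCsaLevel <- function(records) {
  stopifnot(nrow(records) >= 1L)
  if (all(records$csaMm2 <= 0))
    return(list(levelIndex = NA_integer_, csaMm2 = 0, lesionPresent = FALSE))
  ord <- order(-records$csaMm2, records$levelIndex)
  top <- records[ord[1L], ]
  list(levelIndex = top$levelIndex, csaMm2 = top$csaMm2, lesionPresent = TRUE)
}

#' Lesion CSA at a fixed level
#'
#' CSA read at the level of the initial maximum lesion ("CSA fixed");
#' returns 0 when the lesion no longer reaches that level.
#'
#' @param records data.frame with `levelIndex` and `csaMm2`.
#' @param fixedLevel Level index; must be present in the records.
#' @return CSA in mm^2.
#' @export
csaAtFixedLevel <- function(records, fixedLevel) {
  i <- match(fixedLevel, records$levelIndex)
  if (is.na(i)) stop("level ", fixedLevel, " is outside the recorded stack")
  records$csaMm2[i]
}

#' Lesion volume from per-slice CSAs
#'
#' `sum(CSA) * spacing`, where the default spacing is the centre-to-centre
#' slice distance (thickness + gap): each slice stands for the tissue up to
#' the next slice, the standard stereological choice for gapped
#' acquisitions. Pass `spacingMm = sliceThickness` to exclude the gaps.
#'
#' @param records data.frame with `csaMm2` covering every lesion-bearing
#'   level.
#' @param geometry An [MriGeometry-class].
#' @param spacingMm Slice-to-volume multiplier in mm.
#' @return Volume in mm^3.
#' @export
lesionVolume <- function(records, geometry,
                         spacingMm = sliceSpacing(geometry)) {
  sum(records$csaMm2) * spacingMm
}

#' Shift of the maximum-lesion level, in mm
#'
#' `(referenceLevel - currentMaxLevel) * sliceSpacing`; positive values are
#' a shift toward proximal (smaller level indices are proximal).
#'
#' @param currentMaxLevel Maximum-lesion level at the current examination.
#' @param referenceLevel The fixed reference level (initial maximum).
#' @param geometry An [MriGeometry-class].
#' @return Signed distance in mm.
#' @export
levelShift <- function(currentMaxLevel, referenceLevel, geometry) {
  (referenceLevel - currentMaxLevel) * sliceSpacing(geometry)
}

#' Summarise a lesion time course
#'
#' Per time point: CSA at the fixed reference level (the maximum level of
#' the first examination), CSA at the current maximum level, that level,
#' lesion volume, and the level shift. Time points without any lesion keep
#' a rectangular row of zeros with `shiftUndefined = TRUE`.
#'
#' @param recordsByTime List of per-slice record data.frames (one per time
#'   point, as from [lesionSliceRecords()]).
#' @param geometry An [MriGeometry-class].
#' @param spacingMm Volume multiplier, as in [lesionVolume()].
#' @return data.frame with one row per time point: `timePoint`,
#'   `csaFixedMm2`, `csaMaxMm2`, `maxLevelIndex`, `volumeMm3`,
#'   `levelShiftMm`, `shiftUndefined`.
#' @export
lesionSeriesSummary <- function(recordsByTime, geometry,
                                spacingMm = sliceSpacing(geometry)) {
  stopifnot(length(recordsByTime) >= 1L)
  first <- maxCsaLevel(recordsByTime[[1L]])
  refLevel <- first$levelIndex
  do.call(rbind, lapply(seq_along(recordsByTime), function(t) {
    rec <- recordsByTime[[t]]
    mx <- maxCsaLevel(rec)
    undef <- !mx$lesionPresent || !first$lesionPresent
    data.frame(
      timePoint = t,
      csaFixedMm2 = if (first$lesionPresent)
        csaAtFixedLevel(rec, refLevel) else 0,
      csaMaxMm2 = mx$csaMm2,
      maxLevelIndex = if (mx$lesionPresent) mx$levelIndex else NA_integer_,
      volumeMm3 = lesionVolume(rec, geometry, spacingMm),
      levelShiftMm = if (undef) NA_real_ else
        levelShift(mx$levelIndex, refLevel, geometry),
      shiftUndefined = undef)
  }))
}
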