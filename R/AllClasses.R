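#' @include AllGenerics.R
NULL

.SEQUENCE_LABELS <- c("T1w_GRE", "T2*w_GRE", "T2w_FSE", "STIR")

.ROI_ROLES <- c("lesion_whole", "lesion_circle_max", "lesion_circle_1mm2",
                "lesion_auto", "sdft", "cortical_bone",
                "background_lateral", "background_medial", "background_palmar")

#' Supported MRI sequence labels and ROI roles
#'
#' @return Character vector of the labels the package recognises.
#' @export
sequenceLabels <- function() .SEQUENCE_LABELS

#' @rdname sequenceLabels
#' @export
roiRoles <- function() .ROI_ROLES

# ---------------------------------------------------------------------------
# MriGeometry
# ---------------------------------------------------------------------------

#' Physical geometry of a transverse MRI acquisition
#'
#' Square field of view, acquisition matrix, slice thickness and inter-slice
#' gap. Derived quantities: in-plane pixel spacing
#' (`fieldOfViewMm / matrixSize`) and centre-to-centre slice spacing
#' (`sliceThicknessMm + sliceGapMm`).
#'
#' Pixel coordinate convention: matrices are indexed `[row, column]`, row 1 at
#' the image top; the physical position of pixel `(i, j)` is its centre, at
#' `((i - 0.5) * spacing, (j - 0.5) * spacing)` mm. A slice's physical
#' position along the limb axis is `levelIndex * sliceSpacing`; smaller level
#' indices are proximal.
#'
#' @slot fieldOfViewMm Square field-of-view edge length in mm.
#' @slot matrixSize Pixels per image edge.
#' @slot sliceThicknessMm Slice thickness in mm.
#' @slot sliceGapMm Inter-slice gap in mm.
#'
#' @param fieldOfViewMm,matrixSize,sliceThicknessMm,sliceGapMm See slots.
#' @return An `MriGeometry` object.
#' @examples
#' g <- MriGeometry()   # the default low-field protocol
#' pixelSpacing(g)      # 171 / 256 = 0.66796875 mm
#' sliceSpacing(g)      # 5 + 1 = 6 mm
#' @export MriGeometry
#' @exportClass MriGeometry
MriGeometry <- setClass("MriGeometry",
  slots = c(fieldOfViewMm = "numeric", matrixSize = "integer",
            sliceThicknessMm = "numeric", sliceGapMm = "numeric"),
  prototype = prototype(fieldOfViewMm = 171, matrixSize = 256L,
                        sliceThicknessMm = 5, sliceGapMm = 1))

setValidity("MriGeometry", function(object) {
  v <- c(object@fieldOfViewMm, object@matrixSize, object@sliceThicknessMm)
  if (any(!is.finite(v)) || any(v <= 0))
    return("fieldOfViewMm, matrixSize and sliceThicknessMm must be positive")
  if (!is.finite(object@sliceGapMm) || object@sliceGapMm < 0)
    return("sliceGapMm must be non-negative")
  TRUE
})

#' @rdname MriGeometry
#' @param ... Passed through to the class generator.
#' @export
defaultGeometry <- function(...) MriGeometry(...)

setMethod("pixelSpacing", "MriGeometry",
          function(x) x@fieldOfViewMm / x@matrixSize)
setMethod("sliceSpacing", "MriGeometry",
          function(x) x@sliceThicknessMm + x@sliceGapMm)
setMethod("matrixSize", "MriGeometry", function(x) x@matrixSize)
setMethod("fieldOfView", "MriGeometry", function(x) x@fieldOfViewMm)

setMethod("show", "MriGeometry", function(object) {
  cat(sprintf(
    "MriGeometry: %g x %g mm FOV, %d x %d matrix (%.6g mm/px), slices %g mm + %g mm gap\n",
    object@fieldOfViewMm, object@fieldOfViewMm, object@matrixSize,
    object@matrixSize, pixelSpacing(object), object@sliceThicknessMm,
    object@sliceGapMm))
})

# ---------------------------------------------------------------------------
# MriSlice / MriStack
# ---------------------------------------------------------------------------

#' A single transverse MRI slice
#'
#' @slot pixels Numeric matrix of non-negative signal intensities
#'   (`matrixSize x matrixSize`).
#' @slot levelIndex Integer slice position; smaller is proximal.
#' @slot sequenceLabel One of [sequenceLabels()].
#' @slot timePoint Examination index (1-based).
#'
#' @param pixels,levelIndex,sequenceLabel,timePoint See slots.
#' @return An `MriSlice`.
#' @export MriSlice
#' @exportClass MriSlice
MriSlice <- setClass("MriSlice",
  slots = c(pixels = "matrix", levelIndex = "integer",
            sequenceLabel = "character", timePoint = "integer"),
  prototype = prototype(pixels = matrix(0, 1, 1), levelIndex = 1L,
                        sequenceLabel = "T1w_GRE", timePoint = 1L))

setValidity("MriSlice", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (any(!is.finite(p))) return("pixel intensities must be finite")
  if (any(p < 0)) return("pixel intensities must be non-negative")
  if (length(object@sequenceLabel) != 1L ||
      !object@sequenceLabel %in% .SEQUENCE_LABELS)
    return(paste("sequenceLabel must be one of:",
                 paste(.SEQUENCE_LABELS, collapse = ", ")))
  if (length(object@timePoint) != 1L || object@timePoint < 1L)
    return("timePoint must be a positive integer")
  TRUE
})

setMethod("pixels", "MriSlice", function(x) x@pixels)
setMethod("levelIndex", "MriSlice", function(x) x@levelIndex)
setMethod("sequenceLabel", "MriSlice", function(x) x@sequenceLabel)
setMethod("timePoint", "MriSlice", function(x) x@timePoint)

setMethod("show", "MriSlice", function(object) {
  cat(sprintf("MriSlice %d x %d, level %d, %s, time point %d\n",
              nrow(object@pixels), ncol(object@pixels), object@levelIndex,
              object@sequenceLabel, object@timePoint))
})

#' An ordered stack of transverse MRI slices
#'
#' Slices are ordered proximal to distal (strictly increasing `levelIndex`)
#' and share one sequence label and time point.
#'
#' @slot geometry An [MriGeometry-class] object.
#' @slot slices List of [MriSlice-class] objects.
#' @slot subjectId Subject identifier.
#'
#' @param geometry,slices,subjectId See slots.
#' @return An `MriStack`.
#' @export MriStack
#' @exportClass MriStack
MriStack <- setClass("MriStack",
  slots = c(geometry = "MriGeometry", slices = "list", subjectId = "character"),
  prototype = prototype(geometry = new("MriGeometry"), slices = list(),
                        subjectId = "subject"))

setValidity("MriStack", function(object) {
  sl <- object@slices
  if (length(sl) == 0L) return(TRUE)
  if (!all(vapply(sl, is, logical(1), class2 = "MriSlice")))
    return("slices must all be MriSlice objects")
  m <- matrixSize(object@geometry)
  dims <- vapply(sl, function(s) dim(s@pixels), integer(2))
  if (any(dims != m))
    return(sprintf("all slices must be %d x %d to match the geometry", m, m))
  lev <- vapply(sl, levelIndex, integer(1))
  if (any(diff(lev) <= 0)) return("levelIndex must be strictly increasing")
  if (length(unique(vapply(sl, sequenceLabel, character(1)))) != 1L)
    return("all slices must share one sequenceLabel")
  if (length(unique(vapply(sl, timePoint, integer(1)))) != 1L)
    return("all slices must share one timePoint")
  TRUE
})

setMethod("geometry", "MriStack", function(x) x@geometry)
setMethod("slices", "MriStack", function(x) x@slices)
setMethod("length", "MriStack", function(x) length(x@slices))

#' @param i Slice position (1-based, in stack order).
#' @rdname MriStack-class
#' @aliases [[,MriStack-method
#' @export
setMethod("[[", "MriStack", function(x, i) x@slices[[i]])

setMethod("levelIndex", "MriStack",
          function(x) vapply(x@slices, levelIndex, integer(1)))

setMethod("show", "MriStack", function(object) {
  n <- length(object@slices)
  cat(sprintf("MriStack '%s': %d slice(s)", object@subjectId, n))
  if (n > 0L)
    cat(sprintf(", levels %d..%d, %s, time point %d",
                min(levelIndex(object)), max(levelIndex(object)),
                sequenceLabel(object@slices[[1L]]),
                timePoint(object@slices[[1L]])))
  cat("\n")
  show(object@geometry)
})

# ---------------------------------------------------------------------------
# RoiMask
# ---------------------------------------------------------------------------

#' Binary region-of-interest mask on a slice grid
#'
#' @slot mask Logical matrix aligned to the slice pixel grid.
#' @slot role One of [roiRoles()].
#'
#' @param mask,role See slots.
#' @return A `RoiMask`.
#' @export RoiMask
#' @exportClass RoiMask
RoiMask <- setClass("RoiMask",
  slots = c(mask = "matrix", role = "character"),
  prototype = prototype(mask = matrix(FALSE, 1, 1), role = "lesion_whole"))

setValidity("RoiMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  if (any(is.na(object@mask))) return("mask must not contain NA")
  if (length(object@role) != 1L || !object@role %in% .ROI_ROLES)
    return(paste("role must be one of:", paste(.ROI_ROLES, collapse = ", ")))
  TRUE
})

setMethod("maskMatrix", "RoiMask", function(x) x@mask)
setMethod("roiRole", "RoiMask", function(x) x@role)
setMethod("nPixels", "RoiMask", function(x) sum(x@mask))

#' @rdname accessors
#' @param geometry An [MriGeometry-class] giving the pixel spacing.
#' @export
setMethod("roiAreaMm2", "RoiMask",
          function(x, geometry) sum(x@mask) * pixelSpacing(geometry)^2)

setMethod("show", "RoiMask", function(object) {
  cat(sprintf("RoiMask '%s': %d of %d pixels set (%d x %d grid)\n",
              object@role, sum(object@mask), length(object@mask),
              nrow(object@mask), ncol(object@mask)))
})

# ---------------------------------------------------------------------------
# SiMeasurement
# ---------------------------------------------------------------------------

#' Signal-intensity statistics within an ROI
#'
#' Mean and population standard deviation (divisor `n`) of the pixel
#' intensities under a mask, with the pixel count and the ROI role.
#'
#' @slot meanSi Mean signal intensity.
#' @slot sdSi Population SD of the intensities.
#' @slot nPixels Number of pixels measured.
#' @slot role ROI role the measurement came from.
#'
#' @param meanSi,sdSi,nPixels,role See slots.
#' @return An `SiMeasurement`.
#' @export SiMeasurement
#' @exportClass SiMeasurement
SiMeasurement <- setClass("SiMeasurement",
  slots = c(meanSi = "numeric", sdSi = "numeric", nPixels = "integer",
            role = "character"),
  prototype = prototype(meanSi = 0, sdSi = 0, nPixels = 1L,
                        role = "lesion_whole"))

setValidity("SiMeasurement", function(object) {
  if (object@nPixels < 1L) return("nPixels must be >= 1")
  if (!is.finite(object@meanSi)) return("meanSi must be finite")
  if (!is.finite(object@sdSi) || object@sdSi < 0)
    return("sdSi must be finite and >= 0")
  TRUE
})

setMethod("meanSi", "SiMeasurement", function(x) x@meanSi)
setMethod("sdSi", "SiMeasurement", function(x) x@sdSi)
setMethod("nPixels", "SiMeasurement", function(x) x@nPixels)
setMethod("roiRole", "SiMeasurement", function(x) x@role)

setMethod("show", "SiMeasurement", function(object) {
  cat(sprintf("SiMeasurement '%s': mean %.6g, SD %.6g over %d px\n",
              object@role, object@meanSi, object@sdSi, object@nPixels))
})

# ---------------------------------------------------------------------------
# CircleRoi
# ---------------------------------------------------------------------------

#' A circular ROI in physical coordinates
#'
#' @slot centreMm Numeric length-2 `(row, column)` position of the centre in
#'   mm (see [MriGeometry-class] for the coordinate convention).
#' @slot radiusMm Circle radius in mm.
#' @slot targetAreaMm2 Nominal area the circle realises (`pi * r^2` for
#'   derived circles, the requested area for fixed-area ROIs).
#'
#' @param centreMm,radiusMm,targetAreaMm2 See slots.
#' @return A `CircleRoi`.
#' @export CircleRoi
#' @exportClass CircleRoi
CircleRoi <- setClass("CircleRoi",
  slots = c(centreMm = "numeric", radiusMm = "numeric",
            targetAreaMm2 = "numeric"),
  prototype = prototype(centreMm = c(0, 0), radiusMm = 1, targetAreaMm2 = pi))

setValidity("CircleRoi", function(object) {
  if (length(object@centreMm) != 2L || any(!is.finite(object@centreMm)))
    return("centreMm must be a finite (row, column) pair in mm")
  if (!is.finite(object@radiusMm) || object@radiusMm <= 0)
    return("radiusMm must be > 0")
  if (!is.finite(object@targetAreaMm2) || object@targetAreaMm2 <= 0)
    return("targetAreaMm2 must be > 0")
  TRUE
})

setMethod("centreMm", "CircleRoi", function(x) x@centreMm)
setMethod("radiusMm", "CircleRoi", function(x) x@radiusMm)

setMethod("show", "CircleRoi", function(object) {
  cat(sprintf(
    "CircleRoi: centre (%.3f, %.3f) mm, radius %.4f mm, target area %.4g mm^2\n",
    object@centreMm[1L], object@centreMm[2L], object@radiusMm,
    object@targetAreaMm2))
})

# ---------------------------------------------------------------------------
# PhantomParams / GroundTruth
# ---------------------------------------------------------------------------

#' Parameters of the synthetic lesion phantom
#'
#' Controls the synthetic limb cross-section painted by [generateStack()]:
#' a noisy background, a soft-tissue limb disc, a dark cortical-bone annulus
#' with bright marrow, a low-signal SDFT (superficial digital flexor tendon)
#' ellipse, and — on lesion-bearing levels — a hyperintense elliptical lesion
#' with centre-weighted radial falloff. Lesion mean contrast over the SDFT is
#' `contrastK * severity`; the per-level lesion cross-sectional area follows
#' a unimodal parabolic profile peaking at `maxLevelIndex` with peak area
#' `maxCsaMm2`.
#'
#' @slot severity Lesion severity in `[0, 1]`; 0 paints no lesion.
#' @slot maxCsaMm2 Peak lesion cross-sectional area in mm^2.
#' @slot maxLevelIndex Level index of the peak lesion area.
#' @slot nLesionLevels Number of consecutive lesion-bearing levels.
#' @slot noiseSd Base Gaussian noise SD (intensity units) before the
#'   sequence-specific multiplier.
#' @slot sequenceSnrProfile Named numeric noise multipliers, one per
#'   [sequenceLabels()] entry. FSE/STIR default to 3x to emulate their longer
#'   acquisition and motion sensitivity.
#' @slot seed Integer seed; generation is fully reproducible from it.
#' @slot nLevels Number of slices in a stack.
#' @slot contrastK Lesion contrast factor: peak lesion SI is
#'   `sdftMeanSi * (1 + contrastK * severity)`.
#' @slot backgroundMeanSi,limbMeanSi,boneMeanSi,marrowMeanSi,sdftMeanSi Mean
#'   intensities of the painted tissue classes.
#'
#' @param severity,maxCsaMm2,maxLevelIndex,nLesionLevels,noiseSd See slots.
#' @param sequenceSnrProfile,seed,nLevels,contrastK See slots.
#' @param backgroundMeanSi,limbMeanSi,boneMeanSi,marrowMeanSi,sdftMeanSi See
#'   slots.
#' @return A `PhantomParams` object.
#' @export PhantomParams
#' @exportClass PhantomParams
PhantomParams <- setClass("PhantomParams",
  slots = c(severity = "numeric", maxCsaMm2 = "numeric",
            maxLevelIndex = "integer", nLesionLevels = "integer",
            noiseSd = "numeric", sequenceSnrProfile = "numeric",
            seed = "integer", nLevels = "integer", contrastK = "numeric",
            backgroundMeanSi = "numeric", limbMeanSi = "numeric",
            boneMeanSi = "numeric", marrowMeanSi = "numeric",
            sdftMeanSi = "numeric"),
  prototype = prototype(
    severity = 0.8, maxCsaMm2 = 30, maxLevelIndex = 6L, nLesionLevels = 5L,
    noiseSd = 4,
    sequenceSnrProfile = c("T1w_GRE" = 1, "T2*w_GRE" = 1.2,
                           "T2w_FSE" = 3, "STIR" = 3),
    seed = 1L, nLevels = 12L, contrastK = 1.5,
    backgroundMeanSi = 20, limbMeanSi = 90, boneMeanSi = 12,
    marrowMeanSi = 110, sdftMeanSi = 55))

setValidity("PhantomParams", function(object) {
  if (object@severity < 0 || object@severity > 1)
    return("severity must be in [0, 1]")
  if (object@maxCsaMm2 <= 0) return("maxCsaMm2 must be > 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@nLesionLevels < 1L) return("nLesionLevels must be >= 1")
  if (object@nLevels < 1L) return("nLevels must be >= 1")
  if (!all(.SEQUENCE_LABELS %in% names(object@sequenceSnrProfile)))
    return("sequenceSnrProfile must name every sequence label")
  if (any(object@sequenceSnrProfile < 0))
    return("sequenceSnrProfile multipliers must be >= 0")
  TRUE
})

setMethod("show", "PhantomParams", function(object) {
  cat(sprintf(
    "PhantomParams: severity %.2f, peak CSA %.4g mm^2 at level %d (%d lesion levels of %d), noise SD %.3g, seed %d\n",
    object@severity, object@maxCsaMm2, object@maxLevelIndex,
    object@nLesionLevels, object@nLevels, object@noiseSd, object@seed))
})

#' Ground truth accompanying a generated phantom stack
#'
#' @slot lesionMasks,sdftMasks Per-slice [RoiMask-class] lists (stack order).
#' @slot boneMask Cortical-bone annulus mask (shared by all slices).
#' @slot trueCsaPerLevel Realised lesion area per slice in mm^2
#'   (pixel count times pixel area — exact for the painted masks).
#' @slot trueVolumeMm3 Realised lesion volume (sum of CSAs times
#'   centre-to-centre slice spacing).
#' @slot severity The severity the stack was generated with.
#'
#' @param lesionMasks,sdftMasks,boneMask,trueCsaPerLevel,trueVolumeMm3,severity
#'   See slots.
#' @return A `GroundTruth` object.
#' @export GroundTruth
#' @exportClass GroundTruth
GroundTruth <- setClass("GroundTruth",
  slots = c(lesionMasks = "list", sdftMasks = "list", boneMask = "RoiMask",
            trueCsaPerLevel = "numeric", trueVolumeMm3 = "numeric",
            severity = "numeric"))

setValidity("GroundTruth", function(object) {
  if (length(object@lesionMasks) != length(object@sdftMasks))
    return("lesionMasks and sdftMasks must have one entry per slice")
  if (length(object@trueCsaPerLevel) != length(object@lesionMasks))
    return("trueCsaPerLevel must have one entry per slice")
  for (i in seq_along(object@lesionMasks)) {
    les <- object@lesionMasks[[i]]@mask
    sd  <- object@sdftMasks[[i]]@mask
    if (any(les & !sd)) return("every lesion mask must lie within its SDFT mask")
  }
  TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d slice(s), %d lesion-bearing, true volume %.4g mm^3, severity %.2f\n",
    length(object@lesionMasks), sum(object@trueCsaPerLevel > 0),
    object@trueVolumeMm3, object@severity))
})

# ---------------------------------------------------------------------------
# AdaptiveSegParams
# ---------------------------------------------------------------------------

#' Parameters of the locally adaptive lesion segmentation
#'
#' A pixel inside the tendon ROI is labelled lesion when its intensity
#' exceeds the local mean over a `filterWidthPx`-wide square window
#' (restricted to tendon pixels) by more than an offset. In `"relative"`
#' offset mode the margin is `offset` times a robust (MAD-based) SD of the
#' tendon intensities; in `"absolute"` mode it is `offset` intensity units.
#' Connected components smaller than `minLesionPx` are removed and, by
#' default, only the largest surviving component is kept (single-lesion
#' design; set `keepAllComponents = TRUE` for multifocal lesions).
#'
#' @slot filterWidthPx Square window edge in pixels (default 30).
#' @slot offset Offset margin; interpretation depends on `offsetMode`.
#' @slot offsetMode `"relative"` or `"absolute"`.
#' @slot minLesionPx Minimum component size in pixels.
#' @slot connectivity 4 or 8.
#' @slot keepAllComponents Keep all surviving components instead of the
#'   largest one.
#'
#' @param filterWidthPx,offset,offsetMode,minLesionPx,connectivity See slots.
#' @param keepAllComponents See slots.
#' @return An `AdaptiveSegParams` object.
#' @export AdaptiveSegParams
#' @exportClass AdaptiveSegParams
AdaptiveSegParams <- setClass("AdaptiveSegParams",
  slots = c(filterWidthPx = "integer", offset = "numeric",
            offsetMode = "character", minLesionPx = "integer",
            connectivity = "integer", keepAllComponents = "logical"),
  prototype = prototype(filterWidthPx = 30L, offset = 3.5,
                        offsetMode = "relative", minLesionPx = 5L,
                        connectivity = 8L, keepAllComponents = FALSE))

setValidity("AdaptiveSegParams", function(object) {
  if (object@filterWidthPx < 3L) return("filterWidthPx must be >= 3")
  if (object@minLesionPx < 1L) return("minLesionPx must be >= 1")
  if (!object@connectivity %in% c(4L, 8L)) return("connectivity must be 4 or 8")
  if (!object@offsetMode %in% c("relative", "absolute"))
    return("offsetMode must be 'relative' or 'absolute'")
  if (!is.finite(object@offset) || object@offset < 0)
    return("offset must be finite and >= 0")
  TRUE
})

setMethod("show", "AdaptiveSegParams", function(object) {
  cat(sprintf(
    "AdaptiveSegParams: window %d px, offset %.3g (%s), min component %d px, %d-connectivity, %s\n",
    object@filterWidthPx, object@offset, object@offsetMode,
    object@minLesionPx, object@connectivity,
    if (object@keepAllComponents) "all components" else "largest component"))
})
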