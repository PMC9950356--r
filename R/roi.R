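#' @include AllClasses.R
NULL

.FORMULA_IDS <- c("SDNR_background", "SDNR_cortical",
                  "REL_background", "REL_cortical")

#' Supported SI-standardisation formula identifiers
#'
#' @return Character vector: two signal-difference-to-noise-ratio (SDNR)
#'   variants and two relative-SI variants, against background or cortical
#'   bone.
#' @export
formulaIds <- function() .FORMULA_IDS

# Rasterise a circle: pixels whose centres lie within radius (inclusive);
# guarantees at least the pixel containing the centre (floor rule).
.rasteriseCircle <- function(centreMm, radiusMm, geometry, role,
                             requireInBounds = TRUE) {
  fov <- fieldOfView(geometry)
  if (requireInBounds &&
      (any(centreMm - radiusMm < 0) || any(centreMm + radiusMm > fov)))
    stop("circle exceeds image bounds")
  mask <- pixelDist2Mm(centreMm, geometry) <= radiusMm^2
  if (!any(mask)) {
    s <- pixelSpacing(geometry)
    r0 <- min(max(ceiling(centreMm[1L] / s), 1L), matrixSize(geometry))
    c0 <- min(max(ceiling(centreMm[2L] / s), 1L), matrixSize(geometry))
    mask[r0, c0] <- TRUE
  }
  RoiMask(mask = mask, role = role)
}

#' Rasterise a circular ROI of a given area
#'
#' Builds the binary mask of a circle of area `areaMm2` (radius
#' `sqrt(area/pi)`) at a physical centre. A pixel belongs to the mask when
#' its centre lies within the radius (boundary-inclusive); for vanishing
#' areas the pixel containing the centre is always included.
#'
#' @param centreMm `(row, column)` centre in mm.
#' @param areaMm2 Target circle area in mm^2 (> 0).
#' @param geometry An [MriGeometry-class].
#' @param role ROI role for the returned mask.
#' @return A [RoiMask-class].
#' @examples
#' g <- MriGeometry()
#' roi <- makeCircleRoi(c(85, 85), areaMm2 = 50, g)
#' nPixels(roi) * pixelSpacing(g)^2   # close to 50 mm^2
#' @export
makeCircleRoi <- function(centreMm, areaMm2, geometry,
                          role = "background_lateral") {
  if (areaMm2 <= 0) stop("areaMm2 must be > 0")
  .rasteriseCircle(centreMm, sqrt(areaMm2 / pi), geometry, role)
}

#' Place the four 50 mm^2 reference ROIs
#'
#' One circle on the cortical bone and three background circles lateral,
#' medial and palmar to the limb at a clearance from the limb contour, as
#' used for SI standardisation. Lateral/medial are the column directions,
#' palmar is below the limb (increasing row). Background circles are
#' verified not to overlap the limb.
#'
#' @param boneCentreMm Cortex-annulus centre, `(row, col)` mm.
#' @param limbMask A [RoiMask-class] covering the limb cross-section.
#' @param geometry An [MriGeometry-class].
#' @param areaMm2 ROI area (default 50 mm^2).
#' @param clearanceMm Gap between the limb contour and each background
#'   circle edge.
#' @return Named list of [RoiMask-class]: `cortical_bone`,
#'   `background_lateral`, `background_medial`, `background_palmar`.
#' @export
placeReferenceRois <- function(boneCentreMm, limbMask, geometry,
                               areaMm2 = 50, clearanceMm = 3) {
  lm <- limbMask@mask
  if (!any(lm)) stop("limb mask is empty")
  radius <- sqrt(areaMm2 / pi)
  s <- pixelSpacing(geometry)
  rows <- ((row(lm) - 0.5) * s)[lm]
  cols <- ((col(lm) - 0.5) * s)[lm]
  centreRow <- mean(rows); centreCol <- mean(cols)
  off <- clearanceMm + radius
  centres <- list(
    background_lateral = c(centreRow, min(cols) - off),
    background_medial  = c(centreRow, max(cols) + off),
    background_palmar  = c(max(rows) + off, centreCol))
  rois <- lapply(names(centres), function(role) {
    roi <- tryCatch(.rasteriseCircle(centres[[role]], radius, geometry, role),
                    error = function(e)
                      stop("insufficient background clearance for ", role,
                           call. = FALSE))
    if (any(roi@mask & lm))
      stop("background ROI '", role, "' overlaps the limb; ",
           "insufficient clearance")
    roi
  })
  names(rois) <- names(centres)
  c(list(cortical_bone = .rasteriseCircle(boneCentreMm, radius, geometry,
                                          "cortical_bone")),
    rois)
}

#' Measure signal intensity within an ROI
#'
#' Mean and population SD (divisor `n`, the convention of image-viewer ROI
#' statistics) of the slice intensities under the mask.
#'
#' @param slice An [MriSlice-class].
#' @param roi A non-empty [RoiMask-class].
#' @return An [SiMeasurement-class].
#' @export
measureSi <- function(slice, roi) {
  if (!any(roi@mask)) stop("cannot measure SI over an empty ROI")
  if (!identical(dim(slice@pixels), dim(roi@mask)))
    stop("ROI grid does not match the slice grid")
  v <- slice@pixels[roi@mask]
  SiMeasurement(meanSi = mean(v), sdSi = popSd(v),
                nPixels = length(v), role = roi@role)
}

# Exact Euclidean distance (in pixels) from every mask pixel to the nearest
# complement-pixel centre, image border counted as complement. Returns the
# distance matrix (0 outside the mask).
.maskDistance <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(0L, nr + 2L, nc + 2L)
  padded[2L:(nr + 1L), 2L:(nc + 1L)] <- mask * 1L
  d <- EBImage::distmap(padded, metric = "euclidean")
  d <- as.matrix(d)[2L:(nr + 1L), 2L:(nc + 1L), drop = FALSE]
  d
}

# Deepest interior pixel: argmax of the distance transform, ties broken by
# smallest (row, col) lexicographically. Returns list(row, col, distPx).
.deepestPixel <- function(mask) {
  d <- .maskDistance(mask)
  dmax <- max(d)
  cand <- which(d >= dmax - 1e-7, arr.ind = TRUE)
  cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
  list(row = unname(cand[1L, 1L]), col = unname(cand[1L, 2L]),
       distPx = dmax)
}

#' Largest circular ROI inscribed in a lesion mask
#'
#' Centres the circle on the lesion-interior pixel maximising the exact
#' Euclidean distance to the mask complement (image border counted as
#' complement); ties are broken toward the smallest `(row, col)`. The
#' reported radius is that distance minus half a pixel, which guarantees
#' that the rasterised circle (pixel-centre rule) is a subset of the lesion
#' mask.
#'
#' @param lesion A non-empty [RoiMask-class].
#' @param geometry An [MriGeometry-class].
#' @return A [CircleRoi-class]; rasterise it with [circleToMask()].
#' @export
largestInscribedCircle <- function(lesion, geometry) {
  if (!any(lesion@mask)) stop("lesion mask is empty")
  s <- pixelSpacing(geometry)
  deep <- .deepestPixel(lesion@mask)
  radiusMm <- (deep$distPx - 0.5) * s
  CircleRoi(centreMm = pixelCentreMm(deep$row, deep$col, geometry),
            radiusMm = radiusMm, targetAreaMm2 = pi * radiusMm^2)
}

#' Rasterise a [CircleRoi-class] to a mask
#'
#' @param circle A [CircleRoi-class].
#' @param geometry An [MriGeometry-class].
#' @param role ROI role for the mask.
#' @param clipTo Optional [RoiMask-class] to intersect with (used for the
#'   central 1 mm^2 ROI, which is clipped to the lesion).
#' @return A [RoiMask-class].
#' @export
circleToMask <- function(circle, geometry, role = "lesion_circle_max",
                         clipTo = NULL) {
  roi <- .rasteriseCircle(circle@centreMm, circle@radiusMm, geometry, role,
                          requireInBounds = FALSE)
  if (!is.null(clipTo)) {
    clipped <- roi@mask & clipTo@mask
    if (!any(clipped)) clipped <- roi@mask   # degenerate: keep centre pixel
    roi <- RoiMask(mask = clipped, role = role)
  }
  roi
}

#' Small circular ROI at the lesion centre
#'
#' A circle of `areaMm2` (default 1 mm^2) centred on the lesion's deepest
#' interior point (distance-transform argmax — never in a concavity, unlike
#' the centroid). The rasterised mask is clipped to the lesion where it
#' overhangs.
#'
#' @param lesion A non-empty [RoiMask-class].
#' @param geometry An [MriGeometry-class].
#' @param areaMm2 Circle area in mm^2.
#' @return List: `circle` (a [CircleRoi-class]) and `mask` (a
#'   [RoiMask-class], role `lesion_circle_1mm2`).
#' @export
centralSmallRoi <- function(lesion, geometry, areaMm2 = 1) {
  if (!any(lesion@mask)) stop("lesion mask is empty")
  deep <- .deepestPixel(lesion@mask)
  circle <- CircleRoi(centreMm = pixelCentreMm(deep$row, deep$col, geometry),
                      radiusMm = sqrt(areaMm2 / pi),
                      targetAreaMm2 = areaMm2)
  list(circle = circle,
       mask = circleToMask(circle, geometry, role = "lesion_circle_1mm2",
                           clipTo = lesion))
}

#' Pool the three background reference ROIs
#'
#' Combines per-ROI measurements into the single background reference the
#' standardisation formulas use: mean SI is the unweighted mean of the ROI
#' means; the SD pools the within-ROI population variances weighted by pixel
#' count (between-ROI mean offsets are bias, not noise, and are excluded).
#'
#' @param measurements List of [SiMeasurement-class] (typically the three
#'   background ROIs).
#' @return An [SiMeasurement-class] with role `background_lateral` replaced
#'   by the first input's role.
#' @export
poolBackground <- function(measurements) {
  stopifnot(length(measurements) >= 1L)
  means <- vapply(measurements, meanSi, numeric(1))
  vars <- vapply(measurements, function(m) sdSi(m)^2, numeric(1))
  ns <- vapply(measurements, nPixels, numeric(1))
  SiMeasurement(meanSi = mean(means),
                sdSi = sqrt(sum(ns * vars) / sum(ns)),
                nPixels = as.integer(sum(ns)),
                role = measurements[[1L]]@role)
}

#' Standardise a lesion SI measurement
#'
#' The four standardisation formulas:
#' \describe{
#'   \item{`SDNR_background`}{`(SI_lesion - SI_SDFT) / SD_background`}
#'   \item{`SDNR_cortical`}{`(SI_lesion - SI_SDFT) / SD_cortical`}
#'   \item{`REL_background`}{`SI_lesion / SI_background`}
#'   \item{`REL_cortical`}{`SI_lesion / SI_cortical`}
#' }
#' SDNR is a signal-difference-to-noise ratio; REL is relative SI. All four
#' are invariant to rescaling the whole image by a positive constant.
#'
#' @param lesion,sdft [SiMeasurement-class] of the lesion and of healthy
#'   SDFT (`sdft` is only used by the SDNR formulas).
#' @param reference [SiMeasurement-class] of the reference region:
#'   background (pooled via [poolBackground()]) or cortical bone.
#' @param formulaId One of [formulaIds()].
#' @return The standardised SI value (numeric scalar) with attributes
#'   `formulaId`.
#' @examples
#' les <- SiMeasurement(meanSi = 240, sdSi = 5, nPixels = 10L,
#'                      role = "lesion_whole")
#' sd  <- SiMeasurement(meanSi = 90, sdSi = 5, nPixels = 10L, role = "sdft")
#' bg  <- SiMeasurement(meanSi = 30, sdSi = 12, nPixels = 10L,
#'                      role = "background_lateral")
#' standardiseSi(les, sd, bg, "SDNR_background")   # (240-90)/12 = 12.5
#' standardiseSi(les, sd, bg, "REL_background")    # 240/30 = 8
#' @export
standardiseSi <- function(lesion, sdft = NULL, reference, formulaId) {
  formulaId <- match.arg(formulaId, .FORMULA_IDS)
  value <- switch(formulaId,
    SDNR_background = ,
    SDNR_cortical = {
      if (reference@sdSi <= 0)
        stop("undefined result: reference SD is zero in ", formulaId)
      (lesion@meanSi - sdft@meanSi) / reference@sdSi
    },
    REL_background = ,
    REL_cortical = {
      if (reference@meanSi <= 0)
        stop("undefined result: reference mean SI is not positive in ",
             formulaId)
      lesion@meanSi / reference@meanSi
    })
  structure(value, formulaId = formulaId)
}
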