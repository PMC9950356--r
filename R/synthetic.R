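#' @include AllClasses.R
NULL

# Fixed phantom anatomy (mm, (row, col) physical coordinates within the FOV).
# Chosen to emulate a transverse equine metacarpal cross-section: a limb
# disc, the third metacarpal bone dorsally (top of image), and the SDFT
# palmarly (bottom of image).
.phantomAnatomy <- function(geometry) {
  mid <- fieldOfView(geometry) / 2
  list(
    limbCentre = c(mid, mid), limbRadius = 42,
    # cortex 8 mm thick so a 50 mm^2 circle fits inside the annulus
    boneCentre = c(mid - 15.5, mid), boneOuter = 14, boneInner = 6,
    sdftCentre = c(mid + 24.5, mid), sdftSemiAxes = c(5.5, 9),
    lesionAspect = 1.4)   # lesion col semi-axis = 1.4 x row semi-axis
}

# Unimodal per-level lesion CSA profile (parabolic, peak 1 at offset 0).
.lesionProfile <- function(offsets, nLesionLevels) {
  hw <- (nLesionLevels + 1) / 2
  pmax(0, 1 - (offsets / hw)^2)
}

# Lesion-bearing level offsets relative to the peak level.
.lesionOffsets <- function(nLesionLevels) {
  seq.int(-floor((nLesionLevels - 1) / 2), ceiling((nLesionLevels - 1) / 2))
}

.emptyMask <- function(geometry, role) {
  m <- matrixSize(geometry)
  RoiMask(mask = matrix(FALSE, m, m), role = role)
}

#' Generate a synthetic MRI lesion phantom stack with ground truth
#'
#' Paints, per slice: a Gaussian-noise background, a soft-tissue limb disc, a
#' dark cortical-bone annulus enclosing bright marrow, a low-signal SDFT
#' ellipse and — on lesion-bearing levels — a hyperintense elliptical lesion.
#' Lesion intensity has centre-weighted radial falloff,
#' `sdftMeanSi * (1 + contrastK * severity * w)` with
#' `w = 1 - 0.5 * rhat^2` (`rhat` = normalised elliptical radius), so the
#' lesion periphery keeps half the peak contrast. Per-level lesion area
#' follows a parabolic profile peaking at `maxLevelIndex` with peak area
#' `maxCsaMm2`; the recorded ground-truth CSA is the realised rasterised
#' area (pixel count times pixel area), which the painted masks match
#' exactly. Generation is fully reproducible from `params@seed` and leaves
#' the caller's RNG state untouched.
#'
#' @param params A [PhantomParams-class] object.
#' @param geometry An [MriGeometry-class]; the default is the low-field
#'   protocol (171 mm FOV, 256 matrix, 5 mm slices, 1 mm gap).
#' @param sequenceLabel One of [sequenceLabels()]; selects the noise
#'   multiplier from `params@sequenceSnrProfile`.
#' @param timePoint,subjectId Metadata attached to the stack.
#' @return A list with elements `stack` ([MriStack-class]) and `truth`
#'   ([GroundTruth-class]).
#' @examples
#' ph <- generateStack(PhantomParams(severity = 0.8, seed = 7L))
#' ph$truth
#' @export
generateStack <- function(params, geometry = MriGeometry(),
                          sequenceLabel = "T1w_GRE", timePoint = 1L,
                          subjectId = "phantom") {
  validObject(params)
  stopifnot(sequenceLabel %in% .SEQUENCE_LABELS)
  anat <- .phantomAnatomy(geometry)
  m <- matrixSize(geometry)
  spacing <- pixelSpacing(geometry)

  limbMask <- pixelDist2Mm(anat$limbCentre, geometry) <= anat$limbRadius^2
  boneD2 <- pixelDist2Mm(anat$boneCentre, geometry)
  marrowMask <- boneD2 <= anat$boneInner^2
  boneMask <- boneD2 <= anat$boneOuter^2 & !marrowMask
  sdftMask <- ellipseField(anat$sdftCentre, anat$sdftSemiAxes, geometry) <= 1

  lesionLevels <- integer(0)
  lesionAxes <- NULL
  if (params@severity > 0) {
    offsets <- .lesionOffsets(params@nLesionLevels)
    prof <- .lesionProfile(offsets, params@nLesionLevels)
    lesionLevels <- params@maxLevelIndex + offsets
    if (any(lesionLevels < 1L) || any(lesionLevels > params@nLevels))
      stop("lesion levels fall outside the stack (1..", params@nLevels, ")")
    csaTargets <- params@maxCsaMm2 * prof
    ar <- sqrt(csaTargets / (pi * anat$lesionAspect))
    ac <- ar * anat$lesionAspect
    if (max(ar) > 0.95 * anat$sdftSemiAxes[1L] ||
        max(ac) > 0.95 * anat$sdftSemiAxes[2L])
      stop("lesion larger than the SDFT region: reduce maxCsaMm2")
    lesionAxes <- cbind(ar, ac)
  }

  noiseMult <- params@sequenceSnrProfile[[sequenceLabel]]
  base <- matrix(params@backgroundMeanSi, m, m)
  base[limbMask] <- params@limbMeanSi
  base[marrowMask] <- params@marrowMeanSi
  base[boneMask] <- params@boneMeanSi
  base[sdftMask] <- params@sdftMeanSi

  withLocalSeed(params@seed, {
    slices <- vector("list", params@nLevels)
    lesionMasks <- vector("list", params@nLevels)
    sdftMasks <- vector("list", params@nLevels)
    trueCsa <- numeric(params@nLevels)
    for (lev in seq_len(params@nLevels)) {
      px <- base
      lmask <- matrix(FALSE, m, m)
      k <- match(lev, lesionLevels)
      if (!is.na(k) && lesionAxes[k, 1L] > 0) {
        rhat2 <- ellipseField(anat$sdftCentre, lesionAxes[k, ], geometry)
        lmask <- rhat2 <= 1
        w <- 1 - 0.5 * rhat2[lmask]
        px[lmask] <- params@sdftMeanSi *
          (1 + params@contrastK * params@severity * w)
      }
      px <- px + stats::rnorm(m * m, sd = params@noiseSd * noiseMult)
      px <- pmax(px, 0)
      slices[[lev]] <- MriSlice(pixels = px, levelIndex = lev,
                                sequenceLabel = sequenceLabel,
                                timePoint = as.integer(timePoint))
      lesionMasks[[lev]] <- RoiMask(mask = lmask, role = "lesion_whole")
      sdftMasks[[lev]] <- RoiMask(mask = sdftMask, role = "sdft")
      trueCsa[lev] <- sum(lmask) * spacing^2
    }
    stack <- MriStack(geometry = geometry, slices = slices,
                      subjectId = subjectId)
    truth <- GroundTruth(
      lesionMasks = lesionMasks, sdftMasks = sdftMasks,
      boneMask = RoiMask(mask = boneMask, role = "cortical_bone"),
      trueCsaPerLevel = trueCsa,
      trueVolumeMm3 = sum(trueCsa) * sliceSpacing(geometry),
      severity = params@severity)
    list(stack = stack, truth = truth)
  })
}

#' Phantom anatomy landmarks
#'
#' Physical landmarks of the painted phantom, needed to place reference
#' ROIs: bone-annulus centre and the limb mask.
#'
#' @param geometry An [MriGeometry-class].
#' @return List with `boneCentreMm` (bone centre), `corticalRoiCentreMm` (a
#'   point on the dorsal cortex, at the radial middle of the annulus, where
#'   the 50 mm^2 cortical reference circle fits entirely inside the cortex)
#'   and `limbMask` (a [RoiMask-class] covering the whole limb disc; the
#'   `sdft` role label is reused as a generic tissue tag).
#' @export
phantomLandmarks <- function(geometry = MriGeometry()) {
  anat <- .phantomAnatomy(geometry)
  limb <- pixelDist2Mm(anat$limbCentre, geometry) <= anat$limbRadius^2
  midRadial <- (anat$boneOuter + anat$boneInner) / 2
  list(boneCentreMm = anat$boneCentre,
       corticalRoiCentreMm = anat$boneCentre - c(midRadial, 0),
       limbMask = RoiMask(mask = limb, role = "sdft"))
}

#' Generate a longitudinal phantom time course
#'
#' The peak lesion CSA decays geometrically (`maxCsaMm2 * shrinkRate^(t-1)`)
#' and the peak level is offset by `levelDrift[t]`, emulating lesion
#' shrinkage and the proximal/distal migration of the maximum-lesion level
#' over a follow-up series. Each time point gets its own RNG stream
#' (`seed + t - 1`).
#'
#' @param base A [PhantomParams-class] for time point 1.
#' @param nTimepoints Number of examinations (>= 2).
#' @param shrinkRate Geometric per-time-point CSA decay factor (> 0; 1 keeps
#'   the lesion constant).
#' @param levelDrift Integer vector, one peak-level offset per time point
#'   (relative to `base@maxLevelIndex`).
#' @param geometry,sequenceLabel,subjectId As for [generateStack()].
#' @return List of `nTimepoints` `list(stack, truth)` pairs.
#' @export
generateTimecourse <- function(base, nTimepoints, shrinkRate = 0.85,
                               levelDrift = integer(nTimepoints),
                               geometry = MriGeometry(),
                               sequenceLabel = "T1w_GRE",
                               subjectId = "phantom") {
  stopifnot(nTimepoints >= 2L, shrinkRate > 0,
            length(levelDrift) == nTimepoints)
  lapply(seq_len(nTimepoints), function(t) {
    p <- base
    p@maxCsaMm2 <- base@maxCsaMm2 * shrinkRate^(t - 1)
    p@maxLevelIndex <- base@maxLevelIndex + as.integer(levelDrift[t])
    p@seed <- base@seed + t - 1L
    generateStack(p, geometry = geometry, sequenceLabel = sequenceLabel,
                  timePoint = t, subjectId = subjectId)
  })
}

#' Generate a trichrome-like histology image with known blue fraction
#'
#' Produces an RGB image of a tissue disc on a white slide margin, in which
#' an exactly controlled share of tissue pixels is blue-dominant (collagen
#' analogue) and the rest red-dominant (muscle/cytoplasm analogue), with
#' bounded per-channel jitter that never crosses the class margins. The
#' realised blue share (`round(blueFraction * nTissue) / nTissue`) is
#' returned as ground truth and is within 0.5 percentage points of the
#' request for the default image size.
#'
#' @param blueFraction Requested blue share of tissue pixels, in `[0, 1]`.
#' @param size Image edge in pixels (square).
#' @param seed Integer seed.
#' @return List: `image` (`size x size x 3` array in `[0, 1]`),
#'   `blueFraction` (realised), `nTissuePixels`, `nBluePixels`, and the
#'   logical ground-truth masks `tissueMask` and `blueMask`.
#' @export
generateHistology <- function(blueFraction, size = 220L, seed = 1L) {
  if (blueFraction < 0 || blueFraction > 1)
    stop("blueFraction must be in [0, 1]")
  size <- as.integer(size)
  centre <- (size + 1) / 2
  d2 <- outer((seq_len(size) - centre)^2, (seq_len(size) - centre)^2, `+`)
  tissue <- d2 <= (0.41 * size)^2
  nTissue <- sum(tissue)
  nBlue <- as.integer(round(blueFraction * nTissue))
  withLocalSeed(seed, {
    tidx <- which(tissue)
    bidx <- sample(tidx, nBlue)
    blue <- matrix(FALSE, size, size)
    blue[bidx] <- TRUE
    red <- tissue & !blue
    jit <- function(n) stats::runif(n, -0.05, 0.05)
    img <- array(1, dim = c(size, size, 3L))   # white slide background
    nB <- sum(blue); nR <- sum(red)
    # blue-dominant stain: B - R >= 0.37 even at extreme jitter
    img[, , 1L][blue] <- 0.25 + jit(nB)
    img[, , 2L][blue] <- 0.35 + jit(nB)
    img[, , 3L][blue] <- 0.72 + jit(nB)
    # red-dominant stain: R - B >= 0.36
    img[, , 1L][red] <- 0.78 + jit(nR)
    img[, , 2L][red] <- 0.30 + jit(nR)
    img[, , 3L][red] <- 0.22 + jit(nR)
    list(image = img, blueFraction = nBlue / nTissue,
         nTissuePixels = nTissue, nBluePixels = nBlue,
         tissueMask = tissue, blueMask = blue)
  })
}
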