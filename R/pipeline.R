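#' @include AllClasses.R
NULL

#' Default configuration for the synthetic analysis pipeline
#'
#' One plain list drives every study; identical configs give bit-identical
#' result tables (all randomness is derived from `seed`). Cohort sizes are
#' desk-scale defaults chosen so the full pipeline runs in minutes.
#'
#' @param seed Master integer seed.
#' @param outputDir Optional directory; when set, [runAllStudies()] writes
#'   every result table there as CSV.
#' @return A named list (the pipeline config).
#' @export
defaultPipelineConfig <- function(seed = 1L, outputDir = NULL) {
  list(
    seed = as.integer(seed),
    outputDir = outputDir,
    geometry = MriGeometry(),
    segParams = AdaptiveSegParams(),
    standardisation = list(nSamples = 23L, severityRange = c(0.1, 0.9),
                           coupling = "positive", csaRange = c(15, 50)),
    roiComparison = list(nSlices = 40L, severityRange = c(0.3, 0.9),
                         csaRange = c(10, 60)),
    csa = list(nSubjects = 6L, nTimepoints = 10L, shrinkRate = 0.85,
               maxDriftPerStep = 1L, severityRange = c(0.5, 0.9),
               csaRange = c(30, 60)),
    automation = list(nTimepoints = 5L, baseSeverity = 0.9,
                      severityDecay = 0.85, baseCsaMm2 = 40, csaDecay = 0.7))
}

# Single-level phantom sample: one lesion-bearing slice plus its masks and
# the standard reference measurements.
.singleSlicePhantom <- function(severity, maxCsa, seed, geometry,
                                sequenceLabel = "T1w_GRE") {
  p <- PhantomParams(severity = severity, maxCsaMm2 = maxCsa,
                     maxLevelIndex = 1L, nLesionLevels = 1L, nLevels = 1L,
                     seed = as.integer(seed))
  ph <- generateStack(p, geometry = geometry, sequenceLabel = sequenceLabel)
  list(slice = ph$stack[[1L]], lesion = ph$truth@lesionMasks[[1L]],
       sdft = ph$truth@sdftMasks[[1L]], truth = ph$truth)
}

# Reference ROI masks are geometry-fixed for the phantom; compute once.
.referenceMasks <- function(geometry) {
  lm <- phantomLandmarks(geometry)
  placeReferenceRois(lm$corticalRoiCentreMm, lm$limbMask, geometry)
}

# Reference measurements on one slice: pooled background + cortical bone.
.referenceMeasurements <- function(slice, refMasks) {
  bg <- poolBackground(list(
    measureSi(slice, refMasks$background_lateral),
    measureSi(slice, refMasks$background_medial),
    measureSi(slice, refMasks$background_palmar)))
  list(background = bg, cortical = measureSi(slice, refMasks$cortical_bone))
}

# Healthy-tendon SI: SDFT mask with the lesion excluded.
.healthySdftSi <- function(slice, sdft, lesion) {
  healthy <- sdft@mask & !lesion@mask
  measureSi(slice, RoiMask(mask = healthy, role = "sdft"))
}

#' SI-standardisation study: four formulas against histology
#'
#' Generates a cohort of lesion-bearing slices with paired trichrome-like
#' histology (the generator couples the histological blue fraction to
#' lesion severity; `coupling = "positive"` sets blue fraction = severity,
#' `"negative"` its complement, `"none"` decouples them), measures the
#' whole-lesion SI, computes all four standardised-SI formulas and
#' correlates each with the blue-pixel percentage by Spearman rank
#' correlation.
#'
#' @param config A [defaultPipelineConfig()]-style list.
#' @return List: `samples` (per-sample table) and `correlations` (one row
#'   per formula: `r`, `p`, `n`).
#' @export
runStandardisationStudy <- function(config = defaultPipelineConfig()) {
  cs <- config$standardisation
  g <- config$geometry
  n <- cs$nSamples
  if (n < 3L) stop("standardisation cohort needs at least 3 samples")
  refMasks <- .referenceMasks(g)
  severities <- seq(cs$severityRange[1L], cs$severityRange[2L], length.out = n)
  draws <- withLocalSeed(config$seed, {
    list(csa = stats::runif(n, cs$csaRange[1L], cs$csaRange[2L]),
         blueNoise = stats::runif(n))
  })
  blueFractions <- switch(cs$coupling,
    positive = severities,
    negative = 1 - severities,
    none = draws$blueNoise,
    stop("coupling must be 'positive', 'negative' or 'none'"))
  rows <- lapply(seq_len(n), function(i) {
    sp <- .singleSlicePhantom(severities[i], draws$csa[i],
                              config$seed + 100L + i, g)
    refs <- .referenceMeasurements(sp$slice, refMasks)
    lesionSi <- measureSi(sp$slice, sp$lesion)
    sdftSi <- .healthySdftSi(sp$slice, sp$sdft, sp$lesion)
    hist <- generateHistology(blueFractions[i], seed = config$seed + 500L + i)
    hq <- quantifyHistology(hist$image)
    data.frame(
      sample = i, severity = severities[i], bluePercent = hq$bluePercent,
      SDNR_background = as.numeric(
        standardiseSi(lesionSi, sdftSi, refs$background, "SDNR_background")),
      SDNR_cortical = as.numeric(
        standardiseSi(lesionSi, sdftSi, refs$cortical, "SDNR_cortical")),
      REL_background = as.numeric(
        standardiseSi(lesionSi, sdftSi, refs$background, "REL_background")),
      REL_cortical = as.numeric(
        standardiseSi(lesionSi, sdftSi, refs$cortical, "REL_cortical")))
  })
  samples <- do.call(rbind, rows)
  correlations <- do.call(rbind, lapply(formulaIds(), function(f) {
    sp <- spearmanRank(samples[[f]], samples$bluePercent)
    data.frame(formulaId = f, r = sp$r, p = sp$p, n = sp$n)
  }))
  list(samples = samples, correlations = correlations)
}

#' ROI-type comparison: circular lesion ROIs against the whole-lesion ROI
#'
#' Per slice, the lesion SI (standardised with the relative-SI background
#' formula) is measured on the whole-lesion mask, the largest inscribed
#' circle and the central 1 mm^2 circle; each circle type is compared with
#' the whole-lesion value by Spearman correlation and ratio-scale
#' Bland-Altman limits.
#'
#' @param config A [defaultPipelineConfig()]-style list.
#' @return List: `samples` and `stats` (one row per circle ROI type).
#' @export
runRoiComparison <- function(config = defaultPipelineConfig()) {
  cr <- config$roiComparison
  g <- config$geometry
  n <- cr$nSlices
  refMasks <- .referenceMasks(g)
  severities <- seq(cr$severityRange[1L], cr$severityRange[2L], length.out = n)
  csas <- withLocalSeed(config$seed + 1L,
                        stats::runif(n, cr$csaRange[1L], cr$csaRange[2L]))
  rows <- lapply(seq_len(n), function(i) {
    sp <- .singleSlicePhantom(severities[i], csas[i],
                              config$seed + 1000L + i, g)
    refs <- .referenceMeasurements(sp$slice, refMasks)
    circleMax <- circleToMask(largestInscribedCircle(sp$lesion, g), g,
                              role = "lesion_circle_max")
    small <- centralSmallRoi(sp$lesion, g)$mask
    # the relative-SI formula does not use the SDFT term
    rel <- function(mask) {
      as.numeric(standardiseSi(measureSi(sp$slice, mask), NULL,
                               refs$background, "REL_background"))
    }
    data.frame(sample = i, severity = severities[i],
               csaMm2 = roiAreaMm2(sp$lesion, g),
               relWhole = rel(sp$lesion), relCircleMax = rel(circleMax),
               relCircle1mm2 = rel(small))
  })
  samples <- do.call(rbind, rows)
  oneStat <- function(colName, label) {
    sp <- spearmanRank(samples[[colName]], samples$relWhole)
    ba <- blandAltmanLog(samples[[colName]], samples$relWhole)
    data.frame(roiType = label, r = sp$r, p = sp$p, n = sp$n,
               meanRatio = ba$meanRatio, loaLower = ba$loaLower,
               loaUpper = ba$loaUpper)
  }
  list(samples = samples,
       stats = rbind(oneStat("relCircleMax", "lesion_circle_max"),
                     oneStat("relCircle1mm2", "lesion_circle_1mm2")))
}

#' CSA representativeness study: CSA fixed / CSA maximum vs lesion volume
#'
#' Generates longitudinal phantom cohorts (geometric CSA shrinkage with a
#' drifting maximum-lesion level), summarises each series with
#' [lesionSeriesSummary()] and correlates both CSA readings with the lesion
#' volume across all subject-time-point pairs.
#'
#' @param config A [defaultPipelineConfig()]-style list.
#' @return List: `samples` (per subject and time point), `correlations`
#'   (CSA fixed and CSA maximum vs volume).
#' @export
runCsaStudy <- function(config = defaultPipelineConfig()) {
  cc <- config$csa
  g <- config$geometry
  nS <- cc$nSubjects; nT <- cc$nTimepoints
  draws <- withLocalSeed(config$seed + 2L, {
    list(sev = stats::runif(nS, cc$severityRange[1L], cc$severityRange[2L]),
         csa = stats::runif(nS, cc$csaRange[1L], cc$csaRange[2L]),
         steps = matrix(sample(c(-cc$maxDriftPerStep, 0L, cc$maxDriftPerStep),
                               nS * (nT - 1L), replace = TRUE),
                        nS, nT - 1L))
  })
  rows <- lapply(seq_len(nS), function(s) {
    drift <- c(0L, cumsum(draws$steps[s, ]))
    drift <- pmin(pmax(drift, -3L), 3L)   # keep the lesion inside the stack
    base <- PhantomParams(severity = draws$sev[s], maxCsaMm2 = draws$csa[s],
                          maxLevelIndex = 6L, nLesionLevels = 5L,
                          nLevels = 12L,
                          seed = config$seed + 3000L + s * 20L)
    tc <- generateTimecourse(base, nT, shrinkRate = cc$shrinkRate,
                             levelDrift = drift, geometry = g,
                             subjectId = paste0("subject", s))
    recs <- lapply(tc, function(ph)
      data.frame(levelIndex = seq_along(ph$truth@trueCsaPerLevel),
                 csaMm2 = ph$truth@trueCsaPerLevel))
    cbind(subject = s, lesionSeriesSummary(recs, g))
  })
  samples <- do.call(rbind, rows)
  corFixed <- spearmanRank(samples$csaFixedMm2, samples$volumeMm3)
  corMax <- spearmanRank(samples$csaMaxMm2, samples$volumeMm3)
  list(samples = samples,
       correlations = data.frame(
         csaVariant = c("csa_fixed", "csa_maximum"),
         r = c(corFixed$r, corMax$r), p = c(corFixed$p, corMax$p),
         n = c(corFixed$n, corMax$n)))
}

#' Automation study: manual (ground-truth) vs automated lesion measurement
#'
#' For each MRI sequence noise profile, generates a healing time course of
#' phantom stacks — lesion severity and peak CSA decay over the examinations,
#' so late stacks carry small, faint lesions near the detection limit, as in
#' a follow-up series — runs the locally adaptive segmentation on every
#' slice (lesion-bearing and lesion-free), and compares automated with
#' ground-truth measurements: percent agreement of binary lesion detection,
#' plus Spearman and Bland-Altman statistics for CSA and SI over slices
#' where both methods see the lesion. A pooled `overall` row aggregates the
#' four sequences.
#'
#' @param config A [defaultPipelineConfig()]-style list.
#' @return List: `perSlice` and `stats` (one row per sequence plus
#'   `overall`).
#' @export
runAutomationStudy <- function(config = defaultPipelineConfig()) {
  ca <- config$automation
  g <- config$geometry
  perSlice <- do.call(rbind, lapply(sequenceLabels(), function(sq) {
    do.call(rbind, lapply(seq_len(ca$nTimepoints), function(k) {
      p <- PhantomParams(severity = ca$baseSeverity * ca$severityDecay^(k - 1),
                         maxCsaMm2 = ca$baseCsaMm2 * ca$csaDecay^(k - 1),
                         maxLevelIndex = 6L, nLesionLevels = 5L,
                         nLevels = 12L,
                         seed = config$seed + 7000L +
                           match(sq, sequenceLabels()) * 100L + k)
      ph <- generateStack(p, geometry = g, sequenceLabel = sq,
                          subjectId = paste0("auto", k))
      do.call(rbind, lapply(seq_len(length(ph$stack)), function(i) {
        sl <- ph$stack[[i]]
        les <- ph$truth@lesionMasks[[i]]
        auto <- automatedMeasurement(sl, ph$truth@sdftMasks[[i]],
                                     config$segParams, g)
        manualDetected <- any(les@mask)
        manual <- if (manualDetected) {
          si <- measureSi(sl, les)
          c(csa = roiAreaMm2(les, g), si = meanSi(si))
        } else c(csa = 0, si = NA_real_)
        data.frame(sequenceLabel = sq, stack = k, levelIndex = levelIndex(sl),
                   manualDetected = manualDetected,
                   manualCsaMm2 = manual[["csa"]], manualSi = manual[["si"]],
                   autoDetected = auto$detected, autoCsaMm2 = auto$csaMm2,
                   autoSi = auto$meanSi)
      }))
    }))
  }))
  stats <- do.call(rbind, lapply(c(sequenceLabels(), "overall"), function(sq) {
    d <- if (sq == "overall") perSlice else
      perSlice[perSlice$sequenceLabel == sq, ]
    agree <- percentAgreement(d$autoDetected, d$manualDetected)
    both <- d[d$autoDetected & d$manualDetected, ]
    csaCor <- spearmanRank(both$autoCsaMm2, both$manualCsaMm2)
    siCor <- spearmanRank(both$autoSi, both$manualSi)
    csaBa <- blandAltmanLog(both$autoCsaMm2, both$manualCsaMm2)
    siBa <- blandAltmanLog(both$autoSi, both$manualSi)
    data.frame(sequenceLabel = sq, nSlices = nrow(d),
               detectionAgreementPct = agree, nCompared = nrow(both),
               csaR = csaCor$r, csaMeanRatio = csaBa$meanRatio,
               csaLoaLower = csaBa$loaLower, csaLoaUpper = csaBa$loaUpper,
               siR = siCor$r, siMeanRatio = siBa$meanRatio,
               siLoaLower = siBa$loaLower, siLoaUpper = siBa$loaUpper)
  }))
  list(perSlice = perSlice, stats = stats)
}

#' Run every study and optionally write the result tables
#'
#' Executes the four analyses in sequence on the synthetic cohorts defined
#' by `config`. With `config$outputDir` set, each table is written as CSV;
#' rerunning with an identical config reproduces the files bit-identically.
#'
#' @param config A [defaultPipelineConfig()]-style list.
#' @return Named list with the four study results.
#' @export
runAllStudies <- function(config = defaultPipelineConfig()) {
  res <- list(standardisation = runStandardisationStudy(config),
              roiComparison = runRoiComparison(config),
              csa = runCsaStudy(config),
              automation = runAutomationStudy(config))
  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    tables <- list(
      standardisation_samples = res$standardisation$samples,
      standardisation_correlations = res$standardisation$correlations,
      roi_comparison_samples = res$roiComparison$samples,
      roi_comparison_stats = res$roiComparison$stats,
      csa_summary = res$csa$samples,
      csa_correlations = res$csa$correlations,
      automation_per_slice = res$automation$perSlice,
      automation_stats = res$automation$stats)
    for (nm in names(tables))
      saveResults(tables[[nm]],
                  file.path(config$outputDir, paste0(nm, ".csv")))
  }
  res
}
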