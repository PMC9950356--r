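test_that("a uniform tendon yields an empty lesion mask", {
  px <- matrix(50, 40, 40)
  sdft <- matrix(FALSE, 40, 40); sdft[10:30, 10:30] <- TRUE
  sl <- MriSlice(pixels = px, levelIndex = 1L)
  roi <- RoiMask(mask = sdft, role = "sdft")
  for (mode in c("relative", "absolute")) {
    out <- localAdaptiveSegment(sl, roi,
                                AdaptiveSegParams(filterWidthPx = 15L,
                                                  offset = 1,
                                                  offsetMode = mode))
    expect_false(any(maskMatrix(out)))
  }
  expect_error(localAdaptiveSegment(
    sl, RoiMask(mask = matrix(FALSE, 40, 40), role = "sdft")), "empty")
})

test_that("hand-computed toy grid: only the bright pixel exceeds its local mean", {
  px <- matrix(10, 3, 3); px[2, 2] <- 100
  sl <- MriSlice(pixels = px, levelIndex = 1L)
  roi <- RoiMask(mask = matrix(TRUE, 3, 3), role = "sdft")
  # 3x3 window: at the centre it covers the full grid, local mean
  # (100 + 8*10)/9 = 20, and 100 > 20 + 5; at the border pixels the
  # clipped windows give means 25-32.5, far above 10 + 5
  pars <- AdaptiveSegParams(filterWidthPx = 3L, offset = 5,
                            offsetMode = "absolute", minLesionPx = 1L)
  out <- localAdaptiveSegment(sl, roi, pars)
  expected <- matrix(FALSE, 3, 3); expected[2, 2] <- TRUE
  expect_identical(maskMatrix(out), expected)
})

test_that("the automated mask is always a subset of the SDFT mask", {
  for (sq in c("T1w_GRE", "STIR")) {
    ph <- generateStack(PhantomParams(severity = 0.8, seed = 51L),
                        sequenceLabel = sq)
    for (i in c(1L, 6L, 9L)) {
      sdft <- ph$truth@sdftMasks[[i]]
      out <- localAdaptiveSegment(ph$stack[[i]], sdft)
      expect_false(any(maskMatrix(out) & !maskMatrix(sdft)))
      expect_identical(roiRole(out), "lesion_auto")
    }
  }
})

test_that("relative offset mode is shift- and scale-invariant, absolute only shift", {
  ph <- phantomSlice(severity = 0.8, seed = 52L)
  base <- localAdaptiveSegment(ph$slice, ph$sdft)
  shifted <- MriSlice(pixels = pixels(ph$slice) + 37, levelIndex = 1L)
  scaled <- MriSlice(pixels = pixels(ph$slice) * 4.5, levelIndex = 1L)
  expect_identical(maskMatrix(localAdaptiveSegment(shifted, ph$sdft)),
                   maskMatrix(base))
  expect_identical(maskMatrix(localAdaptiveSegment(scaled, ph$sdft)),
                   maskMatrix(base))
  absPars <- AdaptiveSegParams(offset = 25, offsetMode = "absolute")
  absBase <- localAdaptiveSegment(ph$slice, ph$sdft, absPars)
  expect_identical(
    maskMatrix(localAdaptiveSegment(shifted, ph$sdft, absPars)),
    maskMatrix(absBase))
  # under rescaling a fixed absolute offset changes the labelling
  expect_false(identical(
    maskMatrix(localAdaptiveSegment(scaled, ph$sdft, absPars)),
    maskMatrix(absBase)))
})

test_that("small components are removed and the largest one kept", {
  px <- matrix(10, 30, 30)
  px[5:6, 5:6] <- 100          # 4-pixel component
  px[15:18, 15:20] <- 100      # 24-pixel component
  sl <- MriSlice(pixels = px, levelIndex = 1L)
  roi <- RoiMask(mask = matrix(TRUE, 30, 30), role = "sdft")
  pars <- AdaptiveSegParams(filterWidthPx = 29L, offset = 20,
                            offsetMode = "absolute", minLesionPx = 5L)
  out <- localAdaptiveSegment(sl, roi, pars)
  expect_identical(sum(maskMatrix(out)), 24L)
  expect_true(all(maskMatrix(out)[15:18, 15:20]))
  # with a lower floor both components survive in keep-all mode
  parsAll <- AdaptiveSegParams(filterWidthPx = 29L, offset = 20,
                               offsetMode = "absolute", minLesionPx = 3L,
                               keepAllComponents = TRUE)
  expect_identical(sum(maskMatrix(localAdaptiveSegment(sl, roi, parsAll))),
                   28L)
})

test_that("connectivity 4 splits diagonal chains that connectivity 8 joins", {
  px <- matrix(0, 12, 12)
  diagIdx <- cbind(3:7, 3:7)
  px[diagIdx] <- 100
  sl <- MriSlice(pixels = px, levelIndex = 1L)
  roi <- RoiMask(mask = matrix(TRUE, 12, 12), role = "sdft")
  base <- list(filterWidthPx = 11L, offset = 10, offsetMode = "absolute")
  out8 <- localAdaptiveSegment(sl, roi, AdaptiveSegParams(
    filterWidthPx = 11L, offset = 10, offsetMode = "absolute",
    minLesionPx = 5L, connectivity = 8L))
  expect_identical(sum(maskMatrix(out8)), 5L)   # one 5-pixel component
  out4 <- localAdaptiveSegment(sl, roi, AdaptiveSegParams(
    filterWidthPx = 11L, offset = 10, offsetMode = "absolute",
    minLesionPx = 5L, connectivity = 4L))
  expect_false(any(maskMatrix(out4)))           # five 1-pixel components
})

test_that("detection respects the minimum-pixel boundary inclusively", {
  pars <- AdaptiveSegParams(minLesionPx = 5L)
  m <- matrix(FALSE, 10, 10)
  expect_false(detectLesion(RoiMask(mask = m, role = "lesion_auto"), pars))
  m[1, 1:5] <- TRUE
  expect_true(detectLesion(RoiMask(mask = m, role = "lesion_auto"), pars))
  m[1, 5] <- FALSE
  expect_false(detectLesion(RoiMask(mask = m, role = "lesion_auto"), pars))
})

test_that("severity-zero stacks are never called lesioned", {
  ph <- generateStack(PhantomParams(severity = 0, seed = 53L))
  for (i in seq_len(length(ph$stack))) {
    rec <- automatedMeasurement(ph$stack[[i]], ph$truth@sdftMasks[[i]])
    expect_false(rec$detected)
    expect_identical(rec$csaMm2, 0)
    expect_true(is.na(rec$meanSi))
  }
})

test_that("automated measurement recovers strong lesions at base noise", {
  ph <- phantomSlice(severity = 0.8, maxCsa = 30, seed = 54L)
  g <- MriGeometry()
  auto <- localAdaptiveSegment(ph$slice, ph$sdft)
  expect_gte(diceCoefficient(auto, ph$lesion), 0.8)
  rec <- automatedMeasurement(ph$slice, ph$sdft, geometry = g)
  expect_true(rec$detected)
  truthSi <- meanSi(measureSi(ph$slice, ph$lesion))
  expect_lt(abs(rec$meanSi / truthSi - 1), 0.05)
  # the adaptive threshold trims the faint periphery, never adds tissue
  expect_lte(rec$csaMm2, roiAreaMm2(ph$lesion, g))
})
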