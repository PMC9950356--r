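test_that("severity zero paints no lesion anywhere", {
  ph <- generateStack(PhantomParams(severity = 0, seed = 3L))
  expect_true(all(ph$truth@trueCsaPerLevel == 0))
  expect_identical(ph$truth@trueVolumeMm3, 0)
  for (mk in ph$truth@lesionMasks) expect_false(any(maskMatrix(mk)))
})

test_that("lesion-bearing levels and the peak level follow the parameters", {
  p <- PhantomParams(severity = 0.8, maxCsaMm2 = 30, maxLevelIndex = 6L,
                     nLesionLevels = 5L, seed = 2L)
  ph <- generateStack(p)
  csa <- ph$truth@trueCsaPerLevel
  expect_identical(sum(csa > 0), 5L)
  expect_identical(which.max(csa), 6L)
  expect_identical(which(csa > 0), 4:8)
  # unimodal around the peak
  expect_true(all(diff(csa[4:6]) > 0) && all(diff(csa[6:8]) < 0))
})

test_that("ground-truth CSA equals the rasterised mask area exactly", {
  g <- MriGeometry()
  ph <- generateStack(PhantomParams(severity = 0.6, seed = 9L), g)
  for (i in seq_along(ph$truth@lesionMasks))
    expect_identical(roiAreaMm2(ph$truth@lesionMasks[[i]], g),
                     ph$truth@trueCsaPerLevel[i])
  expect_identical(ph$truth@trueVolumeMm3,
                   sum(ph$truth@trueCsaPerLevel) * sliceSpacing(g))
})

test_that("lesion masks are nested inside the SDFT masks", {
  ph <- generateStack(PhantomParams(severity = 0.9, maxCsaMm2 = 60, seed = 4L))
  for (i in seq_along(ph$truth@lesionMasks)) {
    les <- maskMatrix(ph$truth@lesionMasks[[i]])
    sdf <- maskMatrix(ph$truth@sdftMasks[[i]])
    expect_false(any(les & !sdf))
  }
})

test_that("generation is bit-reproducible from the seed and leaves the RNG alone", {
  p <- PhantomParams(severity = 0.7, seed = 21L)
  a <- generateStack(p)
  set.seed(123); before <- stats::runif(3)
  set.seed(123); b <- generateStack(p); after <- stats::runif(3)
  expect_identical(before, after)   # no global RNG perturbation
  for (i in seq_len(length(a$stack)))
    expect_identical(pixels(a$stack[[i]]), pixels(b$stack[[i]]))
  c <- generateStack(PhantomParams(severity = 0.7, seed = 22L))
  expect_false(identical(pixels(a$stack[[1L]]), pixels(c$stack[[1L]])))
})

test_that("lesion contrast increases strictly with severity at fixed seed", {
  contrasts <- sapply(c(0.2, 0.5, 0.8), function(sv) {
    ph <- generateStack(PhantomParams(severity = sv, maxCsaMm2 = 30,
                                      seed = 5L))
    sl <- ph$stack[[6L]]
    les <- ph$truth@lesionMasks[[6L]]
    sdf <- maskMatrix(ph$truth@sdftMasks[[6L]]) & !maskMatrix(les)
    mean(pixels(sl)[maskMatrix(les)]) - mean(pixels(sl)[sdf])
  })
  expect_true(all(diff(contrasts) > 0))
})

test_that("oversized lesions and out-of-stack levels are parameter errors", {
  expect_error(generateStack(PhantomParams(severity = 0.8, maxCsaMm2 = 200)),
               "larger than the SDFT")
  expect_error(
    generateStack(PhantomParams(severity = 0.8, maxLevelIndex = 1L,
                                nLesionLevels = 5L)),
    "outside the stack")
})

test_that("time courses shrink geometrically and drift the peak level", {
  base <- PhantomParams(severity = 0.8, maxCsaMm2 = 40, maxLevelIndex = 6L,
                        nLesionLevels = 5L, seed = 30L)
  # shrinkRate 1, zero drift: identical true volumes at every time point
  tc1 <- generateTimecourse(base, 4L, shrinkRate = 1)
  vols <- sapply(tc1, function(x) x$truth@trueVolumeMm3)
  expect_true(all(vols == vols[1L]))

  drift <- c(0L, 0L, 1L, 1L, -1L, 0L, 0L, 2L, 0L, 0L)
  tc <- generateTimecourse(base, 10L, shrinkRate = 0.8, levelDrift = drift)
  peaks <- sapply(tc, function(x) which.max(x$truth@trueCsaPerLevel))
  expect_identical(peaks, 6L + drift)
  # ground-truth level shifts in mm: drift times the 6 mm slice spacing
  g <- MriGeometry()
  expect_identical(levelShift(peaks, rep(6L, 10L), g), -drift * 6)
  # realised peak CSA tracks the geometric target within rasterisation error
  peakCsa <- sapply(tc, function(x) max(x$truth@trueCsaPerLevel))
  expect_equal(peakCsa[10L], 40 * 0.8^9, tolerance = 0.2)
  expect_true(all(diff(peakCsa) < 0))
  expect_error(generateTimecourse(base, 3L, levelDrift = c(0L, 9L, 0L)),
               "outside the stack")
})

test_that("histology generator realises the requested blue fraction", {
  h1 <- generateHistology(1, seed = 2L)
  expect_identical(h1$blueFraction, 1)
  expect_identical(sum(h1$blueMask), h1$nTissuePixels)
  h0 <- generateHistology(0, seed = 2L)
  expect_identical(h0$blueFraction, 0)
  h <- generateHistology(0.37, seed = 8L)
  expect_identical(h$blueFraction, h$nBluePixels / h$nTissuePixels)
  expect_identical(sum(h$blueMask), h$nBluePixels)
  expect_lt(abs(h$blueFraction - 0.37), 0.005)
  # deterministic from the seed
  expect_identical(generateHistology(0.37, seed = 8L)$image, h$image)
  expect_error(generateHistology(1.2), "\\[0, 1\\]")
})
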