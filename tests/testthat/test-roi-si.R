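test_that("circle ROIs rasterise to the expected pixel counts", {
  g <- MriGeometry()
  s <- pixelSpacing(g)
  # 50 mm^2 at the protocol spacing: ~112 pixels, within 10%
  roi <- makeCircleRoi(c(85.5, 85.5), 50, g)
  expect_lt(abs(nPixels(roi) - 50 / s^2) / (50 / s^2), 0.10)
  # 1 mm^2: at least the centre pixel is always included
  roi1 <- makeCircleRoi(c(85.5, 85.5), 1, g)
  expect_gte(nPixels(roi1), 1L)
  # vanishing area: exactly the pixel containing the centre
  roi0 <- makeCircleRoi(c(85.4, 85.4), 1e-9, g)
  expect_identical(nPixels(roi0), 1L)
  expect_true(maskMatrix(roi0)[ceiling(85.4 / s), ceiling(85.4 / s)])
  expect_error(makeCircleRoi(c(1, 85), 50, g), "bounds")
  expect_error(makeCircleRoi(c(85, 85), -1, g), "> 0")
})

test_that("rasterised area error shrinks as the target area grows", {
  g <- MriGeometry()
  s <- pixelSpacing(g)
  withr::local_seed(31)
  meanErr <- sapply(c(1, 5, 10, 50), function(area) {
    mean(sapply(1:100, function(i) {
      ctr <- c(85, 85) + stats::runif(2, 0, s)
      abs(nPixels(makeCircleRoi(ctr, area, g)) * s^2 - area) / area
    }))
  })
  expect_true(all(diff(meanErr) < 0))
  expect_true(all(meanErr[2:4] < 0.10))   # 5, 10 and 50 mm^2
})

test_that("reference ROIs avoid the limb and sample the intended tissues", {
  g <- MriGeometry()
  lm <- phantomLandmarks(g)
  refs <- placeReferenceRois(lm$corticalRoiCentreMm, lm$limbMask, g)
  expect_named(refs, c("cortical_bone", "background_lateral",
                       "background_medial", "background_palmar"))
  for (role in names(refs)[-1L])
    expect_false(any(maskMatrix(refs[[role]]) & maskMatrix(lm$limbMask)))
  # cortical circle lies entirely on the painted cortex annulus
  ph <- generateStack(PhantomParams(severity = 0, seed = 14L), g)
  expect_false(any(maskMatrix(refs$cortical_bone) &
                     !maskMatrix(ph$truth@boneMask)))
  # background ROI mean is a sound estimate of the noise-floor mean
  for (role in c("background_lateral", "background_medial",
                 "background_palmar")) {
    m <- measureSi(ph$stack[[1L]], refs[[role]])
    expect_lt(abs(meanSi(m) - 20), 3 * 4 / sqrt(nPixels(m)))
  }
  # a limb filling the whole frame leaves nowhere to put background ROIs
  full <- RoiMask(mask = matrix(TRUE, matrixSize(g), matrixSize(g)),
                  role = "sdft")
  expect_error(placeReferenceRois(lm$corticalRoiCentreMm, full, g))
})

test_that("SI measurement returns mean and population SD over the mask", {
  g <- MriGeometry(fieldOfViewMm = 8, matrixSize = 8L)
  mkSlice <- function(px) MriSlice(pixels = px, levelIndex = 1L)
  uniform <- mkSlice(matrix(7, 8, 8))
  all8 <- RoiMask(mask = matrix(TRUE, 8, 8), role = "lesion_whole")
  m <- measureSi(uniform, all8)
  expect_identical(meanSi(m), 7)
  expect_identical(sdSi(m), 0)
  two <- matrix(FALSE, 8, 8); two[1, 1:2] <- TRUE
  px <- matrix(0, 8, 8); px[1, 1] <- 1; px[1, 2] <- 3
  m2 <- measureSi(mkSlice(px), RoiMask(mask = two, role = "lesion_whole"))
  expect_identical(meanSi(m2), 2)
  expect_identical(sdSi(m2), 1)   # population SD, divisor n
  expect_identical(nPixels(m2), 2L)
  empty <- RoiMask(mask = matrix(FALSE, 8, 8), role = "lesion_whole")
  expect_error(measureSi(uniform, empty), "empty ROI")
})

test_that("background SD over a 50 mm^2 ROI sits in the chi-square band", {
  g <- MriGeometry()
  ph <- generateStack(PhantomParams(severity = 0, seed = 17L), g)
  lm <- phantomLandmarks(g)
  refs <- placeReferenceRois(lm$corticalRoiCentreMm, lm$limbMask, g)
  m <- measureSi(ph$stack[[1L]], refs$background_medial)
  expect_gt(sdSi(m), 3.2)   # n ~ 112 draws from N(20, 4)
  expect_lt(sdSi(m), 4.8)
})

test_that("the inscribed circle matches exhaustive search on canonical shapes", {
  g <- MriGeometry(fieldOfViewMm = 15, matrixSize = 15L)
  # solid 9x9 square: centre pixel of the square, radius from brute force
  sq <- matrix(FALSE, 15, 15); sq[4:12, 4:12] <- TRUE
  lesion <- RoiMask(mask = sq, role = "lesion_whole")
  circ <- largestInscribedCircle(lesion, g)
  ref <- bruteInscribedCircle(sq)
  expect_identical(ref$row, 8L); expect_identical(ref$col, 8L)
  expect_equal(centreMm(circ), pixelCentreMm(8, 8, g))
  expect_equal(radiusMm(circ), ref$radiusPx * pixelSpacing(g),
               tolerance = 1e-9)
  # single pixel: that pixel, radius half a pixel
  one <- matrix(FALSE, 15, 15); one[6, 10] <- TRUE
  c1 <- largestInscribedCircle(RoiMask(mask = one, role = "lesion_whole"), g)
  expect_equal(radiusMm(c1), 0.5 * pixelSpacing(g))
  m1 <- circleToMask(c1, g)
  expect_identical(maskMatrix(m1), one)
  # L-shaped mask: circle sits in the thick arm, wholly inside the mask
  L <- matrix(FALSE, 15, 15); L[2:14, 2:5] <- TRUE; L[10:14, 2:12] <- TRUE
  cl <- largestInscribedCircle(RoiMask(mask = L, role = "lesion_whole"), g)
  refL <- bruteInscribedCircle(L)
  expect_equal(centreMm(cl), pixelCentreMm(refL$row, refL$col, g))
  expect_equal(radiusMm(cl), refL$radiusPx * pixelSpacing(g),
               tolerance = 1e-9)
  mL <- circleToMask(cl, g)
  expect_false(any(maskMatrix(mL) & !L))
  expect_error(largestInscribedCircle(
    RoiMask(mask = matrix(FALSE, 15, 15), role = "lesion_whole"), g), "empty")
})

test_that("inscribed circles equal the brute-force oracle on random masks", {
  g <- MriGeometry(fieldOfViewMm = 32, matrixSize = 32L)
  withr::local_seed(44)
  for (i in 1:40) {
    mask <- randomBlobMask()
    circ <- largestInscribedCircle(RoiMask(mask = mask,
                                           role = "lesion_whole"), g)
    ref <- bruteInscribedCircle(mask)
    expect_equal(centreMm(circ), pixelCentreMm(ref$row, ref$col, g))
    expect_equal(radiusMm(circ), ref$radiusPx * pixelSpacing(g),
                 tolerance = 1e-9)
    expect_false(any(maskMatrix(circleToMask(circ, g)) & !mask))
  }
})

test_that("the central small ROI sits at the deepest interior point", {
  g <- MriGeometry(fieldOfViewMm = 21, matrixSize = 21L)
  # disc lesion: centre equals the disc centre pixel
  disc <- outer((1:21 - 11)^2, (1:21 - 11)^2, `+`) <= 36
  res <- centralSmallRoi(RoiMask(mask = disc, role = "lesion_whole"), g)
  expect_equal(centreMm(res$circle), pixelCentreMm(11, 11, g))
  expect_false(any(maskMatrix(res$mask) & !disc))
  # C-shaped lesion: the deepest point stays inside the lesion even though
  # the centroid falls in the central hole
  d2c <- outer((1:21 - 11)^2, (1:21 - 11)^2, `+`)
  cres <- d2c <= 49 & d2c > 16 &
    !(col(matrix(0, 21, 21)) > 11 & abs(row(matrix(0, 21, 21)) - 11) < 3)
  resC <- centralSmallRoi(RoiMask(mask = cres, role = "lesion_whole"), g)
  ctrPx <- centreMm(resC$circle) / pixelSpacing(g) + 0.5
  expect_true(cres[round(ctrPx[1L]), round(ctrPx[2L])])
  centroid <- round(c(mean(row(cres)[cres]), mean(col(cres)[cres])))
  expect_false(cres[centroid[1L], centroid[2L]])
  # 1-pixel lesion: the ROI is that pixel
  one <- matrix(FALSE, 21, 21); one[5, 17] <- TRUE
  resO <- centralSmallRoi(RoiMask(mask = one, role = "lesion_whole"), g)
  expect_identical(maskMatrix(resO$mask), one)
})

test_that("the four standardisation formulas are exact arithmetic", {
  mk <- function(mean, sd = 1, role = "lesion_whole")
    SiMeasurement(meanSi = mean, sdSi = sd, nPixels = 10L, role = role)
  les <- mk(240); sdft <- mk(90)
  bg <- mk(30, sd = 12, role = "background_lateral")
  expect_identical(as.numeric(standardiseSi(les, sdft, bg, "SDNR_background")),
                   12.5)
  expect_identical(as.numeric(standardiseSi(les, sdft, bg, "REL_background")),
                   8)
  cort <- mk(12, sd = 3, role = "cortical_bone")
  expect_identical(as.numeric(standardiseSi(les, sdft, cort, "SDNR_cortical")),
                   (240 - 90) / 3)
  expect_identical(as.numeric(standardiseSi(les, sdft, cort, "REL_cortical")),
                   20)
  # zero numerator and identity quotient
  expect_identical(as.numeric(standardiseSi(mk(90), sdft, bg,
                                            "SDNR_background")), 0)
  expect_identical(as.numeric(standardiseSi(mk(30), sdft, bg,
                                            "REL_background")), 1)
  # undefined denominators name the formula
  expect_error(standardiseSi(les, sdft, mk(30, sd = 0), "SDNR_background"),
               "SDNR_background")
  expect_error(standardiseSi(les, sdft, mk(0), "REL_cortical"),
               "REL_cortical")
})

test_that("standardised SI is invariant to global intensity rescaling", {
  mk <- function(mean, sd, role) SiMeasurement(meanSi = mean, sdSi = sd,
                                               nPixels = 5L, role = role)
  for (cc in c(0.25, 3, 17)) {
    a <- sapply(formulaIds(), function(f)
      standardiseSi(mk(140, 6, "lesion_whole"), mk(60, 4, "sdft"),
                    mk(25, 5, "background_lateral"), f))
    b <- sapply(formulaIds(), function(f)
      standardiseSi(mk(140 * cc, 6 * cc, "lesion_whole"),
                    mk(60 * cc, 4 * cc, "sdft"),
                    mk(25 * cc, 5 * cc, "background_lateral"), f))
    expect_equal(unname(a), unname(b), tolerance = 1e-12)
  }
})

test_that("background pooling averages means and pools variances by pixels", {
  mk <- function(mean, sd, n) SiMeasurement(meanSi = mean, sdSi = sd,
                                            nPixels = n,
                                            role = "background_lateral")
  pooled <- poolBackground(list(mk(10, 2, 100L), mk(14, 4, 100L),
                                mk(12, 3, 200L)))
  expect_identical(meanSi(pooled), 12)
  expect_equal(sdSi(pooled),
               sqrt((100 * 4 + 100 * 16 + 200 * 9) / 400))
  expect_identical(nPixels(pooled), 400L)
  same <- poolBackground(list(mk(8, 3, 50L), mk(8, 3, 50L)))
  expect_identical(meanSi(same), 8)
  expect_identical(sdSi(same), 3)
})
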