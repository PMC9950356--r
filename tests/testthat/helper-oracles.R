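# Independent oracles for the acceptance and property tests. These never
# call the code paths they check.

# --- maximum inscribed circle -----------------------------------------------

# Exhaustive search: for every mask pixel, the largest containment radius is
# the minimum Euclidean distance to any complement-pixel centre (the image
# border ring counts as complement); the best centre maximises it, ties
# broken toward the smallest (row, col). Distances computed by explicit
# pairwise arithmetic.
bruteInscribedCircle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask, arr.ind = TRUE)
  comp <- which(!mask, arr.ind = TRUE)
  ring <- rbind(cbind(0L, 0L:(nc + 1L)), cbind(nr + 1L, 0L:(nc + 1L)),
                cbind(1L:nr, 0L), cbind(1L:nr, nc + 1L))
  comp <- rbind(comp, ring)
  d2 <- outer(fg[, 1L], comp[, 1L], `-`)^2 + outer(fg[, 2L], comp[, 2L], `-`)^2
  dmin <- sqrt(apply(d2, 1L, min))
  dmax <- max(dmin)
  cand <- fg[dmin >= dmax - 1e-7, , drop = FALSE]
  cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
  list(row = unname(cand[1L, 1L]), col = unname(cand[1L, 2L]),
       distPx = dmax, radiusPx = dmax - 0.5)
}

# Radius-stepping containment search (0.05 px steps): at a given centre,
# grow the radius while every pixel whose centre lies within it belongs to
# the mask (pixels beyond the border fail containment).
containmentRadiusAt <- function(mask, r0, c0, step = 0.05) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- 2L + as.integer(ceiling(max(nr, nc)))
  big <- matrix(FALSE, nr + 2L * pad, nc + 2L * pad)
  big[pad + seq_len(nr), pad + seq_len(nc)] <- mask
  d <- sqrt(outer((seq_len(nrow(big)) - (r0 + pad))^2,
                  (seq_len(ncol(big)) - (c0 + pad))^2, `+`))
  r <- 0
  repeat {
    rn <- r + step
    if (any(d <= rn & !big)) break
    r <- rn
  }
  r
}

# Full exhaustive centre x stepped-radius search over a (small) mask.
containmentInscribed <- function(mask, step = 0.05) {
  fg <- which(mask, arr.ind = TRUE)
  radii <- apply(fg, 1L, function(p)
    containmentRadiusAt(mask, p[1L], p[2L], step))
  best <- max(radii)
  cand <- fg[radii >= best - 1e-9, , drop = FALSE]
  cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
  list(row = unname(cand[1L, 1L]), col = unname(cand[1L, 2L]),
       radiusPx = best)
}

# Random blob masks: union of a few discs plus salt pixels.
randomBlobMask <- function(nr = 32L, nc = 32L) {
  m <- matrix(FALSE, nr, nc)
  for (k in seq_len(sample(1:3, 1L))) {
    ctr <- c(runif(1, 4, nr - 3), runif(1, 4, nc - 3))
    rad <- runif(1, 1.2, 8)
    m <- m | (outer((seq_len(nr) - ctr[1L])^2,
                    (seq_len(nc) - ctr[2L])^2, `+`) <= rad^2)
  }
  m[sample(nr * nc, 4L)] <- TRUE
  if (!any(m)) m[sample(nr * nc, 1L)] <- TRUE
  m
}

# --- Spearman ---------------------------------------------------------------

# Rank-then-Pearson via base R (the brute-force reference route).
spearmanOracleR <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

# All permutations of 1..n by prefix-selection recursion (structurally
# different from the package's insertion construction).
oraclePermutations <- function(n, prefix = integer(0),
                               remaining = seq_len(n)) {
  if (length(remaining) == 0L) return(matrix(prefix, 1L))
  do.call(rbind, lapply(seq_along(remaining), function(i)
    oraclePermutations(n, c(prefix, remaining[i]), remaining[-i])))
}

# Exact two-sided permutation p-value by full enumeration.
spearmanPermPOracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  robs <- stats::cor(rx, ry)
  perms <- oraclePermutations(length(y))
  rAll <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
  mean(abs(rAll) >= abs(robs) - 1e-12)
}

# --- misc -------------------------------------------------------------------

# Quick single-slice lesion phantom for ROI tests.
phantomSlice <- function(severity = 0.8, maxCsa = 30, seed = 11L,
                         sequenceLabel = "T1w_GRE") {
  p <- PhantomParams(severity = severity, maxCsaMm2 = maxCsa,
                     maxLevelIndex = 1L, nLesionLevels = 1L, nLevels = 1L,
                     seed = as.integer(seed))
  ph <- generateStack(p, sequenceLabel = sequenceLabel)
  list(slice = ph$stack[[1L]], lesion = ph$truth@lesionMasks[[1L]],
       sdft = ph$truth@sdftMasks[[1L]], truth = ph$truth)
}

# Criterion-style segmentation cohort: six severity-0.8 stacks whose peak
# CSAs span down to the detection limit; returns per-lesion-slice results.
segmentationCohort <- function(sequenceLabel, seed0 = 40L,
                               maxCsas = c(5, 6, 7, 8, 9, 10),
                               params = AdaptiveSegParams()) {
  g <- MriGeometry()
  out <- list()
  for (k in seq_along(maxCsas)) {
    p <- PhantomParams(severity = 0.8, maxCsaMm2 = maxCsas[k],
                       maxLevelIndex = 6L, nLesionLevels = 5L, nLevels = 12L,
                       seed = seed0 + k)
    ph <- generateStack(p, g, sequenceLabel = sequenceLabel)
    for (i in which(ph$truth@trueCsaPerLevel > 0)) {
      sl <- ph$stack[[i]]
      les <- ph$truth@lesionMasks[[i]]
      auto <- localAdaptiveSegment(sl, ph$truth@sdftMasks[[i]], params)
      det <- detectLesion(auto, params)
      out[[length(out) + 1L]] <- data.frame(
        detected = det,
        dice = diceCoefficient(auto, les),
        autoSi = if (det) meanSi(measureSi(sl, auto)) else NA_real_,
        truthSi = meanSi(measureSi(sl, les)),
        autoCsa = roiAreaMm2(auto, g),
        truthCsa = roiAreaMm2(les, g))
    }
  }
  do.call(rbind, out)
}
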