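#' @include AllClasses.R
NULL

# Run expr with a private RNG stream: seeds deterministically, then restores
# the caller's .Random.seed so generation never perturbs global state.
withLocalSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

popSd <- function(v) {
  m <- mean(v)
  sqrt(mean((v - m)^2))
}

# Sliding-window box sum via a zero-padded summed-area table; window is the
# w x w square centred on each pixel, clipped at the borders. Exact in double
# precision for the magnitudes used here.
boxSum <- function(m, w) {
  nr <- nrow(m); nc <- ncol(m)
  h <- (w - 1L) %/% 2L    # for even w the window extends one pixel less above/left
  hi <- w - 1L - h
  cs <- apply(m, 2L, cumsum)
  if (nr == 1L) cs <- matrix(cs, 1L, nc)
  cs2 <- t(apply(cs, 1L, cumsum))
  if (nc == 1L) cs2 <- matrix(cs2, nr, 1L)
  sat <- matrix(0, nr + 1L, nc + 1L)
  sat[2:(nr + 1L), 2:(nc + 1L)] <- cs2
  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + hi, nr)
  c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + hi, nc)
  out <- sat[r2 + 1L, c2 + 1L, drop = FALSE] -
         sat[r1,      c2 + 1L, drop = FALSE] -
         sat[r2 + 1L, c1,      drop = FALSE] +
         sat[r1,      c1,      drop = FALSE]
  out
}

# Label connected components of a logical matrix; returns an integer matrix
# (0 = background). Flood fill with an explicit stack; connectivity 4 or 8.
connectedComponents <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  }
  nextLabel <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (labels[start] != 0L) next
    nextLabel <- nextLabel + 1L
    stack <- start
    labels[start] <- nextLabel
    while (length(stack) > 0L) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r0 <- ((cur - 1L) %% nr) + 1L
      c0 <- ((cur - 1L) %/% nr) + 1L
      rr <- r0 + dr; cc <- c0 + dc
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      nb <- (cc[ok] - 1L) * nr + rr[ok]
      nb <- nb[mask[nb] & labels[nb] == 0L]
      if (length(nb) > 0L) {
        labels[nb] <- nextLabel
        stack <- c(stack, nb)
      }
    }
  }
  labels
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A & B| / (|A| + |B|)`; returns `NA` when both masks are empty.
#'
#' @param a,b Logical matrices of equal dimensions, or [RoiMask-class]
#'   objects.
#' @return Dice coefficient in `[0, 1]`.
#' @export
diceCoefficient <- function(a, b) {
  if (is(a, "RoiMask")) a <- a@mask
  if (is(b, "RoiMask")) b <- b@mask
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0L) return(NA_real_)
  2 * sum(a & b) / denom
}
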