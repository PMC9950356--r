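#' @include AllClasses.R
NULL

# Mid-ranks computed from scratch (average rank across tied values).
midRanks <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  i <- 1L
  pos <- seq_along(x)
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[ord[j + 1L]] == x[ord[i]]) j <- j + 1L
    r[ord[i:j]] <- mean(pos[i:j])
    i <- j + 1L
  }
  r
}

# Pearson correlation written out explicitly (population moments).
.pearson <- function(a, b) {
  am <- mean(a); bm <- mean(b)
  num <- sum((a - am) * (b - bm))
  den <- sqrt(sum((a - am)^2) * sum((b - bm)^2))
  num / den
}

# All permutations of 1..n as an (n! x n) matrix, built by inserting n into
# every position of each permutation of 1..(n-1).
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  prev <- allPermutations(n - 1L)
  out <- matrix(0L, nrow(prev) * n, n)
  row <- 0L
  for (pos in seq_len(n)) {
    idx <- row + seq_len(nrow(prev))
    if (pos == 1L) out[idx, ] <- cbind(n, prev)
    else if (pos == n) out[idx, ] <- cbind(prev, n)
    else out[idx, ] <- cbind(prev[, seq_len(pos - 1L), drop = FALSE], n,
                             prev[, pos:(n - 1L), drop = FALSE])
    row <- row + nrow(prev)
  }
  out
}

#' Spearman rank correlation with tie-aware r and exact small-sample p
#'
#' The correlation is the Pearson correlation of mid-ranks (correct under
#' ties, unlike the classical `1 - 6*sum(d^2)/...` shortcut). The two-sided
#' p-value is computed by full enumeration of the permutation distribution
#' for `n <= exactLimit` (counting permutations with `|r|` at least the
#' observed `|r|`) and by the t-approximation
#' `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom otherwise.
#'
#' @param x,y Paired numeric vectors, `n >= 3`, no constant vector.
#' @param exactLimit Largest `n` for exact permutation enumeration
#'   (default 10; `10!` permutations is the practical ceiling).
#' @return List: `r`, `p`, `n`, `method` (`"exact"` or `"t-approximation"`).
#' @examples
#' spearmanRank(1:5, c(2, 1, 4, 3, 5))
#' @export
spearmanRank <- function(x, y, exactLimit = 10L) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  n <- length(x)
  if (n < 3L) stop("spearmanRank() needs at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("undefined correlation: constant vector")
  rx <- midRanks(x); ry <- midRanks(y)
  r <- .pearson(rx, ry)
  if (n <= exactLimit) {
    perms <- allPermutations(n)
    rxc <- rx - mean(rx); ryc <- ry - mean(ry)
    den <- sqrt(sum(rxc^2) * sum(ryc^2))
    # r for every permutation of y against fixed x, via one matrix product
    sums <- as.vector(matrix(ryc[perms], nrow(perms), n) %*% rxc)
    rAll <- sums / den
    p <- mean(abs(rAll) >= abs(r) - 1e-12)
    method <- "exact"
  } else {
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- min(max(p, .Machine$double.xmin), 1)
    method <- "t-approximation"
  }
  list(r = r, p = p, n = n, method = method)
}

#' Bland-Altman limits of agreement on the ratio scale
#'
#' Method differences are taken on the natural-log scale,
#' `d_i = ln(a_i) - ln(b_i)`, and backtransformed: the mean ratio is
#' `exp(mean(d))` and the limits of agreement
#' `exp(mean(d) +/- multiplier * SD(d))` (sample SD, divisor `n - 1`;
#' classical multiplier 1.96). The returned per-pair ratios and geometric
#' means are plot-ready (ratio against mean, log-scaled y).
#'
#' Swapping the two methods inverts the mean ratio and swaps/inverts the
#' limits exactly.
#'
#' @param a,b Paired positive measurements from the two methods, `n >= 2`.
#' @param multiplier Half-width of the limits in SD units.
#' @return List: `meanRatio`, `loaLower`, `loaUpper`, `n`, `ratios`,
#'   `means`.
#' @examples
#' blandAltmanLog(c(1, 2, 4), c(1, 1, 1))
#' @export
blandAltmanLog <- function(a, b, multiplier = 1.96) {
  if (length(a) != length(b)) stop("a and b must be paired (equal length)")
  if (length(a) < 2L) stop("blandAltmanLog() needs at least 2 pairs")
  bad <- which(!(a > 0) | !(b > 0))
  if (length(bad) > 0L)
    stop("non-positive value(s) at pair(s) ",
         paste(bad, collapse = ", "), "; the log transform requires > 0")
  d <- log(a) - log(b)
  md <- mean(d)
  sdd <- if (length(d) > 1L) stats::sd(d) else 0
  list(meanRatio = exp(md),
       loaLower = exp(md - multiplier * sdd),
       loaUpper = exp(md + multiplier * sdd),
       n = length(a),
       ratios = a / b,
       means = exp((log(a) + log(b)) / 2))
}

#' Percent agreement between two binary detection series
#'
#' @param detectA,detectB Equal-length logical vectors, `n >= 1`.
#' @return Percentage of positions where the two calls agree, in
#'   `[0, 100]`.
#' @export
percentAgreement <- function(detectA, detectB) {
  if (length(detectA) != length(detectB))
    stop("detection vectors must have equal length")
  if (length(detectA) < 1L) stop("need at least one paired detection")
  100 * mean(detectA == detectB)
}

#' Bland-Altman ratio plot
#'
#' Per-pair ratios against geometric means on a log-scaled y axis, with the
#' mean ratio (solid) and limits of agreement (dashed).
#'
#' @param ba Result of [blandAltmanLog()].
#' @param ... Passed to [graphics::plot()].
#' @return `ba`, invisibly.
#' @export
blandAltmanPlot <- function(ba, ...) {
  graphics::plot(ba$means, ba$ratios, log = "y",
                 xlab = "Geometric mean of methods",
                 ylab = "Ratio (method A / method B)", ...)
  graphics::abline(h = ba$meanRatio, lty = 1)
  graphics::abline(h = c(ba$loaLower, ba$loaUpper), lty = 2)
  invisible(ba)
}
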