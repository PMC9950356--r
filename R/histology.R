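#' @include AllClasses.R
NULL

#' Extract red and blue channels from a trichrome RGB image
#'
#' @param image `h x w x 3` (or more channels) numeric array; channel order
#'   R, G, B.
#' @return List with numeric matrices `red` and `blue`.
#' @export
extractChannels <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3L] < 3L)
    stop("extractChannels() requires a 3-channel RGB image")
  list(red = image[, , 1L], blue = image[, , 3L])
}

#' Segment trichrome stain classes from red/blue channel maps
#'
#' Each pixel is assigned to exactly one class. Background: both channels at
#' or above `whiteThreshold` (unstained slide) or both at or below
#' `blackThreshold`. Otherwise blue when `blue - red >= margin`, red when
#' `red - blue >= margin`; remaining ambiguous pixels go to the larger
#' channel, with exact ties assigned to red. Thresholds are fractions of
#' `channelMax`.
#'
#' @param red,blue Numeric matrices of equal dimensions.
#' @param whiteThreshold,blackThreshold,margin Classification thresholds as
#'   fractions of `channelMax`.
#' @param channelMax Full-scale channel value (1 for normalised images, 255
#'   for 8-bit).
#' @return List of disjoint logical masks `blue`, `red`, `background` that
#'   partition the image.
#' @export
segmentStain <- function(red, blue, whiteThreshold = 0.9,
                         blackThreshold = 0.02, margin = 0.05,
                         channelMax = 1) {
  if (!identical(dim(red), dim(blue)))
    stop("red and blue maps must have identical dimensions")
  wt <- whiteThreshold * channelMax
  bt <- blackThreshold * channelMax
  mg <- margin * channelMax
  background <- (red >= wt & blue >= wt) | (red <= bt & blue <= bt)
  blueMask <- !background & (blue - red >= mg)
  redMask <- !background & (red - blue >= mg)
  ambiguous <- !background & !blueMask & !redMask
  blueMask <- blueMask | (ambiguous & blue > red)   # exact ties fall to red
  redMask <- redMask | (ambiguous & blue <= red)
  list(blue = blueMask, red = redMask, background = background)
}

#' Blue-pixel percentage of a segmented trichrome image
#'
#' The blue-stained share, the study's histological lesion-severity readout.
#' With `denominator = "tissue"` (default) the percentage is taken over
#' stained tissue pixels (blue plus red), so slide background area does not
#' dilute the score; `"all"` uses every image pixel.
#'
#' @param blueMask,redMask Disjoint logical masks from [segmentStain()].
#' @param denominator `"tissue"` or `"all"`.
#' @return List: `bluePercent` in `[0, 100]`, `nTissuePixels`,
#'   `nBluePixels`, `nRedPixels`.
#' @export
bluePixelPercentage <- function(blueMask, redMask,
                                denominator = c("tissue", "all")) {
  denominator <- match.arg(denominator)
  if (!identical(dim(blueMask), dim(redMask)))
    stop("masks must have identical dimensions")
  if (any(blueMask & redMask)) stop("blue and red masks must be disjoint")
  nBlue <- sum(blueMask); nRed <- sum(redMask)
  nTissue <- nBlue + nRed
  denom <- if (denominator == "tissue") nTissue else length(blueMask)
  if (denom == 0L)
    stop("blue-pixel percentage undefined: no tissue pixels segmented")
  list(bluePercent = 100 * nBlue / denom,
       nTissuePixels = nTissue, nBluePixels = nBlue, nRedPixels = nRed)
}

#' Quantify a trichrome image end to end
#'
#' Convenience wrapper: [extractChannels()], [segmentStain()],
#' [bluePixelPercentage()].
#'
#' @param image RGB array.
#' @param ... Passed to [segmentStain()] and [bluePixelPercentage()]
#'   (threshold arguments and `denominator`).
#' @inheritParams bluePixelPercentage
#' @return As [bluePixelPercentage()].
#' @export
quantifyHistology <- function(image, denominator = c("tissue", "all"), ...) {
  ch <- extractChannels(image)
  seg <- segmentStain(ch$red, ch$blue, ...)
  bluePixelPercentage(seg$blue, seg$red, denominator = denominator)
}
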