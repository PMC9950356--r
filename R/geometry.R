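#' @include AllClasses.R
NULL

# Physical mm coordinates of pixel centres along one axis (1-based rows/cols).
axisCentresMm <- function(geometry) {
  (seq_len(matrixSize(geometry)) - 0.5) * pixelSpacing(geometry)
}

# Squared physical distance of every pixel centre from a (row, col) mm point,
# as a matrixSize x matrixSize matrix.
pixelDist2Mm <- function(centre, geometry) {
  ax <- axisCentresMm(geometry)
  outer((ax - centre[1L])^2, (ax - centre[2L])^2, `+`)
}

# Elliptical "normalised radius squared" field: ((r-cr)/ar)^2 + ((c-cc)/ac)^2.
ellipseField <- function(centre, semiAxesMm, geometry) {
  ax <- axisCentresMm(geometry)
  outer(((ax - centre[1L]) / semiAxesMm[1L])^2,
        ((ax - centre[2L]) / semiAxesMm[2L])^2, `+`)
}

#' Physical centre of a pixel
#'
#' @param row,col 1-based pixel indices.
#' @param geometry An [MriGeometry-class].
#' @return `(row, column)` position in mm of the pixel centre.
#' @export
pixelCentreMm <- function(row, col, geometry) {
  c((row - 0.5) * pixelSpacing(geometry), (col - 0.5) * pixelSpacing(geometry))
}

#' Average of triplicate measurements
#'
#' Manual ROI measurements are taken in triplicate and summarised by their
#' arithmetic mean before further analysis.
#'
#' @param values Numeric vector of exactly 3 finite values.
#' @return Their arithmetic mean.
#' @examples
#' averageTriplicate(c(0.5, 0.7, 0.6))
#' @export
averageTriplicate <- function(values) {
  if (length(values) != 3L)
    stop("averageTriplicate() expects exactly 3 values, got ", length(values))
  if (any(!is.finite(values)))
    stop("averageTriplicate() requires finite values")
  mean(values)
}
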