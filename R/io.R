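#' @include AllClasses.R
NULL

readGrayImage <- function(path, bitDepth = 8L) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' for ", path))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] >= 3L &&
        (max(abs(img[, , 1L] - img[, , 2L])) > 0 ||
         max(abs(img[, , 1L] - img[, , 3L])) > 0))
      stop("expected a grayscale image, got colour: ", path)
    img <- img[, , 1L]
  }
  # readPNG/readTIFF normalise to [0, 1]; map back onto the container's
  # integer scale, no further rescaling.
  img * (2^bitDepth - 1)
}

#' Load an MRI slice stack from a directory of grayscale images
#'
#' Reads every PNG/TIFF in `path` as one transverse slice. The slice level is
#' parsed from the last integer in each filename (e.g. `slice_07.png` is
#' level 7), so shuffled directory listings still produce a correctly
#' ordered, proximal-to-distal stack.
#'
#' @param path Directory containing the slice images.
#' @param geometry An [MriGeometry-class]; image dimensions must match its
#'   matrix size.
#' @param sequenceLabel,timePoint,subjectId Metadata attached to the stack.
#' @param bitDepth Declared container bit depth (8 or 16); intensities are
#'   mapped onto `[0, 2^bitDepth - 1]`.
#' @return An [MriStack-class].
#' @export
loadStack <- function(path, geometry = MriGeometry(),
                      sequenceLabel = "T1w_GRE", timePoint = 1L,
                      subjectId = basename(path), bitDepth = 8L) {
  if (!dir.exists(path)) stop("not a directory: ", path)
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L) stop("no PNG/TIFF slices found in ", path)
  levels <- vapply(files, function(f) {
    m <- regmatches(basename(f), gregexpr("[0-9]+", basename(f)))[[1L]]
    if (length(m) == 0L) NA_integer_ else as.integer(m[length(m)])
  }, integer(1))
  if (any(is.na(levels)))
    stop("cannot parse a slice level index from filename(s): ",
         paste(basename(files)[is.na(levels)], collapse = ", "))
  if (anyDuplicated(levels))
    stop("duplicate slice level indices in ", path)
  ord <- order(levels)
  files <- files[ord]; levels <- levels[ord]
  m <- matrixSize(geometry)
  slices <- lapply(seq_along(files), function(i) {
    px <- readGrayImage(files[i], bitDepth = bitDepth)
    if (!identical(dim(px), c(m, m)))
      stop(sprintf("image %s is %d x %d, expected %d x %d",
                   basename(files[i]), nrow(px), ncol(px), m, m))
    MriSlice(pixels = px, levelIndex = levels[i],
             sequenceLabel = sequenceLabel, timePoint = as.integer(timePoint))
  })
  MriStack(geometry = geometry, slices = slices, subjectId = subjectId)
}

#' Save and reload a result table
#'
#' `saveResults()` writes a plain UTF-8 CSV ('.' decimal separator) with a
#' single header row; reals survive a round trip to at least 12 significant
#' digits and integers exactly. `readResults()` reads it back.
#'
#' @param table A non-empty data.frame.
#' @param path Output CSV path.
#' @return `saveResults()` returns `path` invisibly; `readResults()` returns
#'   a data.frame.
#' @export
saveResults <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("saveResults() requires a non-empty data.frame")
  out <- table
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 15, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname saveResults
#' @export
readResults <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Read and write binary ROI masks as 0/255 PNG
#'
#' @param mask A [RoiMask-class] (writing) or PNG path (reading).
#' @param path Target PNG path.
#' @param role ROI role to attach on reading.
#' @return `writeMaskPng()` returns `path` invisibly; `readMaskPng()` a
#'   [RoiMask-class].
#' @export
writeMaskPng <- function(mask, path) {
  png::writePNG(mask@mask * 1.0, path)
  invisible(path)
}

#' @rdname writeMaskPng
#' @export
readMaskPng <- function(path, role = "lesion_whole") {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  RoiMask(mask = img > 0.5, role = role)
}

#' Write a slice as a grayscale PNG
#'
#' Intensities are clipped to `[0, 2^bitDepth - 1]` and stored on that
#' scale; integer-valued intensities on the 8-bit scale round-trip exactly
#' through [loadStack()].
#'
#' @param slice An [MriSlice-class].
#' @param path Output path.
#' @param bitDepth Declared intensity scale (8 for lossless round trips).
#' @return `path`, invisibly.
#' @export
writeSlicePng <- function(slice, path, bitDepth = 8L) {
  maxv <- 2^bitDepth - 1
  px <- pmin(pmax(slice@pixels, 0), maxv) / maxv
  png::writePNG(px, path)
  invisible(path)
}
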