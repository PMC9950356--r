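#' @include AllGenerics.R
NULL

#' Accessor generics
#'
#' Small accessor generics for the tendonSI S4 classes. Accessors are the
#' supported way to read object contents; slot access via `@` is internal.
#'
#' @param x An object of the appropriate tendonSI class.
#' @return The corresponding slot value (see the class documentation).
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' @rdname accessors
#' @export
setGeneric("sliceSpacing", function(x) standardGeneric("sliceSpacing"))

#' @rdname accessors
#' @export
setGeneric("matrixSize", function(x) standardGeneric("matrixSize"))

#' @rdname accessors
#' @export
setGeneric("fieldOfView", function(x) standardGeneric("fieldOfView"))

#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname accessors
#' @export
setGeneric("slices", function(x) standardGeneric("slices"))

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("levelIndex", function(x) standardGeneric("levelIndex"))

#' @rdname accessors
#' @export
setGeneric("sequenceLabel", function(x) standardGeneric("sequenceLabel"))

#' @rdname accessors
#' @export
setGeneric("timePoint", function(x) standardGeneric("timePoint"))

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname accessors
#' @export
setGeneric("roiRole", function(x) standardGeneric("roiRole"))

#' @rdname accessors
#' @export
setGeneric("nPixels", function(x) standardGeneric("nPixels"))

#' @rdname accessors
#' @export
setGeneric("meanSi", function(x) standardGeneric("meanSi"))

#' @rdname accessors
#' @export
setGeneric("sdSi", function(x) standardGeneric("sdSi"))

#' @rdname accessors
#' @export
setGeneric("centreMm", function(x) standardGeneric("centreMm"))

#' @rdname accessors
#' @export
setGeneric("radiusMm", function(x) standardGeneric("radiusMm"))

#' @rdname accessors
#' @export
setGeneric("roiAreaMm2", function(x, ...) standardGeneric("roiAreaMm2"))
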