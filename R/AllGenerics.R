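#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' @param x An object of one of the package's S4 classes.
#' @param ... Further arguments passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("patients", function(x, ...) standardGeneric("patients"))

#' @rdname accessors
#' @export
setGeneric("raters", function(x, ...) standardGeneric("raters"))

#' @rdname accessors
#' @export
setGeneric("compartments", function(x, ...) standardGeneric("compartments"))

#' @rdname accessors
#' @export
setGeneric("presentMap", function(x, ...) standardGeneric("presentMap"))

#' @rdname accessors
#' @export
setGeneric("presentTimePoints", function(x, ...) standardGeneric("presentTimePoints"))

#' @rdname accessors
#' @export
setGeneric("labelData", function(x, ...) standardGeneric("labelData"))

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x, ...) standardGeneric("voxelSpacing"))

#' @rdname accessors
#' @export
setGeneric("voxelVolume", function(x, ...) standardGeneric("voxelVolume"))

#' @rdname accessors
#' @export
setGeneric("disagreementTotals", function(x, ...) standardGeneric("disagreementTotals"))

#' @rdname accessors
#' @export
setGeneric("disagreementCounts", function(x, ...) standardGeneric("disagreementCounts"))

#' @rdname accessors
#' @export
setGeneric("volumeSeries", function(x, rater, compartment, ...)
  standardGeneric("volumeSeries"))
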