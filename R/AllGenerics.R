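#' @rdname vaf
#' @export
setGeneric("vaf", function(x, ...) standardGeneric("vaf"))

#' @rdname vaf
#' @export
setGeneric("readDepth", function(x, ...) standardGeneric("readDepth"))

#' @rdname vaf
#' @export
setGeneric("altCounts", function(x, ...) standardGeneric("altCounts"))

#' @rdname vaf
#' @export
setGeneric("mutationIds", function(x, ...) standardGeneric("mutationIds"))

#' @rdname vaf
#' @export
setGeneric("cellIds", function(x, ...) standardGeneric("cellIds"))

#' @rdname vaf
#' @export
setGeneric("cellAnnotations", function(x, ...)
    standardGeneric("cellAnnotations"))
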