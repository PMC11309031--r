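#' @title Accessor generics
#' @description Accessors for the package's S4 containers.
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("traitLabel", function(x) standardGeneric("traitLabel"))

#' @rdname accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' @rdname accessors
#' @export
setGeneric("sampleSize", function(x) standardGeneric("sampleSize"))

#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname accessors
#' @export
setGeneric("harmonizedPairs", function(x) standardGeneric("harmonizedPairs"))

#' @rdname accessors
#' @export
setGeneric("exclusionLog", function(x) standardGeneric("exclusionLog"))

#' @rdname accessors
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))
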