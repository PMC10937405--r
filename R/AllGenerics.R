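#' @include AllClasses.R
NULL

#' @rdname SVCatalog-class
#' @param object,x an \code{SVCatalog}
#' @export
setGeneric("svRanges", function(x) standardGeneric("svRanges"))

#' @rdname SVCatalog-class
#' @export
setGeneric("svID", function(x) standardGeneric("svID"))

#' @rdname SVCatalog-class
#' @export
setGeneric("svType", function(x) standardGeneric("svType"))

#' @rdname SVCatalog-class
#' @export
setGeneric("altLength", function(x) standardGeneric("altLength"))

#' @rdname SVCatalog-class
#' @export
setGeneric("sourceGenomes", function(x) standardGeneric("sourceGenomes"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("accessionData", function(x) standardGeneric("accessionData"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("morphotypes", function(x) standardGeneric("morphotypes"))

#' @rdname SyntheticBundle-class
#' @export
setGeneric("svTruth", function(x) standardGeneric("svTruth"))

#' @rdname SyntheticBundle-class
#' @export
setGeneric("bundleGenes", function(x) standardGeneric("bundleGenes"))
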