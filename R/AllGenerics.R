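#' @include AllClasses.R
NULL

#' Accessors for rohmapper classes
#'
#' @param object,x an object of the documented class
#' @param ... unused
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pedTable", function(object) standardGeneric("pedTable"))

#' @rdname accessors
#' @export
setGeneric("founders", function(object) standardGeneric("founders"))

#' @rdname accessors
#' @export
setGeneric("affectedIds", function(object) standardGeneric("affectedIds"))

#' @rdname accessors
#' @export
setGeneric("unaffectedIds", function(object) standardGeneric("unaffectedIds"))

#' @rdname accessors
#' @export
setGeneric("markers", function(object) standardGeneric("markers"))

#' @rdname accessors
#' @export
setGeneric("chromosomes", function(object) standardGeneric("chromosomes"))

#' @rdname accessors
#' @export
setGeneric("variantSites", function(object) standardGeneric("variantSites"))

#' @rdname accessors
#' @export
setGeneric("genotypes", function(object) standardGeneric("genotypes"))

#' @rdname accessors
#' @export
setGeneric("altDepth", function(object) standardGeneric("altDepth"))

#' @rdname accessors
#' @export
setGeneric("refDepth", function(object) standardGeneric("refDepth"))

#' @rdname accessors
#' @export
setGeneric("readDepth", function(object) standardGeneric("readDepth"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("truthRecord", function(object) standardGeneric("truthRecord"))

#' @rdname accessors
#' @export
setGeneric("ibdSegments", function(object) standardGeneric("ibdSegments"))

#' @rdname accessors
#' @export
setGeneric("survivingVariants", function(object) standardGeneric("survivingVariants"))

#' @rdname accessors
#' @export
setGeneric("excludedCounts", function(object) standardGeneric("excludedCounts"))

#' @rdname accessors
#' @export
setGeneric("isConsistent", function(object) standardGeneric("isConsistent"))

#' @rdname accessors
#' @export
setGeneric("violations", function(object) standardGeneric("violations"))
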