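#' @title Generics for parcelTBS containers
#' @name parcelTBS-generics
#' @description Accessor generics shared by the core S4 containers.
#' @param x a parcelTBS object
#' @return \code{parcelIds}: character vector of parcel identifiers;
#'   \code{values}: the numeric matrix payload; \code{frameMask}: logical
#'   vector of retained frames; \code{nParcels}: integer parcel count;
#'   \code{edgeTable}: data.frame with one row per upper-triangle edge.
NULL

#' @rdname parcelTBS-generics
#' @export
setGeneric("parcelIds", function(x) standardGeneric("parcelIds"))

#' @rdname parcelTBS-generics
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname parcelTBS-generics
#' @export
setGeneric("frameMask", function(x) standardGeneric("frameMask"))

#' @rdname parcelTBS-generics
#' @export
setGeneric("nParcels", function(x) standardGeneric("nParcels"))

#' @rdname parcelTBS-generics
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
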