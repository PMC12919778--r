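#' @include AllClasses.R
NULL

#' Feature matrix of an EmbeddingSet
#'
#' Returns the n x d feature matrix (items in rows), the orientation the
#' analysis functions work in.
#'
#' @param x An \linkS4class{EmbeddingSet}.
#' @return Numeric matrix, one row per item, row names = item ids.
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' Item identifiers
#' @param x An \linkS4class{EmbeddingSet}.
#' @return Character vector of unique item ids, in set order.
#' @export
setGeneric("itemIds", function(x) standardGeneric("itemIds"))

#' Per-item metadata
#'
#' @param x An \linkS4class{EmbeddingSet}.
#' @param variable Optional variable name; when given, returns that
#'   variable's values as a character vector named by item id.
#' @return A data.frame of all metadata, or one variable's values.
#' @export
setGeneric("itemMeta", function(x, variable) standardGeneric("itemMeta"))

#' Number of items / feature dimension
#' @param x An \linkS4class{EmbeddingSet}.
#' @return Integer scalar.
#' @export
setGeneric("nItems", function(x) standardGeneric("nItems"))

#' @rdname nItems
#' @export
setGeneric("featureDim", function(x) standardGeneric("featureDim"))
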