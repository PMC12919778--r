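#' @include AllGenerics.R
NULL

#' Construct an EmbeddingSet
#'
#' @param features Numeric matrix, one row per item (n x d), all values
#'   finite. Column names are kept if present, otherwise named
#'   \code{f0 ... f(d-1)}.
#' @param ids Character vector of unique item identifiers, length n.
#' @param metadata Optional data.frame (n rows) of categorical metadata;
#'   all columns are coerced to character and missing cells materialised
#'   as the explicit level \code{"NA"}.
#' @return A validated \linkS4class{EmbeddingSet}.
#' @examples
#' es <- EmbeddingSet(matrix(rnorm(12), 3), ids = c("a", "b", "c"),
#'                    metadata = data.frame(site = c("s1", "s1", "s2")))
#' nItems(es)
#' @export
EmbeddingSet <- function(features, ids, metadata = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features)) flensError("features must be numeric")
  n <- nrow(features)
  ids <- as.character(ids)
  if (length(ids) != n)
    flensError(sprintf("ids (%d) must match feature rows (%d)",
                       length(ids), n))
  if (anyDuplicated(ids))
    flensError(sprintf("duplicate item id: '%s'", ids[duplicated(ids)][1]))
  if (any(!is.finite(features))) {
    bad <- which(!is.finite(features), arr.ind = TRUE)[1, ]
    flensError(sprintf("non-finite feature value at row %d (id '%s'), column %d",
                       bad[1], ids[bad[1]], bad[2]))
  }
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)) - 1L)
  if (is.null(metadata)) metadata <- data.frame(row.names = ids)
  metadata <- as.data.frame(metadata)
  if (nrow(metadata) && nrow(metadata) != n)
    flensError("metadata rows must match feature rows")
  if (!nrow(metadata) && length(metadata) == 0L)
    metadata <- data.frame(matrix(nrow = n, ncol = 0L))
  for (v in colnames(metadata)) {
    col <- as.character(metadata[[v]])
    col[is.na(col)] <- "NA"
    metadata[[v]] <- col
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(embeddings = t(features)),
    colData = S4Vectors::DataFrame(metadata, row.names = ids))
  colnames(se) <- ids
  new("EmbeddingSet", se)
}

#' @rdname features
#' @export
setMethod("features", "EmbeddingSet", function(x) {
  t(SummarizedExperiment::assay(x, "embeddings"))
})

#' @rdname itemIds
#' @export
setMethod("itemIds", "EmbeddingSet", function(x) colnames(x))

#' @rdname itemMeta
#' @export
setMethod("itemMeta", "EmbeddingSet", function(x, variable) {
  cd <- SummarizedExperiment::colData(x)
  if (missing(variable))
    return(as.data.frame(cd))
  if (!variable %in% colnames(cd))
    flensError(sprintf("metadata variable '%s' not found (have: %s)",
                       variable, paste(colnames(cd), collapse = ", ")))
  stats::setNames(as.character(cd[[variable]]), colnames(x))
})

#' @rdname nItems
#' @export
setMethod("nItems", "EmbeddingSet", function(x) ncol(x))

#' @rdname nItems
#' @export
setMethod("featureDim", "EmbeddingSet", function(x) nrow(x))

#' @describeIn EmbeddingSet Compact display.
#' @param object An EmbeddingSet.
#' @export
setMethod("show", "EmbeddingSet", function(object) {
  cat(sprintf("EmbeddingSet: %d items x %d features\n",
              nItems(object), featureDim(object)))
  mv <- colnames(SummarizedExperiment::colData(object))
  cat("metadata:", if (length(mv)) paste(mv, collapse = ", ") else "(none)", "\n")
  ids <- itemIds(object)
  cat("ids:", paste(utils::head(ids, 4L), collapse = ", "),
      if (length(ids) > 4L) "..." else "", "\n")
})

#' Subset an EmbeddingSet by item id
#'
#' Returns the requested items in the requested order, metadata carried
#' along. Unknown ids are an error.
#'
#' @param set An \linkS4class{EmbeddingSet}.
#' @param ids Character vector of item ids, a subset of \code{itemIds(set)}.
#' @return An \linkS4class{EmbeddingSet} with \code{length(ids)} items.
#' @export
subsetEmbeddings <- function(set, ids) {
  stopifnot(is(set, "EmbeddingSet"))
  ids <- as.character(ids)
  unknown <- setdiff(ids, itemIds(set))
  if (length(unknown))
    flensError(sprintf("unknown item id(s): %s",
                       paste(utils::head(unknown, 5L), collapse = ", ")))
  out <- set[, ids]
  new("EmbeddingSet", out)
}

## Validate a VariableSpec against a set; returns label vector.
variableLabels <- function(set, variable) {
  name <- if (is(variable, "VariableSpec")) variable@name else as.character(variable)
  itemMeta(set, name)
}

#' @rdname VariableSpec-class
#' @param name Metadata variable name.
#' @param role \code{"bias"} or \code{"prognostic"}.
#' @export
variableSpec <- function(name, role = c("bias", "prognostic")) {
  new("VariableSpec", name = name, role = match.arg(role))
}
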