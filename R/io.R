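#' @include EmbeddingSet.R
NULL

## File dialect: one header row; "id" column, zero or more "meta_<var>"
## columns, feature columns "f0" ... "f{d-1}". Features are printed with
## %.17g so a text round-trip reproduces the double exactly and
## save -> load -> save is byte-stable.

FEATURE_FMT <- "%.17g"

#' Load an embedding table
#'
#' Reads a delimited text file (\code{tsv}, \code{csv}) or the binary
#' columnar dialect (\code{binary}, an Arrow/Feather file) into a
#' validated \linkS4class{EmbeddingSet}. The header must declare one
#' \code{id} column; columns prefixed \code{meta_} become metadata
#' variables; all remaining columns are features. Row order is preserved.
#'
#' @param path Input file.
#' @param format One of \code{"tsv"}, \code{"csv"}, \code{"binary"};
#'   default guesses from the file extension (\code{.tsv}, \code{.csv},
#'   anything else binary).
#' @return An \linkS4class{EmbeddingSet}.
#' @seealso [saveEmbeddings()]
#' @export
loadEmbeddings <- function(path, format = c("auto", "tsv", "csv", "binary")) {
  format <- match.arg(format)
  if (format == "auto") format <- guessFormat(path)
  if (!file.exists(path)) flensError(sprintf("file not found: %s", path))
  df <- if (format == "binary") {
    as.data.frame(arrow::read_feather(path))
  } else {
    sep <- if (format == "tsv") "\t" else ","
    tryCatch(
      as.data.frame(data.table::fread(path, sep = sep, header = TRUE,
                                      colClasses = list(character = "id"),
                                      data.table = FALSE, fill = FALSE)),
      error = function(e) flensError(
        sprintf("malformed table %s: %s", path, conditionMessage(e))))
  }
  if (!"id" %in% colnames(df))
    flensError(sprintf("%s: no 'id' column in header", path))
  metaCols <- grep("^meta_", colnames(df), value = TRUE)
  featCols <- setdiff(colnames(df), c("id", metaCols))
  feat <- df[, featCols, drop = FALSE]
  for (j in seq_along(featCols)) {
    col <- feat[[j]]
    if (is.character(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        flensError(sprintf("non-numeric feature value '%s' at row %d, column '%s'",
                           col[bad[1]], bad[1], featCols[j]))
      feat[[j]] <- num
    }
  }
  features <- as.matrix(feat)
  colnames(features) <- featCols
  metadata <- df[, metaCols, drop = FALSE]
  colnames(metadata) <- sub("^meta_", "", metaCols)
  EmbeddingSet(features, ids = df$id, metadata = metadata)
}

#' Save an embedding table
#'
#' Writes an \linkS4class{EmbeddingSet} so that it round-trips through
#' [loadEmbeddings()]: exactly for the binary dialect (Arrow/Feather,
#' float64 feature columns), and to full double precision for the text
#' dialects (features printed with 17 significant digits).
#'
#' @param set An \linkS4class{EmbeddingSet}.
#' @param path Destination file.
#' @param format \code{"tsv"}, \code{"csv"} or \code{"binary"} (default
#'   guesses from the extension).
#' @return \code{path}, invisibly.
#' @export
saveEmbeddings <- function(set, path, format = c("auto", "tsv", "csv", "binary")) {
  stopifnot(is(set, "EmbeddingSet"))
  format <- match.arg(format)
  if (format == "auto") format <- guessFormat(path)
  feat <- features(set)
  colnames(feat) <- paste0("f", seq_len(ncol(feat)) - 1L)
  md <- itemMeta(set)
  if (ncol(md)) colnames(md) <- paste0("meta_", colnames(md))
  if (format == "binary") {
    df <- data.frame(id = itemIds(set), md, feat,
                     check.names = FALSE, stringsAsFactors = FALSE)
    ok <- tryCatch({ arrow::write_feather(df, path); TRUE },
                   error = function(e) flensError(
                     sprintf("cannot write %s: %s", path, conditionMessage(e))))
  } else {
    sep <- if (format == "tsv") "\t" else ","
    txt <- apply(feat, 2L, function(col) sprintf(FEATURE_FMT, col))
    if (nItems(set) == 1L) txt <- matrix(txt, nrow = 1L)
    header <- paste(c("id", colnames(md), colnames(feat)), collapse = sep)
    body <- do.call(paste, c(list(itemIds(set)),
                             unname(as.list(as.data.frame(md, stringsAsFactors = FALSE))),
                             unname(as.list(as.data.frame(txt, stringsAsFactors = FALSE))),
                             sep = sep))
    ok <- tryCatch({ writeLines(c(header, body), path); TRUE },
                   error = function(e) flensError(
                     sprintf("cannot write %s: %s", path, conditionMessage(e))))
  }
  invisible(path)
}

guessFormat <- function(path) {
  switch(tolower(tools::file_ext(path)), tsv = "tsv", csv = "csv", "binary")
}

#' Flatten tile images into raw-pixel feature vectors
#'
#' Resizes each image to \code{targetSide} x \code{targetSide} by area
#' averaging (box filter), scales to [0, 1], and flattens the three
#' channel planes row-major (R plane, then G, then B) into one feature
#' vector of length \code{3 * targetSide^2}. Used for the raw-pixel
#' comparison projection: if a projection of these vectors shows the same
#' grouping as the encoder embeddings, the encoder may only be picking up
#' trivial colour/intensity patterns.
#'
#' @param imagePaths Character vector of PNG/JPG paths, or a list of
#'   in-memory image arrays (H x W x 3, values in [0,1] or 0..255).
#' @param targetSide Output side length in pixels (>= 1).
#' @return An \linkS4class{EmbeddingSet} with one row per image.
#' @export
pixelsAsEmbeddings <- function(imagePaths, targetSide = 32L) {
  stopifnot(targetSide >= 1L)
  targetSide <- as.integer(targetSide)
  imgs <- lapply(imagePaths, asRGBArray)
  ids <- if (is.character(imagePaths)) {
    b <- basename(imagePaths)
    b <- sub("\\.[^.]+$", "", b)
    if (anyDuplicated(b)) as.character(imagePaths) else b
  } else sprintf("img_%d", seq_along(imgs))
  feat <- t(vapply(imgs, function(img) {
    planes <- lapply(1:3, function(ch)
      boxResize(img[, , ch], targetSide))
    unlist(lapply(planes, function(p) as.vector(t(p))), use.names = FALSE)
  }, numeric(3L * targetSide^2)))
  rownames(feat) <- ids
  EmbeddingSet(feat, ids = ids)
}

## Area-average (box filter) resize of one channel to side x side.
## Output pixel (i, j) averages the input over the rectangle
## [(i-1)H/s, iH/s) x [(j-1)W/s, jW/s) with partial-pixel weights, so the
## result is exact block means when the ratio is integral and an exact
## area-weighted mean otherwise.
boxResize <- function(mat, side) {
  H <- nrow(mat); W <- ncol(mat)
  wr <- intervalWeights(H, side)   # side x H
  wc <- intervalWeights(W, side)   # side x W
  num <- wr %*% mat %*% t(wc)
  area <- (H / side) * (W / side)
  num / area
}

intervalWeights <- function(n, side) {
  w <- matrix(0, side, n)
  bounds <- (0:side) * n / side
  for (i in seq_len(side)) {
    lo <- bounds[i]; hi <- bounds[i + 1L]
    r0 <- floor(lo) + 1L
    r1 <- min(n, ceiling(hi))
    for (r in r0:r1)
      w[i, r] <- max(0, min(r, hi) - max(r - 1L, lo))
  }
  w
}
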