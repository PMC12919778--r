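#' @include EmbeddingSet.R
NULL

#' Tessellate a slide into a grid of fixed-size tiles
#'
#' Tile origins lie on a regular grid with stride
#' \code{round(tileSide * (1 - overlap))}; only tiles that fit fully
#' inside the slide are kept (partial edge tiles are dropped, matching the
#' fixed-input-size requirement of downstream encoders). A slide smaller
#' than one tile yields an empty grid, not an error.
#'
#' @param width,height Slide dimensions in pixels.
#' @param tileSide Tile side length in pixels (default 1024).
#' @param overlap Fractional overlap between adjacent tiles in [0, 1)
#'   (default 0.25, i.e. stride 768 at the default side).
#' @param slideId Optional slide identifier carried in the result.
#' @return A \linkS4class{TileGrid}; \code{origins} holds 0-based
#'   top-left (x, y) coordinates, x varying fastest.
#' @examples
#' nrow(tileGrid(1792, 1024)@origins)  # 2 tiles: (0,0) and (768,0)
#' @export
tileGrid <- function(width, height, tileSide = 1024L, overlap = 0.25,
                     slideId = "slide") {
  stopifnot(tileSide >= 1L, overlap >= 0, overlap < 1)
  stride <- round(tileSide * (1 - overlap))
  if (stride < 1) flensError("stride must be >= 1")
  xs <- if (width >= tileSide) seq(0L, width - tileSide, by = stride) else integer(0)
  ys <- if (height >= tileSide) seq(0L, height - tileSide, by = stride) else integer(0)
  origins <- as.matrix(expand.grid(x = as.integer(xs), y = as.integer(ys)))
  if (!nrow(origins)) origins <- matrix(integer(0), 0L, 2L,
                                        dimnames = list(NULL, c("x", "y")))
  new("TileGrid", slideId = slideId, tileSide = as.integer(tileSide),
      overlap = overlap, origins = origins)
}

#' Whitespace fraction of a tile
#'
#' The fraction of pixels that count as whitespace: all three channels at
#' least \code{cutoff} on the 8-bit scale (default 220, i.e. near-white
#' background of a scanned slide).
#'
#' @param tile An H x W x 3 array in [0, 1] or 0..255, a grayscale matrix,
#'   or an image file path.
#' @param cutoff Per-channel 8-bit whitespace cutoff (default 220).
#' @return Fraction in [0, 1].
#' @export
whitespaceFraction <- function(tile, cutoff = 220) {
  img <- asRGBArray(tile)
  if (!length(img)) flensError("empty image")
  white <- img[, , 1] >= cutoff / 255 & img[, , 2] >= cutoff / 255 &
    img[, , 3] >= cutoff / 255
  mean(white)
}

#' Filter tiles by whitespace content
#'
#' Keeps a tile iff its whitespace fraction is at most \code{threshold}
#' (strictly-greater tiles are removed: a tile at exactly the threshold is
#' kept). The default 0.85 removes tiles that are more than 85\%
#' background.
#'
#' @param tiles List of tiles (arrays or file paths, as in
#'   [whitespaceFraction()]).
#' @param threshold Removal threshold in [0, 1].
#' @param cutoff Per-channel whitespace cutoff, see [whitespaceFraction()].
#' @return Integer vector of kept tile indices (1-based).
#' @export
filterWhitespace <- function(tiles, threshold = 0.85, cutoff = 220) {
  stopifnot(threshold >= 0, threshold <= 1)
  fr <- vapply(tiles, whitespaceFraction, numeric(1), cutoff = cutoff)
  which(fr <= threshold)
}

#' Rank groups by item count and keep the top n
#'
#' Groups are sorted by count descending, ties broken by group id
#' ascending; the first \code{min(n, #groups)} are returned. Used to
#' restrict an analysis to the largest sites, which guarantees enough
#' samples per class for probing and projection.
#'
#' @param counts Named numeric vector or table: group id -> item count.
#' @param n Number of groups to keep.
#' @return Character vector of group ids, largest first.
#' @examples
#' topNGroups(c("22" = 19499, "39" = 32686, "60" = 19300,
#'              "66" = 25694, "85" = 49355), 5)
#' @export
topNGroups <- function(counts, n) {
  if (is.table(counts)) counts <- stats::setNames(as.numeric(counts),
                                                  names(counts))
  if (!length(counts)) flensError("empty group counts")
  if (is.null(names(counts))) flensError("counts must be named by group")
  stopifnot(n >= 1L)
  ord <- order(-counts, names(counts))
  names(counts)[ord][seq_len(min(n, length(counts)))]
}

#' Balance groups over a covariate by min-cell equalisation
#'
#' Two steps: (1) covariate levels that are absent from any group are
#' dropped entirely (the generalisation of excluding a tumour stage that
#' only one site has); (2) every remaining (group, covariate) cell is
#' subsampled (seeded, uniform, without replacement) down to the global
#' minimum cell count. The result has identical covariate contingency rows
#' for all groups, removing covariate confounding by construction.
#'
#' @param set An \linkS4class{EmbeddingSet}.
#' @param groupVar Grouping variable name (e.g. site).
#' @param covariateVar Covariate variable name (e.g. stage).
#' @param seed RNG seed for the cell subsampling.
#' @return A balanced \linkS4class{EmbeddingSet} (original row order).
#' @export
balanceByCovariate <- function(set, groupVar, covariateVar, seed = 0L) {
  stopifnot(is(set, "EmbeddingSet"))
  groups <- itemMeta(set, groupVar)
  covs <- itemMeta(set, covariateVar)
  ids <- itemIds(set)
  gLevels <- sort(unique(groups))
  levelsByGroup <- lapply(gLevels, function(g) unique(covs[groups == g]))
  common <- Reduce(intersect, levelsByGroup)
  if (!length(common)) {
    sizes <- vapply(levelsByGroup, length, integer(1))
    flensError(sprintf(
      "no covariate level shared by all groups; offending group(s): %s",
      paste(gLevels[sizes == min(sizes)], collapse = ", ")))
  }
  keepLevel <- covs %in% common
  cellCount <- table(groups[keepLevel], covs[keepLevel])
  cellCount <- cellCount[, common, drop = FALSE]
  if (any(cellCount == 0)) {
    bad <- which(cellCount == 0, arr.ind = TRUE)[1, ]
    flensError(sprintf("group '%s' has no items at covariate level '%s'",
                       rownames(cellCount)[bad[1]], common[bad[2]]))
  }
  target <- min(cellCount)
  cellSeeds <- matrix(subSeeds(seed, length(gLevels) * length(common)),
                      nrow = length(gLevels))
  keep <- character(0)
  for (i in seq_along(gLevels)) for (j in seq_along(common)) {
    cell <- ids[groups == gLevels[i] & covs == common[j]]
    keep <- c(keep, withSeed(cellSeeds[i, j], sample(cell, target)))
  }
  subsetEmbeddings(set, ids[ids %in% keep])
}

#' Patient-disjoint train/validation/test split
#'
#' Shuffles the grouping units (patients by default) with the seed, then
#' assigns each unit greedily to the split whose current item-count
#' shortfall relative to its target (fraction x total items) is largest;
#' ties resolve in train, validation, test order. All of a unit's items
#' follow it, so the three splits have pairwise-disjoint unit sets and no
#' leakage; per-split item proportions deviate from the targets by at most
#' the largest single unit's share.
#'
#' @param set An \linkS4class{EmbeddingSet}.
#' @param unitVar Grouping variable (default \code{"patient"}).
#' @param fractions Length-3 positive target fractions (train,
#'   validation, test) summing to 1; default \code{c(0.70, 0.15, 0.15)}.
#' @param seed RNG seed for the unit shuffle.
#' @return A \linkS4class{SplitAssignment}.
#' @export
patientDisjointSplit <- function(set, unitVar = "patient",
                                 fractions = c(0.70, 0.15, 0.15), seed = 0L) {
  stopifnot(is(set, "EmbeddingSet"), length(fractions) == 3L)
  if (any(fractions <= 0)) flensError("split fractions must be positive")
  if (abs(sum(fractions) - 1) > 1e-9)
    flensError("split fractions must sum to 1")
  units <- itemMeta(set, unitVar)
  uniq <- unique(units)
  if (length(uniq) < 3L)
    flensError(sprintf("need at least 3 '%s' units for a 3-way split, have %d",
                       unitVar, length(uniq)))
  sizes <- table(units)[uniq]
  ord <- withSeed(seed, sample(uniq))
  total <- nItems(set)
  splitNames <- c("train", "validation", "test")
  target <- fractions * total
  got <- c(0, 0, 0)
  unitSplit <- stats::setNames(character(length(ord)), ord)
  for (u in ord) {
    shortfall <- target - got
    pick <- which.max(shortfall)      # ties: first index wins
    unitSplit[u] <- splitNames[pick]
    got[pick] <- got[pick] + sizes[[u]]
  }
  assignments <- stats::setNames(unitSplit[units], itemIds(set))
  new("SplitAssignment", assignments = assignments, fractions = fractions,
      unit = unitVar)
}

#' Items of one split
#'
#' @param set An \linkS4class{EmbeddingSet}.
#' @param split A \linkS4class{SplitAssignment} for the set.
#' @param which One of \code{"train"}, \code{"validation"}, \code{"test"},
#'   or a vector of these (items of all named splits, original order).
#' @return An \linkS4class{EmbeddingSet}.
#' @export
splitItems <- function(set, split, which = "train") {
  stopifnot(is(split, "SplitAssignment"))
  ids <- names(split@assignments)[split@assignments %in% which]
  subsetEmbeddings(set, itemIds(set)[itemIds(set) %in% ids])
}
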