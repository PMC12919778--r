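#' @include EmbeddingSet.R
NULL

#' @rdname SyntheticConfig-class
#' @param nSites,nClasses Number of sites (batches) and stage classes.
#' @param d Feature dimension; must be at least \code{nClasses + nSites}.
#' @param patientsPerSite,slidesPerPatient,tilesPerSlide Hierarchy sizes;
#'   the total item count is their product times \code{nSites}.
#' @param delta Site batch-effect magnitude (>= 0).
#' @param sigma Noise scale (> 0).
#' @param classSep Class-mean separation (>= 0).
#' @param seed RNG seed; the whole generation is a deterministic function
#'   of the config.
#' @export
syntheticConfig <- function(nSites = 5L, nClasses = 3L, d = 64L,
                            patientsPerSite = 10L, slidesPerPatient = 2L,
                            tilesPerSlide = 10L, delta = 1, sigma = 1,
                            classSep = 1, seed = 0L) {
  new("SyntheticConfig", nSites = as.integer(nSites),
      nClasses = as.integer(nClasses), d = as.integer(d),
      patientsPerSite = as.integer(patientsPerSite),
      slidesPerPatient = as.integer(slidesPerPatient),
      tilesPerSlide = as.integer(tilesPerSlide),
      delta = as.numeric(delta), sigma = as.numeric(sigma),
      classSep = as.numeric(classSep), seed = as.integer(seed))
}

#' Generate synthetic embeddings with known batch-effect structure
#'
#' Emulates encoder output for a multi-site cohort with a patient/slide
#' hierarchy. Each item's feature vector is
#' \deqn{x = classSep \cdot \mu_c + delta \cdot v_s + sigma \cdot \epsilon}
#' where the class directions \eqn{\mu_c} are the first \code{nClasses}
#' standard basis vectors, the site directions \eqn{v_s} the next
#' \code{nSites} (orthonormal, and orthogonal to every class direction),
#' and \eqn{\epsilon} is i.i.d. standard normal. Orthogonality makes the
#' site signal analytically controllable: site centroids sit at pairwise
#' distance \eqn{delta \sqrt{2}}, and class balance cannot alter expected
#' site separability.
#'
#' Stage classes are assigned at the patient level (all of a patient's
#' tiles share a stage) from a balanced, seed-shuffled label vector, so
#' every class is occupied and the marginal is uniform. Metadata columns:
#' \code{site}, \code{class}, \code{patient}, \code{slide}.
#'
#' @param config A \linkS4class{SyntheticConfig}.
#' @return An \linkS4class{EmbeddingSet} with
#'   \code{nSites * patientsPerSite * slidesPerPatient * tilesPerSlide}
#'   items.
#' @examples
#' es <- genEmbeddings(syntheticConfig(delta = 4, seed = 1))
#' table(itemMeta(es, "site"))
#' @export
genEmbeddings <- function(config = syntheticConfig()) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  ns <- config@nSites; nc <- config@nClasses; d <- config@d
  nPat <- ns * config@patientsPerSite
  nSlides <- nPat * config@slidesPerPatient
  n <- nSlides * config@tilesPerSlide

  site <- rep(seq_len(ns), each = config@patientsPerSite)      # per patient
  patClassPool <- rep_len(seq_len(nc), nPat)
  withSeed(config@seed, {
    patClass <- sample(patClassPool)                            # per patient
    noise <- matrix(stats::rnorm(n * d), n, d)
  })

  patOfSlide <- rep(seq_len(nPat), each = config@slidesPerPatient)
  slideOfTile <- rep(seq_len(nSlides), each = config@tilesPerSlide)
  patOfTile <- patOfSlide[slideOfTile]
  siteOfTile <- site[patOfTile]
  classOfTile <- patClass[patOfTile]

  X <- config@sigma * noise
  ## orthonormal directions: classes on basis vectors 1..nc, sites on the next ns
  cIdx <- cbind(seq_len(n), classOfTile)
  sIdx <- cbind(seq_len(n), nc + siteOfTile)
  X[cIdx] <- X[cIdx] + config@classSep
  X[sIdx] <- X[sIdx] + config@delta

  ids <- sprintf("s%02d_p%04d_sl%05d_t%03d", siteOfTile, patOfTile,
                 slideOfTile, stats::ave(slideOfTile, slideOfTile,
                                         FUN = seq_along))
  metadata <- data.frame(
    site = sprintf("site%02d", siteOfTile),
    class = sprintf("class%d", classOfTile),
    patient = sprintf("p%04d", patOfTile),
    slide = sprintf("sl%05d", slideOfTile),
    stringsAsFactors = FALSE)
  EmbeddingSet(X, ids = ids, metadata = metadata)
}

#' Generate toy tiles with exact whitespace fractions
#'
#' Builds square RGB tiles in which exactly \code{round(fraction * side^2)}
#' pixels are white (all channels 1.0) and the rest dark (all channels
#' 50/255), with seeded-random positions. The true white fraction of each
#' tile is therefore known by construction, which makes the whitespace
#' filter directly checkable.
#'
#' @param whiteFractions Numeric vector in [0, 1], one tile per entry.
#' @param side Tile side length in pixels.
#' @param seed RNG seed for the pixel positions.
#' @return A list with \code{tiles} (list of side x side x 3 arrays in
#'   [0,1]) and \code{trueFractions} (the realised fractions,
#'   \code{round(f * side^2) / side^2}).
#' @export
genTiles <- function(whiteFractions, side = 32L, seed = 0L) {
  stopifnot(all(whiteFractions >= 0 & whiteFractions <= 1), side >= 1L)
  side <- as.integer(side)
  nPix <- side * side
  seeds <- subSeeds(seed, length(whiteFractions))
  tiles <- vector("list", length(whiteFractions))
  trueFractions <- numeric(length(whiteFractions))
  dark <- 50 / 255
  for (i in seq_along(whiteFractions)) {
    nWhite <- round(whiteFractions[i] * nPix)
    trueFractions[i] <- nWhite / nPix
    pos <- withSeed(seeds[i], sample.int(nPix, nWhite))
    plane <- rep(dark, nPix)
    plane[pos] <- 1
    tiles[[i]] <- array(rep(plane, 3L), dim = c(side, side, 3L))
  }
  list(tiles = tiles, trueFractions = trueFractions)
}

#' Write tiles to PNG files
#'
#' Convenience for the command-line interface and for building image
#' fixtures: writes each tile array of [genTiles()] as a PNG.
#'
#' @param tiles List of H x W x 3 arrays in [0, 1].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of file paths.
#' @export
writeTiles <- function(tiles, dir, prefix = "tile") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%03d.png", prefix, seq_along(tiles)))
  for (i in seq_along(tiles)) png::writePNG(tiles[[i]], paths[i])
  paths
}
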