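#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' EmbeddingSet: embeddings with aligned categorical metadata
#'
#' The universal currency of the toolkit: \code{n} items (image tiles,
#' typically), each carrying a \code{d}-dimensional feature vector produced
#' by some encoder, plus zero or more categorical metadata variables (site,
#' stage, patient, slide, ...). Internally a
#' \linkS4class{SummarizedExperiment} whose single \code{"embeddings"} assay
#' is the \code{d x n} feature matrix (features in rows, items in columns,
#' Bioconductor convention); item ids are the column names and metadata live
#' in \code{colData}.
#'
#' Validity requires unique item ids, all-finite features, and metadata
#' defined for every item (missing values are materialised as the explicit
#' level \code{"NA"} by the constructor, never stored as R \code{NA}).
#'
#' @seealso [EmbeddingSet()], [features()], [itemIds()], [itemMeta()]
#' @export
setClass("EmbeddingSet", contains = "SummarizedExperiment")

setValidity("EmbeddingSet", function(object) {
  if (!"embeddings" %in% SummarizedExperiment::assayNames(object))
    return("assay 'embeddings' is missing")
  m <- SummarizedExperiment::assay(object, "embeddings")
  if (is.null(colnames(object)))
    return("item ids (column names) are missing")
  if (anyDuplicated(colnames(object))) {
    dup <- colnames(object)[duplicated(colnames(object))][1]
    return(sprintf("duplicate item id: '%s'", dup))
  }
  if (!is.numeric(m)) return("features must be numeric")
  if (any(!is.finite(m))) return("features contain non-finite values")
  cd <- SummarizedExperiment::colData(object)
  for (v in colnames(cd)) {
    col <- cd[[v]]
    if (!is.character(col))
      return(sprintf("metadata variable '%s' must be character", v))
    if (anyNA(col))
      return(sprintf("metadata variable '%s' has missing values; encode as explicit \"NA\"", v))
  }
  TRUE
})

#' VariableSpec: a metadata variable to analyse
#'
#' Names a categorical metadata variable together with its role in the
#' analysis: \code{"bias"} for sensitive variables a model should not
#' encode (tissue source site, scanner, gender), \code{"prognostic"} for
#' variables it legitimately may (tumour stage).
#'
#' @export
setClass("VariableSpec",
         representation(name = "character", role = "character"),
         prototype(role = "bias"))

setValidity("VariableSpec", function(object) {
  if (!isScalarString(object@name)) return("name must be a single string")
  if (!object@role %in% c("bias", "prognostic"))
    return("role must be 'bias' or 'prognostic'")
  TRUE
})

#' ProbeConfig: linear-probe training and evaluation settings
#'
#' Defaults follow standard practice for probing frozen embeddings:
#' 20 epochs of mini-batch Adam (batches of 256, learning rate 1e-3,
#' beta1 0.9, beta2 0.999), 100 bootstrap resamples of the test set and a
#' 95\% percentile confidence interval.
#'
#' @export
setClass("ProbeConfig",
         representation(epochs = "integer", batchSize = "integer",
                        learningRate = "numeric", beta1 = "numeric",
                        beta2 = "numeric", nBootstrap = "integer",
                        ciLevel = "numeric", seed = "integer"),
         prototype(epochs = 20L, batchSize = 256L, learningRate = 1e-3,
                   beta1 = 0.9, beta2 = 0.999, nBootstrap = 100L,
                   ciLevel = 0.95, seed = 0L))

setValidity("ProbeConfig", function(object) {
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@learningRate <= 0) return("learningRate must be > 0")
  if (object@nBootstrap < 1L) return("nBootstrap must be >= 1")
  if (object@ciLevel <= 0 || object@ciLevel >= 1)
    return("ciLevel must be in (0, 1)")
  TRUE
})

#' ProbeModel: a trained linear probe
#'
#' An affine map from d features to m class scores. Prediction is the
#' argmax of the affine map (softmax is monotone, so it is omitted at
#' predict time); argmax ties break toward the lowest class index.
#' \code{center} and \code{scale} hold the training-split standardisation
#' applied before the linear layer.
#'
#' @export
setClass("ProbeModel",
         representation(weights = "matrix", bias = "numeric",
                        classLabels = "character", center = "numeric",
                        scale = "numeric", provenance = "list"))

setValidity("ProbeModel", function(object) {
  m <- length(object@classLabels)
  if (m < 2L) return("a probe needs >= 2 classes")
  if (ncol(object@weights) != m) return("weights columns must match classes")
  if (length(object@bias) != m) return("bias length must match classes")
  if (length(object@center) != nrow(object@weights) ||
      length(object@scale) != nrow(object@weights))
    return("standardisation vectors must match feature dimension")
  TRUE
})

#' ProbeResult: held-out probe performance with uncertainty
#'
#' Accuracy on the full test set, percentile-bootstrap confidence bounds,
#' Cohen's kappa averaged over bootstrap replicates (\code{NA} when chance
#' agreement is 1 in every replicate), per-class accuracies and the full
#' confusion matrix (rows = true, columns = predicted).
#'
#' @export
setClass("ProbeResult",
         representation(accuracy = "numeric", ciLow = "numeric",
                        ciHigh = "numeric", kappaMean = "numeric",
                        perClassAccuracy = "numeric", confusion = "matrix",
                        nTrain = "integer", nTest = "integer",
                        nClasses = "integer", seed = "integer",
                        provenance = "list"))

setValidity("ProbeResult", function(object) {
  if (object@accuracy < 0 || object@accuracy > 1)
    return("accuracy out of [0,1]")
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
      (object@ciLow > object@ciHigh))
    return("ciLow > ciHigh")
  if (any(object@confusion < 0) ||
      any(object@confusion != round(object@confusion)))
    return("confusion entries must be non-negative integers")
  if (sum(object@confusion) != object@nTest)
    return("confusion must sum to nTest")
  if (!is.na(object@kappaMean) && object@kappaMean > 1 + 1e-12)
    return("kappaMean > 1")
  TRUE
})

#' ProjectorParams: 2-D projection settings
#'
#' \code{method} is either \code{"neighbor_embedding"} (delegates to a
#' runtime-registered reducer such as UMAP, honouring \code{nNeighbors},
#' \code{minDist} and \code{seed}) or \code{"linear_fallback"} (built-in
#' deterministic projection onto the top two principal directions).
#' Defaults \code{nNeighbors = 15} and \code{minDist = 0.1} are the usual
#' neighbour-embedding starting points; \code{sampleSizes} defaults to one
#' small sample (10000) for local patterns and one large (70000) for global
#' ones.
#'
#' @export
setClass("ProjectorParams",
         representation(method = "character", nNeighbors = "integer",
                        minDist = "numeric", seed = "integer",
                        sampleSizes = "integer"),
         prototype(method = "linear_fallback", nNeighbors = 15L,
                   minDist = 0.1, seed = 0L,
                   sampleSizes = c(10000L, 70000L)))

setValidity("ProjectorParams", function(object) {
  if (!object@method %in% c("neighbor_embedding", "linear_fallback"))
    return("method must be 'neighbor_embedding' or 'linear_fallback'")
  if (object@nNeighbors < 2L) return("nNeighbors must be >= 2")
  if (object@minDist < 0) return("minDist must be >= 0")
  if (any(object@sampleSizes < 1L)) return("sampleSizes must be positive")
  TRUE
})

#' ProjectionResult: 2-D coordinates for a set of items
#'
#' Rows of \code{coords} align with \code{ids}; \code{sourceHash} is a
#' digest of the input features so a projection can be matched back to the
#' embeddings that produced it.
#'
#' @export
setClass("ProjectionResult",
         representation(ids = "character", coords = "matrix",
                        params = "ProjectorParams", sourceHash = "character"))

setValidity("ProjectionResult", function(object) {
  if (nrow(object@coords) != length(object@ids))
    return("coords rows must match ids")
  if (ncol(object@coords) != 2L) return("coords must have 2 columns")
  if (any(!is.finite(object@coords))) return("coords must be finite")
  TRUE
})

#' StructureScores: separation and structure-preservation of a projection
#'
#' Bundles the four scores computed for one projection: mean silhouette
#' width of the label classes in the 2-D plane, adjusted Rand index between
#' a k-means partition of the plane and the labels, mean k-nearest-neighbour
#' preservation between the high- and low-dimensional spaces, and the
#' Spearman correlation of pairwise distances (CPD).
#'
#' @export
setClass("StructureScores",
         representation(silhouette = "numeric", ari = "numeric",
                        knnPreservation = "numeric", cpd = "numeric",
                        kUsed = "integer", nScored = "integer",
                        subsampleSeed = "integer"))

setValidity("StructureScores", function(object) {
  rng <- function(x, lo, hi) !is.na(x) && (x < lo - 1e-9 || x > hi + 1e-9)
  if (rng(object@silhouette, -1, 1)) return("silhouette out of [-1,1]")
  if (rng(object@ari, -1, 1)) return("ari out of [-1,1]")
  if (rng(object@knnPreservation, 0, 1)) return("knnPreservation out of [0,1]")
  if (rng(object@cpd, -1, 1)) return("cpd out of [-1,1]")
  if (object@kUsed >= object@nScored) return("kUsed must be < nScored")
  TRUE
})

#' SyntheticConfig: generative settings for synthetic embeddings
#'
#' Emulates the multi-site, multi-stage, patient/slide hierarchy of a
#' whole-slide-image cohort: 5 sites and 3 stage classes by default.
#' Each item's feature vector is
#' \code{classSep * mu_class + delta * v_site + sigma * noise} with fixed
#' orthonormal class and site directions, so \code{delta} is a directly
#' controllable batch-effect magnitude and \code{delta / sigma} the
#' signal-to-noise ratio of the site signal.
#'
#' @export
setClass("SyntheticConfig",
         representation(nSites = "integer", nClasses = "integer", d = "integer",
                        patientsPerSite = "integer", slidesPerPatient = "integer",
                        tilesPerSlide = "integer", delta = "numeric",
                        sigma = "numeric", classSep = "numeric", seed = "integer"),
         prototype(nSites = 5L, nClasses = 3L, d = 64L, patientsPerSite = 10L,
                   slidesPerPatient = 2L, tilesPerSlide = 10L, delta = 1,
                   sigma = 1, classSep = 1, seed = 0L))

setValidity("SyntheticConfig", function(object) {
  if (object@d < object@nClasses + object@nSites)
    return(sprintf("d (%d) must be >= nClasses + nSites (%d)",
                   object@d, object@nClasses + object@nSites))
  if (object@delta < 0) return("delta must be >= 0")
  if (object@sigma <= 0) return("sigma must be > 0")
  if (object@classSep < 0) return("classSep must be >= 0")
  if (min(object@nSites, object@nClasses, object@patientsPerSite,
          object@slidesPerPatient, object@tilesPerSlide) < 1L)
    return("hierarchy sizes must be positive")
  TRUE
})

#' TileGrid: tessellation of a slide into fixed-size tiles
#'
#' Tile origins (0-based, top-left) on a regular grid with stride
#' \code{round(tileSide * (1 - overlap))}; partial edge tiles are dropped
#' so every tile fits fully inside the slide.
#'
#' @export
setClass("TileGrid",
         representation(slideId = "character", tileSide = "integer",
                        overlap = "numeric", origins = "matrix"))

setValidity("TileGrid", function(object) {
  if (object@tileSide < 1L) return("tileSide must be >= 1")
  if (object@overlap < 0 || object@overlap >= 1)
    return("overlap must be in [0, 1)")
  if (round(object@tileSide * (1 - object@overlap)) < 1)
    return("stride must be >= 1")
  if (ncol(object@origins) != 2L) return("origins must have 2 columns")
  TRUE
})

#' SplitAssignment: a grouped train/validation/test partition
#'
#' Maps every item id to one of \code{train}, \code{validation},
#' \code{test}, with the guarantee that all items of one grouping unit
#' (by default the patient) share a split.
#'
#' @export
setClass("SplitAssignment",
         representation(assignments = "character", fractions = "numeric",
                        unit = "character"))

setValidity("SplitAssignment", function(object) {
  if (is.null(names(object@assignments)))
    return("assignments must be named by item id")
  if (!all(object@assignments %in% c("train", "validation", "test")))
    return("splits must be train/validation/test")
  if (length(object@fractions) != 3L) return("fractions must have length 3")
  if (abs(sum(object@fractions) - 1) > 1e-9) return("fractions must sum to 1")
  TRUE
})

#' InspectionPolicy: when and how to inspect a training loop
#'
#' Run an inspection every \code{everyN} epochs on the validation
#' embeddings the host loop provides: train a light linear probe per
#' variable (and optionally project + score), append a metric record, and
#' signal an early stop when \code{stopRule} — a list
#' \code{(variable, comparator, threshold)} with comparator \code{"above"}
#' or \code{"below"} — is met by the probe accuracy.
#'
#' @export
setClass("InspectionPolicy",
         representation(everyN = "integer", variables = "list",
                        probeConfig = "ProbeConfig",
                        projectorParams = "ANY", stopRule = "listOrNULL",
                        unitVar = "character"),
         prototype(everyN = 20L, projectorParams = NULL, stopRule = NULL,
                   unitVar = "patient"))

setValidity("InspectionPolicy", function(object) {
  if (object@everyN < 1L) return("everyN must be >= 1")
  if (!length(object@variables)) return("at least one variable is required")
  if (!all(vapply(object@variables, is, logical(1), "VariableSpec")))
    return("variables must be VariableSpec objects")
  if (!is.null(object@stopRule)) {
    sr <- object@stopRule
    if (!all(c("variable", "comparator", "threshold") %in% names(sr)))
      return("stopRule needs variable, comparator, threshold")
    if (!sr$comparator %in% c("above", "below"))
      return("stopRule comparator must be 'above' or 'below'")
    if (sr$threshold < 0 || sr$threshold > 1)
      return("stopRule threshold must be in [0, 1]")
  }
  TRUE
})

#' ReportBundle: everything one interactive report needs
#'
#' Projections with their structure scores, optional raw-pixel companion
#' projections, probe results, per-item labels for every metadata variable
#' of interest, and a class colour palette.
#'
#' @export
setClass("ReportBundle",
         representation(projections = "list", scores = "list",
                        probeResults = "list", variable = "VariableSpec",
                        labels = "list", palette = "character",
                        rawProjections = "list"))

setValidity("ReportBundle", function(object) {
  if (!length(object@projections)) return("bundle needs >= 1 projection")
  if (length(object@scores) != length(object@projections))
    return("every projection needs a matching score entry")
  if (!all(vapply(object@projections, is, logical(1), "ProjectionResult")))
    return("projections must be ProjectionResult objects")
  if (!all(vapply(object@scores, is, logical(1), "StructureScores")))
    return("scores must be StructureScores objects")
  if (!length(object@labels)) return("per-item labels are required")
  lv <- object@labels[[object@variable@name]]
  if (is.null(lv)) return("labels must cover the bundle variable")
  if (!all(unique(lv) %in% names(object@palette)))
    return("palette must cover all classes of the bundle variable")
  TRUE
})
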