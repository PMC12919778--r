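#' @include probe.R
NULL

#' @rdname InspectionPolicy-class
#' @param everyN Inspect every N epochs (default 20).
#' @param variables List of \linkS4class{VariableSpec} (or names) to probe.
#' @param probeConfig Probe settings; the in-loop defaults are lighter
#'   (5 epochs, 25 bootstrap resamples) to bound per-checkpoint cost, with
#'   batches of 32 so that a validation-sized embedding set still yields
#'   enough optimiser steps per epoch.
#' @param projectorParams Optional \linkS4class{ProjectorParams}; when
#'   given, each inspection also projects and scores the embeddings.
#' @param stopRule Optional early-stop rule:
#'   \code{list(variable=, comparator="above"|"below", threshold=)} on the
#'   probe accuracy of \code{variable}.
#' @param unitVar Grouping variable for the internal probe split.
#' @export
inspectionPolicy <- function(everyN = 20L, variables,
                             probeConfig = featurelens::probeConfig(
                               epochs = 5L, batchSize = 32L, nBootstrap = 25L),
                             projectorParams = NULL, stopRule = NULL,
                             unitVar = "patient") {
  variables <- lapply(variables, function(v)
    if (is(v, "VariableSpec")) v else variableSpec(v))
  new("InspectionPolicy", everyN = as.integer(everyN), variables = variables,
      probeConfig = probeConfig, projectorParams = projectorParams,
      stopRule = stopRule, unitVar = unitVar)
}

#' Training-loop inspection hook
#'
#' Call at the end of every epoch with the validation embeddings the host
#' loop just produced. On epochs that are multiples of the policy's
#' \code{everyN}, the hook splits the embeddings by the policy's unit
#' variable (70/15/15 greedy unit-disjoint split; the probe trains on the
#' train portion and is evaluated on the rest), probes every policy
#' variable, optionally projects and scores, appends a metric record to
#' the history, and returns \code{action = "stop"} iff the stop rule is
#' met. On all other epochs the history is returned unchanged with
#' \code{action = "continue"}. The hook never mutates its inputs.
#'
#' @param epoch Current epoch (>= 1).
#' @param embeddings Validation \linkS4class{EmbeddingSet}.
#' @param policy An \linkS4class{InspectionPolicy}.
#' @param history List of previous metric records.
#' @return \code{list(history=, action="continue"|"stop")}; each appended
#'   record is \code{list(epoch, variables=, scores=, timestamp)} with one
#'   accuracy/CI/kappa summary per variable.
#' @export
onEpochEnd <- function(epoch, embeddings, policy, history = list()) {
  stopifnot(is(embeddings, "EmbeddingSet"), is(policy, "InspectionPolicy"),
            epoch >= 1L)
  if (epoch %% policy@everyN != 0L)
    return(list(history = history, action = "continue"))
  md <- colnames(itemMeta(embeddings))
  for (v in policy@variables)
    if (!v@name %in% md)
      flensError(sprintf("variable '%s' missing from embeddings", v@name))
  cfg <- policy@probeConfig
  cfg@seed <- as.integer((cfg@seed + epoch) %% .Machine$integer.max)
  split <- patientDisjointSplit(embeddings, unitVar = policy@unitVar,
                                seed = cfg@seed)
  trainSet <- splitItems(embeddings, split, "train")
  testSet <- splitItems(embeddings, split, c("validation", "test"))

  summaries <- list()
  action <- "continue"
  for (v in policy@variables) {
    model <- trainProbe(trainSet, v, cfg)
    res <- evaluateProbe(model, testSet, v, cfg)
    summaries[[v@name]] <- list(accuracy = res@accuracy, ciLow = res@ciLow,
                                ciHigh = res@ciHigh,
                                kappaMean = res@kappaMean,
                                nTest = res@nTest)
    sr <- policy@stopRule
    if (!is.null(sr) && identical(sr$variable, v@name)) {
      hit <- if (sr$comparator == "above") res@accuracy > sr$threshold
             else res@accuracy < sr$threshold
      if (hit) action <- "stop"
    }
  }
  scores <- NULL
  if (!is.null(policy@projectorParams)) {
    proj <- projectEmbeddings(embeddings, policy@projectorParams)
    sc <- scoreProjection(embeddings, proj, policy@variables[[1]],
                          k = policy@projectorParams@nNeighbors,
                          seed = cfg@seed)
    scores <- list(silhouette = sc@silhouette, ari = sc@ari,
                   knnPreservation = sc@knnPreservation, cpd = sc@cpd)
  }
  record <- list(epoch = epoch, variables = summaries, scores = scores,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  list(history = c(history, list(record)), action = action)
}

#' Write / read a metric history as JSON lines
#'
#' One JSON object per line, append-safe: re-running a loop can
#' concatenate files without any framing.
#'
#' @param history List of metric records (as produced by [onEpochEnd()]).
#' @param path Destination file.
#' @return \code{path}, invisibly.
#' @export
writeHistory <- function(history, path) {
  lines <- vapply(history, function(rec)
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 10,
                                  null = "null", na = "null")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeHistory
#' @export
readHistory <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
}
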