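# Accessors and show methods.

#' @rdname SourceSpace-class
#' @export
setMethod("nSources", "SourceSpace", function(x) x@nSources)

#' @rdname SourceSpace-class
#' @export
setMethod("adjacency", "SourceSpace", function(x) x@edges)

#' @rdname SourceSpace-class
#' @export
setMethod("regionMask", "SourceSpace", function(x, name) {
  if (!name %in% names(x@regionMasks))
    stop(sprintf("no region mask named '%s'", name))
  x@regionMasks[[name]]
})

#' @rdname SourceSpace-class
#' @export
setMethod("regionMasks", "SourceSpace", function(x) x@regionMasks)

#' @export
#' @rdname timeAxis
setMethod("timeAxis", "SourceSpace", function(x)
  c(startMs = x@timeStartMs, stepMs = x@timeStepMs))

#' @export
#' @rdname timeAxis
setMethod("timeAxis", "TrialTensor", function(x)
  c(startMs = x@timeStartMs, stepMs = x@timeStepMs))

#' @rdname TrialTensor-class
#' @export
setMethod("trialData", "TrialTensor", function(x) x@data)

#' @rdname TrialTensor-class
#' @export
setMethod("conditions", "TrialTensor", function(x) x@condition)

#' @rdname TrialTensor-class
#' @export
setMethod("covariates", "TrialTensor", function(x)
  data.frame(word1LogFreq = x@word1LogFreq, word2LogFreq = x@word2LogFreq))

#' @rdname TrialTensor-class
#' @export
setMethod("subjectId", "TrialTensor", function(x) x@subjectId)

#' @rdname StatResult-class
#' @export
setMethod("statMap", "StatResult", function(x) x@stat)

#' @rdname StatResult-class
#' @export
setMethod("tfceMap", "StatResult", function(x) x@tfce)

#' @rdname StatResult-class
#' @export
setMethod("pValues", "StatResult", function(x) x@p)

#' @rdname significantPoints
#' @export
setMethod("significantPoints", "StatResult", function(x, alpha = 0.05) {
  x@p <= alpha
})

#' @rdname BetaStack-class
#' @export
setMethod("predictors", "BetaStack", function(x) x@predictors)

setMethod("show", "SourceSpace", function(object) {
  cat(sprintf("SourceSpace: %d sources, %d edges\n", object@nSources,
              nrow(object@edges)))
  if (length(object@regionMasks)) {
    sizes <- vapply(object@regionMasks, length, integer(1))
    cat("  region masks:",
        paste(sprintf("%s (%d)", names(sizes), sizes), collapse = ", "), "\n")
  }
  cat(sprintf("  default time axis: start %g ms, step %g ms\n",
              object@timeStartMs, object@timeStepMs))
})

setMethod("show", "TrialTensor", function(object) {
  d <- dim(object@data)
  cat(sprintf("TrialTensor '%s': %d trials x %d sources x %d samples\n",
              object@subjectId, d[1], d[2], d[3]))
  tb <- table(object@condition)
  cat("  conditions:",
      paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = ", "), "\n")
  cat(sprintf("  time: %g..%g ms, step %g ms\n", object@timeStartMs,
              object@timeStartMs + (d[3] - 1) * object@timeStepMs,
              object@timeStepMs))
})

setMethod("show", "BetaStack", function(object) {
  d <- dim(object@beta)
  cat(sprintf("BetaStack: %d subjects x %d predictors x %d sources x %d times\n",
              d[1], d[2], d[3], d[4]))
  cat("  predictors:", paste(object@predictors, collapse = ", "), "\n")
})

setMethod("show", "StatResult", function(object) {
  cat(sprintf("StatResult: %d x %d grid, %s, %d permutations\n",
              nrow(object@stat), ncol(object@stat), object@tail,
              object@nPermutations))
  sig <- sum(object@p <= 0.05)
  cat(sprintf("  min p = %.4g; %d points with p <= 0.05\n", min(object@p), sig))
})

setMethod("show", "RDMSeries", function(object) {
  cat(sprintf("RDMSeries '%s': %d item pairs x %d times (%d items)\n",
              object@region, nrow(object@rdm), ncol(object@rdm),
              length(object@itemLabels)))
})

setMethod("show", "FlowGrid", function(object) {
  cat(sprintf("FlowGrid %s -> %s: %d lags x %d times\n", object@direction[1],
              object@direction[2], nrow(object@pc), ncol(object@pc)))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d planted effects, %d couplings%s\n",
              length(object@effects), length(object@couplings),
              if (isTRUE(object@overlapFlag)) " (overlapping windows)" else ""))
})

setMethod("show", "AccuracyMap", function(object) {
  d <- dim(object@accuracy)
  cat(sprintf("AccuracyMap %s vs %s: %d subjects x %d x %d centers (mean %.3f)\n",
              object@pair[1], object@pair[2], d[1], d[2], d[3],
              mean(object@accuracy)))
})
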