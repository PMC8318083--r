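# User-facing constructors (validity-checked).

#' Construct a SourceSpace
#'
#' @param edges two-column matrix of 1-based undirected edges.
#' @param nSources number of sources.
#' @param regionMasks named list of integer source-index vectors.
#' @param timeStartMs,timeStepMs default time-axis metadata (ms).
#' @return a \code{\linkS4class{SourceSpace}}.
#' @export
sourceSpace <- function(nSources, edges, regionMasks = list(),
                        timeStartMs = -100, timeStepMs = 1) {
  new("SourceSpace", nSources = as.integer(nSources),
      edges = matrix(as.integer(edges), ncol = 2L),
      regionMasks = lapply(regionMasks, function(m) sort(as.integer(m))),
      timeStartMs = timeStartMs, timeStepMs = timeStepMs)
}

#' Rectangular-lattice source space
#'
#' Builds a 4-connected nrow x ncol lattice as a stand-in cortical sheet
#' (sources numbered column-major), with optional rectangular region masks.
#'
#' @param nrow,ncol lattice dimensions.
#' @param regions named list of \code{c(rowMin, rowMax, colMin, colMax)}
#'   rectangles converted to source-index masks.
#' @param timeStartMs,timeStepMs time-axis metadata.
#' @return a \code{\linkS4class{SourceSpace}}.
#' @export
latticeSourceSpace <- function(nrow, ncol, regions = list(),
                               timeStartMs = -100, timeStepMs = 1) {
  idx <- function(r, c) (c - 1L) * nrow + r
  e <- list()
  for (c in seq_len(ncol)) {
    if (nrow > 1L)
      e[[length(e) + 1L]] <- cbind(idx(seq_len(nrow - 1L), c),
                                   idx(seq_len(nrow - 1L) + 1L, c))
    if (c < ncol)
      e[[length(e) + 1L]] <- cbind(idx(seq_len(nrow), c),
                                   idx(seq_len(nrow), c + 1L))
  }
  edges <- do.call(rbind, e)
  masks <- lapply(regions, function(rc) {
    as.integer(outer(rc[1]:rc[2], rc[3]:rc[4], idx))
  })
  sourceSpace(nrow * ncol, edges, masks, timeStartMs, timeStepMs)
}

#' @rdname TFCEParams-class
#' @param E,H,dh,h0 see slots.
#' @export
tfceParams <- function(E = 0.5, H = 2, dh = NA_real_, h0 = 0) {
  new("TFCEParams", E = E, H = H, dh = dh, h0 = h0)
}

#' @rdname DesignSpec-class
#' @param nSubjects,trialsPerCondition,epochStartMs,epochEndMs,sampleRateHz,word2OnsetMs
#'   see slots.
#' @export
designSpec <- function(nSubjects = 21L, trialsPerCondition = 60L,
                       epochStartMs = -100, epochEndMs = 1200,
                       sampleRateHz = 1000, word2OnsetMs = 600) {
  new("DesignSpec", nSubjects = as.integer(nSubjects),
      trialsPerCondition = as.integer(trialsPerCondition),
      conditions = CONDITION_LEVELS, epochStartMs = epochStartMs,
      epochEndMs = epochEndMs, sampleRateHz = sampleRateHz,
      word2OnsetMs = word2OnsetMs)
}

#' @rdname PlantedEffect-class
#' @param predictorName,regionMask,windowMs,amplitude,effectForm,patternSeed
#'   see slots.
#' @export
plantedEffect <- function(predictorName, regionMask, windowMs, amplitude,
                          effectForm = c("univariate-amplitude",
                                         "multivariate-pattern"),
                          patternSeed = 1L) {
  new("PlantedEffect", predictorName = predictorName,
      regionMask = as.integer(regionMask), windowMs = as.numeric(windowMs),
      amplitude = amplitude, effectForm = match.arg(effectForm),
      patternSeed = as.integer(patternSeed))
}

#' @rdname CouplingSpec-class
#' @param sourceRegion,targetRegion,lagMs,gain,windowMs see slots.
#' @export
couplingSpec <- function(sourceRegion, targetRegion, lagMs, gain,
                         windowMs) {
  new("CouplingSpec", sourceRegion = sourceRegion,
      targetRegion = targetRegion, lagMs = lagMs, gain = gain,
      windowMs = as.numeric(windowMs))
}

#' @rdname NoiseSpec-class
#' @param sensorSd,spatialCorrLength,subjectSd,temporalSmoothingMs see slots.
#' @export
noiseSpec <- function(sensorSd = 1, spatialCorrLength = 2, subjectSd = 0.2,
                      temporalSmoothingMs = 20) {
  new("NoiseSpec", sensorSd = sensorSd, spatialCorrLength = spatialCorrLength,
      subjectSd = subjectSd, temporalSmoothingMs = temporalSmoothingMs)
}

#' @rdname AssociationParams-class
#' @param highThreshold,lowThreshold,nPcs see slots.
#' @export
associationParams <- function(highThreshold = 0.3, lowThreshold = 0.15,
                              nPcs = 30L) {
  new("AssociationParams", highThreshold = highThreshold,
      lowThreshold = lowThreshold, nPcs = as.integer(nPcs))
}

#' Construct a TrialTensor
#'
#' @param data numeric array \[trial, source, time\].
#' @param condition per-trial labels from \code{\link{CONDITION_LEVELS}}.
#' @param word1LogFreq,word2LogFreq per-trial log10 frequencies.
#' @param subjectId subject label.
#' @param timeStartMs,timeStepMs time axis.
#' @return a \code{\linkS4class{TrialTensor}}.
#' @export
trialTensor <- function(data, condition, word1LogFreq, word2LogFreq,
                        subjectId, timeStartMs = -100, timeStepMs = 1) {
  new("TrialTensor", data = data, condition = as.character(condition),
      word1LogFreq = as.numeric(word1LogFreq),
      word2LogFreq = as.numeric(word2LogFreq),
      subjectId = as.character(subjectId), timeStartMs = timeStartMs,
      timeStepMs = timeStepMs)
}

#' Mask-restricted spatial adjacency
#'
#' Induced subgraph of a source space's adjacency on a mask, re-indexed to
#' 1..length(mask) — the edge set that masked-grid results (e.g. from
#' \code{\link{secondStage}}) are defined over.
#'
#' @param space a \code{SourceSpace} (or a two-column edge matrix).
#' @param mask integer source indices.
#' @return two-column integer edge matrix over mask positions.
#' @export
maskedEdges <- function(space, mask) {
  edges <- if (is(space, "SourceSpace")) space@edges else space
  induced_edges(edges, sort(as.integer(mask)))
}

#' Graph neighborhood of the k nearest sources
#'
#' Breadth-first hop-distance neighborhood used by the searchlight: the
#' \code{k} sources nearest to \code{center} (including it), expanding one hop
#' at a time; when the final hop ring overshoots \code{k}, ties are broken by
#' ascending source index.
#'
#' @param space a \code{SourceSpace} (or adjacency list).
#' @param center 1-based source index.
#' @param k neighborhood size.
#' @return sorted integer vector of \code{min(k, reachable)} source indices.
#' @export
graphNeighborhood <- function(space, center, k) {
  adj <- if (is(space, "SourceSpace"))
    adjacency_list(space@edges, space@nSources) else space
  visited <- rep(FALSE, length(adj))
  visited[center] <- TRUE
  out <- center
  frontier <- center
  while (length(out) < k && length(frontier) > 0L) {
    nxt <- sort(unique(unlist(adj[frontier])))
    nxt <- nxt[!visited[nxt]]
    if (length(nxt) == 0L) break
    visited[nxt] <- TRUE
    room <- k - length(out)
    out <- c(out, if (length(nxt) > room) nxt[seq_len(room)] else nxt)
    frontier <- nxt
  }
  sort(out)
}
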