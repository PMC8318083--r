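# Core S4 containers.  Data objects carry their own grid metadata so every
# downstream stage can check congruence instead of trusting call order.

#' Condition labels of the two-word design
#'
#' The five cells of the 2 x 2 (association high/low x composition
#' phrase/list) design plus the single-word visual baseline, in canonical
#' order.
#' @export
CONDITION_LEVELS <- c("HA-comp", "LA-comp", "HA-list", "LA-list", "single")

TWO_WORD_CONDITIONS <- c("HA-comp", "LA-comp", "HA-list", "LA-list")

#' @title Source-space description
#'
#' @description Undirected source adjacency graph with named region masks and
#' default time-axis metadata; the spatial scaffold shared by simulation,
#' regression, decoding and connectivity.
#'
#' @slot nSources number of sources.
#' @slot edges two-column integer matrix of 1-based undirected edges.
#' @slot regionMasks named list of integer source-index vectors (analysis
#'   mask, fROIs, control regions).
#' @slot timeStartMs,timeStepMs default epoch start and sample step (ms).
#' @export
setClass("SourceSpace",
  representation(nSources = "integer", edges = "matrix",
                 regionMasks = "list", timeStartMs = "numeric",
                 timeStepMs = "numeric"),
  prototype(nSources = 0L, edges = matrix(integer(0), ncol = 2L),
            regionMasks = list(), timeStartMs = -100, timeStepMs = 1),
  validity = function(object) {
    msg <- character(0)
    e <- object@edges
    if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
    if (nrow(e) > 0L) {
      if (any(e < 1L) || any(e > object@nSources))
        msg <- c(msg, "edges reference invalid source indices")
      if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-loops not allowed")
    }
    for (nm in names(object@regionMasks)) {
      m <- object@regionMasks[[nm]]
      if (any(m < 1L) || any(m > object@nSources))
        msg <- c(msg, sprintf("mask '%s' outside the source space", nm))
    }
    if (object@timeStepMs <= 0) msg <- c(msg, "timeStepMs must be positive")
    if (length(msg)) msg else TRUE
  })

#' @title Trial-level source estimates for one subject
#'
#' @description Dense trials x sources x time tensor of source-amplitude
#' estimates (arbitrary dSPM-like units) with per-trial condition labels and
#' word-frequency covariates.
#'
#' @slot data numeric array \[trial, source, time\].
#' @slot condition factor-like character vector, one of
#'   \code{\link{CONDITION_LEVELS}} per trial.
#' @slot word1LogFreq,word2LogFreq per-trial log10 word frequencies.
#' @slot subjectId subject label.
#' @slot timeStartMs,timeStepMs time axis (ms relative to first-word onset;
#'   epoch is half-open \[start, end)).
#' @export
setClass("TrialTensor",
  representation(data = "array", condition = "character",
                 word1LogFreq = "numeric", word2LogFreq = "numeric",
                 subjectId = "character", timeStartMs = "numeric",
                 timeStepMs = "numeric"),
  validity = function(object) {
    msg <- character(0)
    d <- dim(object@data)
    if (length(d) != 3L) msg <- c(msg, "data must be trial x source x time")
    n <- d[1L]
    if (length(object@condition) != n)
      msg <- c(msg, "one condition label per trial required")
    if (!all(object@condition %in% CONDITION_LEVELS))
      msg <- c(msg, "unknown condition labels")
    if (length(object@word1LogFreq) != n || length(object@word2LogFreq) != n)
      msg <- c(msg, "one frequency covariate pair per trial required")
    if (anyNA(object@data)) msg <- c(msg, "missing values not allowed")
    if (object@timeStepMs <= 0) msg <- c(msg, "timeStepMs must be positive")
    if (length(msg)) msg else TRUE
  })

#' @title First-stage regression coefficients across subjects
#'
#' @description Subject x predictor x source x time array of per-subject OLS
#' coefficients on the masked grid, plus the grid bookkeeping (which sources
#' of the parent space, which times).
#'
#' @slot beta numeric array \[subject, predictor, source, time\].
#' @slot predictors predictor names in design-matrix column order.
#' @slot subjects subject labels.
#' @slot sources 1-based indices into the parent \code{SourceSpace}.
#' @slot timesMs time points (ms) of the analysis window.
#' @export
setClass("BetaStack",
  representation(beta = "array", predictors = "character",
                 subjects = "character", sources = "integer",
                 timesMs = "numeric"),
  validity = function(object) {
    d <- dim(object@beta)
    msg <- character(0)
    if (length(d) != 4L)
      msg <- c(msg, "beta must be subject x predictor x source x time")
    else {
      if (d[2L] != length(object@predictors))
        msg <- c(msg, "predictor axis mismatch")
      if (d[1L] != length(object@subjects))
        msg <- c(msg, "subject axis mismatch")
      if (d[3L] != length(object@sources)) msg <- c(msg, "source axis mismatch")
      if (d[4L] != length(object@timesMs)) msg <- c(msg, "time axis mismatch")
    }
    if (!all(is.finite(object@beta))) msg <- c(msg, "beta must be finite")
    if (length(msg)) msg else TRUE
  })

#' @title TFCE parameters
#'
#' @description Exponents and integration step of threshold-free cluster
#' enhancement.  \code{dh = NA} selects the per-map default, max(stat)/100.
#'
#' @slot E extent exponent (default 0.5).
#' @slot H height exponent (default 2).
#' @slot dh integration step (NA for per-map automatic).
#' @slot h0 threshold origin (default 0).
#' @export
setClass("TFCEParams",
  representation(E = "numeric", H = "numeric", dh = "numeric", h0 = "numeric"),
  prototype(E = 0.5, H = 2, dh = NA_real_, h0 = 0),
  validity = function(object) {
    msg <- character(0)
    if (object@E < 0 || object@H < 0) msg <- c(msg, "E and H must be >= 0")
    if (!is.na(object@dh) && object@dh <= 0) msg <- c(msg, "dh must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @title Statistic map with TFCE scores and permutation p-values
#'
#' @description Result of a permutation test on a grid: the observed statistic
#' map, its TFCE enhancement, and p-values (max-statistic family-wise by
#' default).  Grids are matrices; rows are sources (or lags), columns time.
#'
#' @slot stat,tfce,p congruent numeric matrices.
#' @slot nPermutations number of random permutations.
#' @slot tail \code{"two-sided"} or \code{"one-sided-positive"}.
#' @slot rowValues,colValues grid coordinates (source indices / lag ms; time ms).
#' @slot meta named list: predictor/pair, params, seed, correction, etc.
#' @export
setClass("StatResult",
  representation(stat = "matrix", tfce = "matrix", p = "matrix",
                 nPermutations = "integer", tail = "character",
                 rowValues = "numeric", colValues = "numeric", meta = "list"),
  validity = function(object) {
    msg <- character(0)
    if (!all(dim(object@stat) == dim(object@tfce)) ||
        !all(dim(object@stat) == dim(object@p)))
      msg <- c(msg, "stat/tfce/p grids must be congruent")
    if (any(object@p < 0 | object@p > 1)) msg <- c(msg, "p outside [0, 1]")
    if (object@nPermutations < 1L) msg <- c(msg, "at least one permutation")
    if (!object@tail %in% c("two-sided", "one-sided-positive"))
      msg <- c(msg, "unknown tail")
    if (length(msg)) msg else TRUE
  })

#' @title Time-resolved representational dissimilarity series
#'
#' @description Per-region, per-time vectors of pairwise dissimilarities
#' (1 - Pearson correlation between item patterns over the region's sources).
#'
#' @slot region region label.
#' @slot rdm numeric matrix \[item pair, time\], entries in \[0, 2\].
#' @slot itemLabels ordered item labels; pairs are ordered as
#'   (1,2), (1,3), ..., (n-1,n) (column-major lower triangle).
#' @slot timesMs time points (ms).
#' @export
setClass("RDMSeries",
  representation(region = "character", rdm = "matrix", itemLabels = "character",
                 timesMs = "numeric"),
  validity = function(object) {
    msg <- character(0)
    n <- length(object@itemLabels)
    if (nrow(object@rdm) != n * (n - 1L) / 2L)
      msg <- c(msg, "rdm rows must equal n_items*(n_items-1)/2")
    if (ncol(object@rdm) != length(object@timesMs))
      msg <- c(msg, "time axis mismatch")
    if (any(object@rdm < -1e-8 | object@rdm > 2 + 1e-8, na.rm = TRUE))
      msg <- c(msg, "dissimilarities must lie in [0, 2]")
    if (length(msg)) msg else TRUE
  })

#' @title Lagged partial-correlation flow grid
#'
#' @description Directed-connectivity surface: partial correlation of the
#' source region's past RDM with the target region's current RDM, partialling
#' out the target's past, over a (lag dt) x (current time t) grid.
#'
#' @slot pc numeric matrix \[dt, t\] of partial correlations.
#' @slot dtMs,tMs lag and current-time axes (ms).
#' @slot direction character(2): (source region, target region).
#' @export
setClass("FlowGrid",
  representation(pc = "matrix", dtMs = "numeric", tMs = "numeric",
                 direction = "character"),
  validity = function(object) {
    msg <- character(0)
    if (nrow(object@pc) != length(object@dtMs) ||
        ncol(object@pc) != length(object@tMs))
      msg <- c(msg, "pc grid does not match dt/t axes")
    if (any(abs(object@pc) > 1 + 1e-8, na.rm = TRUE))
      msg <- c(msg, "partial correlations outside [-1, 1]")
    if (length(object@direction) != 2L)
      msg <- c(msg, "direction must be (source, target)")
    if (length(msg)) msg else TRUE
  })

#' @title Experimental design specification
#'
#' @description The two-word design the generator emulates: five conditions,
#' epoch \[-100, 1200) ms at 1000 Hz, second word at 600 ms.
#' @slot nSubjects,trialsPerCondition counts.
#' @slot conditions condition labels (fixed set).
#' @slot epochStartMs,epochEndMs,sampleRateHz,word2OnsetMs timing.
#' @export
setClass("DesignSpec",
  representation(nSubjects = "integer", trialsPerCondition = "integer",
                 conditions = "character", epochStartMs = "numeric",
                 epochEndMs = "numeric", sampleRateHz = "numeric",
                 word2OnsetMs = "numeric"),
  prototype(nSubjects = 21L, trialsPerCondition = 60L,
            conditions = CONDITION_LEVELS, epochStartMs = -100,
            epochEndMs = 1200, sampleRateHz = 1000, word2OnsetMs = 600),
  validity = function(object) {
    msg <- character(0)
    if (!(object@epochStartMs < object@word2OnsetMs &&
          object@word2OnsetMs < object@epochEndMs))
      msg <- c(msg, "need epochStartMs < word2OnsetMs < epochEndMs")
    if (object@trialsPerCondition < 2L)
      msg <- c(msg, "trialsPerCondition must be >= 2")
    if (!setequal(object@conditions, CONDITION_LEVELS))
      msg <- c(msg, "all five condition labels must be present")
    if (object@sampleRateHz <= 0) msg <- c(msg, "sampleRateHz must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @title Planted effect for the synthetic generator
#'
#' @description A ground-truth signal: either a univariate amplitude tied to a
#' design-matrix predictor, a multivariate pattern difference for a condition
#' pair (\code{"A_vs_B"}), or per-condition drifting patterns
#' (\code{"condition-patterns"}) used by the connectivity simulations.
#' @slot predictorName design predictor, \code{"A_vs_B"} pair contrast, or
#'   \code{"condition-patterns"}.
#' @slot regionMask integer source indices.
#' @slot windowMs \[start, end) ms.
#' @slot amplitude signal units.
#' @slot effectForm \code{"univariate-amplitude"} or
#'   \code{"multivariate-pattern"}.
#' @slot patternSeed seed for the pattern field.
#' @export
setClass("PlantedEffect",
  representation(predictorName = "character", regionMask = "integer",
                 windowMs = "numeric", amplitude = "numeric",
                 effectForm = "character", patternSeed = "integer"),
  prototype(effectForm = "univariate-amplitude", patternSeed = 1L),
  validity = function(object) {
    msg <- character(0)
    if (length(object@regionMask) == 0L) msg <- c(msg, "regionMask is empty")
    if (length(object@windowMs) != 2L || object@windowMs[1] >= object@windowMs[2])
      msg <- c(msg, "windowMs must be an increasing pair")
    if (!object@effectForm %in% c("univariate-amplitude", "multivariate-pattern"))
      msg <- c(msg, "unknown effectForm")
    if (length(msg)) msg else TRUE
  })

#' @title Lagged inter-region coupling for the synthetic generator
#'
#' @description Directed dependence: the target region receives a gain-scaled,
#' lag-shifted projection of the source region's signal.
#' @slot sourceRegion,targetRegion region-mask labels.
#' @slot lagMs positive lag (ms).
#' @slot gain dimensionless.
#' @slot windowMs \[start, end) ms window of the copied signal.
#' @export
setClass("CouplingSpec",
  representation(sourceRegion = "character", targetRegion = "character",
                 lagMs = "numeric", gain = "numeric", windowMs = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (object@lagMs <= 0) msg <- c(msg, "lagMs must be > 0")
    if (identical(object@sourceRegion, object@targetRegion))
      msg <- c(msg, "sourceRegion must differ from targetRegion")
    if (length(object@windowMs) != 2L || object@windowMs[1] >= object@windowMs[2])
      msg <- c(msg, "windowMs must be an increasing pair")
    if (length(msg)) msg else TRUE
  })

#' @title Noise specification for the synthetic generator
#'
#' @description Trial noise standard deviation, spatial correlation length
#' (graph-diffusion steps), per-subject amplitude-offset SD, and temporal
#' smoothing (moving-average width, ms).
#' @slot sensorSd,spatialCorrLength,subjectSd,temporalSmoothingMs non-negative.
#' @export
setClass("NoiseSpec",
  representation(sensorSd = "numeric", spatialCorrLength = "numeric",
                 subjectSd = "numeric", temporalSmoothingMs = "numeric"),
  prototype(sensorSd = 1, spatialCorrLength = 2, subjectSd = 0.2,
            temporalSmoothingMs = 20),
  validity = function(object) {
    vals <- c(object@sensorSd, object@spatialCorrLength, object@subjectSd,
              object@temporalSmoothingMs)
    if (any(vals < 0)) "all noise parameters must be non-negative" else TRUE
  })

#' @title Ground truth of a simulated dataset
#'
#' @description Records every planted effect, coupling and frequency-mixing
#' choice of \code{\link{simulateDataset}}, plus a flag for overlapping effect
#' and coupling windows.
#' @slot design the \code{DesignSpec} used.
#' @slot effects,couplings the planted lists.
#' @slot freqEffect frequency-mixing description (list or NULL-list).
#' @slot overlapFlag TRUE if any effect window overlaps a coupling window.
#' @export
setClass("GroundTruth",
  representation(design = "DesignSpec", effects = "list", couplings = "list",
                 freqEffect = "list", overlapFlag = "logical"))

#' @title Searchlight specification
#'
#' @description Neighborhoods for searchlight decoding: the k graph-nearest
#' sources (BFS hop distance, ties broken by source index) by n consecutive
#' decimated time samples centered on each center (edges truncate).
#' @slot nSourcesPerLight,nTimepointsPerLight neighborhood sizes.
#' @slot centerSources source indices of searchlight centers.
#' @slot centerTimesMs center time points (ms).
#' @slot neighborhoods list (per center source) of source-index vectors.
#' @slot sourceStride,timeStride center spacing used to build the grid.
#' @export
setClass("SearchlightSpec",
  representation(nSourcesPerLight = "integer", nTimepointsPerLight = "integer",
                 centerSources = "integer", centerTimesMs = "numeric",
                 neighborhoods = "list", sourceStride = "integer",
                 timeStride = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (object@nSourcesPerLight < 1L || object@nTimepointsPerLight < 1L)
      msg <- c(msg, "neighborhood sizes must be positive")
    if (length(object@neighborhoods) != length(object@centerSources))
      msg <- c(msg, "one neighborhood per center source required")
    if (length(msg)) msg else TRUE
  })

#' @title Searchlight accuracy maps for one condition pair
#'
#' @description Per-subject classification accuracy at every searchlight
#' center, for one pairwise classifier; chance level 0.5.
#' @slot accuracy numeric array \[subject, center source, center time\].
#' @slot pair character(2) condition pair.
#' @slot chance chance level (0.5).
#' @slot spec the \code{SearchlightSpec} used.
#' @slot nReps number of cross-validation repartitions averaged.
#' @export
setClass("AccuracyMap",
  representation(accuracy = "array", pair = "character", chance = "numeric",
                 spec = "SearchlightSpec", nReps = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (length(dim(object@accuracy)) != 3L)
      msg <- c(msg, "accuracy must be subject x center-source x center-time")
    if (any(object@accuracy < 0 | object@accuracy > 1, na.rm = TRUE))
      msg <- c(msg, "accuracy outside [0, 1]")
    if (length(object@pair) != 2L) msg <- c(msg, "pair must have two labels")
    if (length(msg)) msg else TRUE
  })

#' @title Pseudo-trial set
#'
#' @description Block means of a random disjoint partition of each condition's
#' trials (remainder trials assigned round-robin), used to raise SNR before
#' decoding and RDM computation.
#' @slot patterns numeric array \[condition, pseudo-trial, source, time\].
#' @slot conditions condition labels of the first axis.
#' @slot partitionSeed seed that produced the partition.
#' @export
setClass("PseudoTrialSet",
  representation(patterns = "array", conditions = "character",
                 partitionSeed = "integer"),
  validity = function(object) {
    if (length(dim(object@patterns)) != 4L)
      "patterns must be condition x pseudo-trial x source x time"
    else if (dim(object@patterns)[1L] != length(object@conditions))
      "condition axis mismatch"
    else TRUE
  })

#' @title Word-embedding table
#'
#' @description Dense distributional word vectors (GloVe-style), one row per
#' token.
#' @slot vectors numeric matrix with token rownames.
#' @slot sourceTag provenance string.
#' @export
setClass("EmbeddingTable",
  representation(vectors = "matrix", sourceTag = "character"),
  validity = function(object) {
    msg <- character(0)
    if (is.null(rownames(object@vectors)))
      msg <- c(msg, "vectors must have token rownames")
    nrm <- sqrt(rowSums(object@vectors^2))
    if (any(nrm == 0)) msg <- c(msg, "zero-norm vectors are not admitted")
    if (length(msg)) msg else TRUE
  })

#' @title Association-scoring parameters
#'
#' @description Cosine thresholds for the high/low association split and the
#' number of principal components of the reduced-dimension variant.
#' @slot highThreshold cosine above which a pair is "high" (default 0.3).
#' @slot lowThreshold cosine below which a pair is "low" (default 0.15).
#' @slot nPcs principal components retained (default 30).
#' @export
setClass("AssociationParams",
  representation(highThreshold = "numeric", lowThreshold = "numeric",
                 nPcs = "integer"),
  prototype(highThreshold = 0.3, lowThreshold = 0.15, nPcs = 30L),
  validity = function(object) {
    if (object@lowThreshold >= object@highThreshold)
      "lowThreshold must be below highThreshold" else TRUE
  })
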