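# Generics for the shared accessor vocabulary.

#' @rdname SourceSpace-class
#' @param x object.
#' @export
setGeneric("nSources", function(x) standardGeneric("nSources"))

#' @rdname SourceSpace-class
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname SourceSpace-class
#' @param name region-mask label.
#' @export
setGeneric("regionMask", function(x, name) standardGeneric("regionMask"))

#' @rdname SourceSpace-class
#' @export
setGeneric("regionMasks", function(x) standardGeneric("regionMasks"))

#' Time axis of a gridded object
#'
#' @param x object with a time axis.
#' @return named numeric: \code{startMs}, \code{stepMs}.
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))

#' @rdname TrialTensor-class
#' @param x object.
#' @export
setGeneric("trialData", function(x) standardGeneric("trialData"))

#' @rdname TrialTensor-class
#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))

#' @rdname TrialTensor-class
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @rdname TrialTensor-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname StatResult-class
#' @param x object.
#' @export
setGeneric("statMap", function(x) standardGeneric("statMap"))

#' @rdname StatResult-class
#' @export
setGeneric("tfceMap", function(x) standardGeneric("tfceMap"))

#' @rdname StatResult-class
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' Significant grid points of a permutation result
#'
#' @param x a \code{StatResult}.
#' @param alpha significance level (default 0.05).
#' @return logical matrix on the result grid.
#' @export
setGeneric("significantPoints",
           function(x, alpha = 0.05) standardGeneric("significantPoints"))

#' @rdname BetaStack-class
#' @param x object.
#' @export
setGeneric("predictors", function(x) standardGeneric("predictors"))
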