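# Two-stage mass-univariate regression: per-subject OLS at every source and
# time point inside the analysis mask, then a group-level sign-flip TFCE
# permutation test on each predictor's coefficient maps.

DESIGN_PREDICTORS <- c("intercept", "association", "composition",
                       "interaction", "n_words", "word1_logfreq",
                       "word2_logfreq")

#' Build the trial design matrix
#'
#' Codes the 2 x 2 factors as binary variables with the single-word baseline
#' at the origin: association = 1 for high-association conditions,
#' composition = 1 for phrases, interaction their product, n_words = 1 for
#' two-word trials; word-frequency covariates are centered across the
#' subject's trials so condition coefficients are evaluated at mean
#' frequency.  \code{coding = "effect"} recodes the two factors as +/- 0.5
#' (single-word trials stay at 0).
#'
#' @param condition per-trial labels from \code{\link{CONDITION_LEVELS}}.
#' @param word1LogFreq,word2LogFreq per-trial covariates.
#' @param coding \code{"dummy"} (default) or \code{"effect"}.
#' @return numeric matrix with columns \code{intercept, association,
#'   composition, interaction, n_words, word1_logfreq, word2_logfreq};
#'   checked for full column rank.
#' @export
buildDesign <- function(condition, word1LogFreq, word2LogFreq,
                        coding = c("dummy", "effect")) {
  coding <- match.arg(coding)
  if (!all(condition %in% CONDITION_LEVELS)) {
    bad <- setdiff(unique(condition), CONDITION_LEVELS)
    stop(sprintf("unknown condition label(s): %s", paste(bad, collapse = ", ")))
  }
  assoc <- as.numeric(condition %in% c("HA-comp", "HA-list"))
  comp <- as.numeric(condition %in% c("HA-comp", "LA-comp"))
  nw <- as.numeric(condition != "single")
  if (coding == "effect") {
    assoc <- ifelse(nw == 1, assoc - 0.5, 0)
    comp <- ifelse(nw == 1, comp - 0.5, 0)
  }
  X <- cbind(intercept = 1, association = assoc, composition = comp,
             interaction = assoc * comp, n_words = nw,
             word1_logfreq = word1LogFreq - mean(word1LogFreq),
             word2_logfreq = word2LogFreq - mean(word2LogFreq))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; collinear columns: %s",
                 paste(bad, collapse = ", ")))
  }
  X
}

#' First-stage regression for one subject
#'
#' Fits an independent OLS at every (source, time) grid point of the mask and
#' analysis window: one coefficient per design column per point.
#'
#' @param tensor a \code{TrialTensor}.
#' @param X design matrix from \code{\link{buildDesign}} (rows = trials).
#' @param mask integer source indices (non-empty).
#' @param windowMs half-open analysis window \[start, end) in ms.
#' @return numeric array \[predictor, source-in-mask, time-in-window\] with a
#'   \code{timesMs} attribute.
#' @export
firstStage <- function(tensor, X, mask, windowMs) {
  stopifnot(is(tensor, "TrialTensor"))
  mask <- as.integer(mask)
  if (length(mask) == 0L) stop("mask is empty")
  d <- dim(tensor@data)
  if (any(mask < 1L | mask > d[2L])) stop("mask outside the source axis")
  ax <- timeAxis(tensor)
  win <- window_indices(windowMs, ax["startMs"], ax["stepMs"], d[3L])
  if (length(win) == 0L) stop("analysis window outside the epoch")
  if (nrow(X) != d[1L]) stop("design rows must match trials")
  Y <- matrix(tensor@data[, mask, win, drop = FALSE], nrow = d[1L])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; collinear columns: %s",
                 paste(bad, collapse = ", ")))
  }
  B <- qr.coef(qx, Y)
  out <- array(B, c(ncol(X), length(mask), length(win)))
  dimnames(out) <- list(colnames(X), NULL, NULL)
  attr(out, "timesMs") <- time_points(ax["startMs"], ax["stepMs"], d[3L])[win]
  out
}

#' Two-stage mass regression, first stage across subjects
#'
#' Builds each subject's design matrix and runs \code{\link{firstStage}} on
#' the masked grid, stacking coefficients into a
#' \code{\linkS4class{BetaStack}}.
#'
#' @param tensors list of per-subject \code{TrialTensor}s.
#' @param mask integer source indices of the analysis mask.
#' @param windowMs half-open analysis window (ms).
#' @param coding factor coding passed to \code{\link{buildDesign}}.
#' @return a \code{\linkS4class{BetaStack}}.
#' @export
massRegression <- function(tensors, mask, windowMs, coding = "dummy") {
  stopifnot(length(tensors) >= 1L)
  first <- lapply(tensors, function(tt) {
    X <- buildDesign(conditions(tt), tt@word1LogFreq, tt@word2LogFreq,
                     coding = coding)
    firstStage(tt, X, mask, windowMs)
  })
  times <- attr(first[[1L]], "timesMs")
  beta <- array(0, c(length(tensors), dim(first[[1L]])))
  for (s in seq_along(first)) beta[s, , , ] <- first[[s]]
  new("BetaStack", beta = beta, predictors = dimnames(first[[1L]])[[1L]],
      subjects = vapply(tensors, subjectId, character(1)),
      sources = as.integer(mask), timesMs = as.numeric(times))
}

#' Second-stage group test for one predictor
#'
#' One-sample t test of the subject distribution of first-stage coefficients
#' against zero at every grid point, with TFCE and sign-flip max-statistic
#' permutation correction (see \code{\link{permutationTest}}).
#'
#' @param betas a \code{BetaStack}.
#' @param predictor design-column name.
#' @param space the \code{SourceSpace} the stack's sources index into
#'   (adjacency is restricted to the masked sources).
#' @param params \code{\link{tfceParams}}.
#' @param nPerm permutations.
#' @param seed RNG seed.
#' @param tail default \code{"two-sided"} for regression coefficients.
#' @param ... passed to \code{\link{permutationTest}} (e.g. correction,
#'   nullMethod).
#' @return a \code{\linkS4class{StatResult}}; rows are the stack's sources,
#'   columns its time points.
#' @export
secondStage <- function(betas, predictor, space, params = tfceParams(),
                        nPerm = 1000L, seed,
                        tail = c("two-sided", "one-sided-positive"), ...) {
  stopifnot(is(betas, "BetaStack"))
  tail <- match.arg(tail)
  j <- match(predictor, betas@predictors)
  if (is.na(j)) stop(sprintf("predictor '%s' not in the BetaStack", predictor))
  maps <- betas@beta[, j, , , drop = FALSE]
  maps <- array(maps, dim(maps)[c(1L, 3L, 4L)])
  edges <- induced_edges(adjacency(space), betas@sources)
  permutationTest(maps, popmean = 0, edges = edges, params = params,
                  nPerm = nPerm, tail = tail, seed = seed,
                  rowValues = as.numeric(betas@sources),
                  colValues = betas@timesMs,
                  meta = list(predictor = predictor,
                              windowMs = range(betas@timesMs)), ...)
}

#' Summarize significant spatiotemporal clusters
#'
#' Groups significant grid points of a \code{StatResult} into connected
#' components (spatial edges within a time sample, same row across adjacent
#' samples) and reports each component's extent, time window and peak.
#'
#' @param result a \code{StatResult}.
#' @param edges spatial adjacency over the result's rows (edge matrix,
#'   re-indexed as in the result grid), or a \code{SourceSpace} whose
#'   masked/induced edges the caller has prepared.
#' @param alpha significance level.
#' @return data.frame: cluster id, number of points, number of distinct rows,
#'   window start/end (column coordinates), peak statistic, minimum p.
#' @export
significantClusters <- function(result, edges, alpha = 0.05) {
  stopifnot(is(result, "StatResult"))
  if (is(edges, "SourceSpace")) edges <- edges@edges
  sig <- which(result@p <= alpha)
  empty <- data.frame(cluster = integer(0), nPoints = integer(0),
                      nRows = integer(0), windowStart = numeric(0),
                      windowEnd = numeric(0), peakStat = numeric(0),
                      minP = numeric(0))
  if (length(sig) == 0L) return(empty)
  nS <- nrow(result@p); nT <- ncol(result@p)
  el <- list()
  if (nrow(edges) > 0L) {
    for (t in seq_len(nT)) {
      keepi <- (edges[, 1L] + (t - 1L) * nS) %in% sig &
        (edges[, 2L] + (t - 1L) * nS) %in% sig
      if (any(keepi))
        el[[length(el) + 1L]] <- edges[keepi, , drop = FALSE] + (t - 1L) * nS
    }
  }
  if (nT > 1L) {
    a <- sig[sig <= nS * (nT - 1L)]
    a <- a[(a + nS) %in% sig]
    if (length(a)) el[[length(el) + 1L]] <- cbind(a, a + nS)
  }
  g <- igraph::graph_from_data_frame(
    d = if (length(el)) as.data.frame(do.call(rbind, el)) else
      data.frame(from = integer(0), to = integer(0)),
    directed = FALSE, vertices = data.frame(name = sig))
  comp <- igraph::components(g)$membership
  ids <- as.integer(names(comp))
  rows <- (ids - 1L) %% nS + 1L
  cols <- (ids - 1L) %/% nS + 1L
  out <- do.call(rbind, lapply(split(seq_along(ids), comp), function(ii) {
    data.frame(nPoints = length(ii), nRows = length(unique(rows[ii])),
               windowStart = min(result@colValues[cols[ii]]),
               windowEnd = max(result@colValues[cols[ii]]),
               peakStat = result@stat[ids[ii]][which.max(abs(result@stat[ids[ii]]))],
               minP = min(result@p[ids[ii]]))
  }))
  out <- out[order(out$minP, -out$nPoints), , drop = FALSE]
  out <- cbind(cluster = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
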