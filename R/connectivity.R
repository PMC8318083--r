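# RDM-based directed connectivity: time-resolved representational
# dissimilarity matrices per region, lagged partial-correlation flow grids,
# and the direction-contrast permutation test (Granger-style logic: region
# A's past RDM predicting region B's current RDM beyond B's own past).

#' Time-resolved RDM series for one region
#'
#' At each time point the item patterns are the mean source pattern per item
#' over the region (items: the four two-word condition means over
#' pseudo-trials by default, or the individual pseudo-trials), and the RDM
#' entries are 1 minus the pairwise Pearson correlations between item
#' patterns.  Undefined correlations (a constant item pattern) are imputed as
#' dissimilarity 1 (zero correlation) with a warning.
#'
#' @param tensor a preprocessed (frequency-residualized, decimated)
#'   \code{TrialTensor}.
#' @param region integer source indices (>= 3 sources).
#' @param granularity \code{"condition"} (4 items, 6 entries) or
#'   \code{"pseudo-trial"}.
#' @param nPseudo pseudo-trials per condition.
#' @param seed RNG seed for the pseudo-trial partition.
#' @param regionLabel label stored in the result.
#' @return an \code{\linkS4class{RDMSeries}}; pair rows are ordered
#'   (1,2), (1,3), ..., (n-1,n) (column-major lower triangle).
#' @export
computeRDMSeries <- function(tensor, region,
                             granularity = c("condition", "pseudo-trial"),
                             nPseudo = 15L, seed, regionLabel = "region") {
  granularity <- match.arg(granularity)
  region <- as.integer(region)
  if (length(region) < 3L) stop("region needs at least 3 sources")
  items_present <- intersect(TWO_WORD_CONDITIONS, unique(tensor@condition))
  if (length(items_present) < 3L) stop("need at least 3 item conditions")
  ps <- buildPseudoTrialSet(tensor, nPseudo, seed, conditions = items_present)
  arr <- ps@patterns[, , region, , drop = FALSE]
  n_time <- dim(arr)[4L]
  if (granularity == "condition") {
    items <- ps@conditions
    pat <- array(0, c(length(items), length(region), n_time))
    for (ci in seq_along(items))
      pat[ci, , ] <- apply(arr[ci, , , , drop = FALSE], c(3L, 4L), mean)
  } else {
    items <- as.vector(t(outer(ps@conditions, seq_len(nPseudo), paste,
                               sep = ".")))
    pat <- array(aperm(arr, c(2L, 1L, 3L, 4L)),
                 c(length(items), length(region), n_time))
  }
  n_items <- length(items)
  lt <- lower.tri(matrix(0, n_items, n_items))
  rdm <- matrix(0, sum(lt), n_time)
  warned <- FALSE
  for (t in seq_len(n_time)) {
    C <- suppressWarnings(cor(t(pat[, , t])))
    if (anyNA(C)) {
      warned <- TRUE
      C[is.na(C)] <- 0
    }
    rdm[, t] <- 1 - C[lt]
  }
  if (warned)
    warning("constant item pattern(s); undefined dissimilarities imputed as 1")
  new("RDMSeries", region = regionLabel, rdm = pmin(pmax(rdm, 0), 2),
      itemLabels = items, timesMs = tensorTimes(tensor))
}

#' Lagged partial-correlation flow grid
#'
#' Directed activity from the source to the target region:
#' \code{pc[dt, t]} is the partial correlation between the source RDM at
#' t - dt and the target RDM at t, partialling out the target RDM at t - dt
#' (correlations taken across RDM entries).  Cells whose lagged time falls
#' off the axis are NA; undefined correlations (constant RDM vectors) give 0.
#'
#' @param src,dst \code{RDMSeries} with identical time axes and item sets.
#' @param tWindowMs half-open window of current-time points t (ms), e.g.
#'   \code{c(600, 1200)} for second-word onset to +600.
#' @param dtMinMs,dtMaxMs,dtStepMs lag grid (defaults 5, 600, 5 ms); lags are
#'   snapped to the sample step.
#' @return a \code{\linkS4class{FlowGrid}}.
#' @export
directedFlow <- function(src, dst, tWindowMs, dtMinMs = 5, dtMaxMs = 600,
                         dtStepMs = 5) {
  stopifnot(is(src, "RDMSeries"), is(dst, "RDMSeries"))
  if (!isTRUE(all.equal(src@timesMs, dst@timesMs)))
    stop("source and target time axes differ")
  if (nrow(src@rdm) != nrow(dst@rdm)) stop("RDM vector lengths differ")
  times <- src@timesMs
  step <- times[2L] - times[1L]
  t_idx <- which(times >= tWindowMs[1] & times < tWindowMs[2])
  if (length(t_idx) == 0L) stop("no time points inside tWindowMs")
  dts <- seq(dtMinMs, dtMaxMs, by = dtStepMs)
  dlag <- unique(pmax(1L, as.integer(round(dts / step))))
  dts <- dlag * step
  A <- src@rdm; B <- dst@rdm
  Cab <- suppressWarnings(cor(A, B))
  Cbb <- suppressWarnings(cor(B, B))
  Cab[is.na(Cab)] <- 0
  Cbb[is.na(Cbb)] <- 0
  pc <- matrix(NA_real_, length(dlag), length(t_idx))
  for (k in seq_along(dlag)) {
    lagged <- t_idx - dlag[k]
    ok <- lagged >= 1L
    if (!any(ok)) next
    ti <- t_idx[ok]; li <- lagged[ok]
    rxy <- Cab[cbind(li, ti)]
    rxz <- Cab[cbind(li, li)]
    ryz <- Cbb[cbind(ti, li)]
    den <- sqrt(pmax(0, (1 - rxz^2) * (1 - ryz^2)))
    val <- ifelse(den > 0, (rxy - rxz * ryz) / den, 0)
    pc[k, ok] <- pmin(1, pmax(-1, val))
  }
  new("FlowGrid", pc = pc, dtMs = as.numeric(dts),
      tMs = as.numeric(times[t_idx]), direction = c(src@region, dst@region))
}

#' Direction-contrast permutation test
#'
#' Per-subject contrast of the two flow directions (A to B minus B to A) on
#' the lag x time grid, tested against zero with a one-sample sign-flip
#' permutation test and TFCE correction (grid connectivity: 4-neighborhood,
#' i.e. adjacent lags and adjacent times).
#'
#' @param ab,ba lists (one per subject) of \code{FlowGrid}s for the two
#'   directions, on congruent grids.
#' @param params \code{\link{tfceParams}}.
#' @param nPerm permutations.
#' @param seed RNG seed.
#' @param ... passed to \code{\link{permutationTest}}.
#' @return a \code{\linkS4class{StatResult}} on the lag x time grid (rows =
#'   lags dt, columns = current time t).
#' @export
directionContrastTest <- function(ab, ba, params = tfceParams(),
                                  nPerm = 1000L, seed, ...) {
  stopifnot(length(ab) == length(ba), length(ab) >= 4L)
  g1 <- ab[[1L]]
  for (x in c(ab, ba)) {
    if (!isTRUE(all.equal(x@dtMs, g1@dtMs)) ||
        !isTRUE(all.equal(x@tMs, g1@tMs)))
      stop("flow grids are not congruent")
  }
  n_dt <- length(g1@dtMs); n_t <- length(g1@tMs)
  maps <- array(0, c(length(ab), n_dt, n_t))
  has_na <- FALSE
  for (s in seq_along(ab)) {
    m <- ab[[s]]@pc - ba[[s]]@pc
    if (anyNA(m)) { has_na <- TRUE; m[is.na(m)] <- 0 }
    maps[s, , ] <- m
  }
  if (has_na)
    warning("out-of-range flow cells set to 0 for the group test")
  edges <- if (n_dt > 1L)
    cbind(seq_len(n_dt - 1L), seq_len(n_dt - 1L) + 1L)
  else matrix(integer(0), ncol = 2L)
  permutationTest(maps, popmean = 0, edges = edges, params = params,
                  nPerm = nPerm, tail = "two-sided", seed = seed,
                  rowValues = g1@dtMs, colValues = g1@tMs,
                  meta = list(direction = sprintf("%s->%s minus %s->%s",
                                                  g1@direction[1],
                                                  g1@direction[2],
                                                  g1@direction[2],
                                                  g1@direction[1])), ...)
}

#' Assemble a functional ROI from two analysis results
#'
#' Union of the sources carrying any significant point in either the
#' univariate regression result or the multivariate classification result at
#' level \code{alpha} (fROIs are defined from prior results, not anatomy).
#'
#' @param regression,decoding \code{StatResult}s whose \code{rowValues} are
#'   source indices.
#' @param alpha significance level.
#' @return sorted integer vector of source indices.
#' @export
froiFromResults <- function(regression, decoding, alpha = 0.05) {
  pick <- function(res) {
    if (is.null(res)) return(integer(0))
    as.integer(res@rowValues[rowSums(res@p <= alpha) > 0])
  }
  sort(unique(c(pick(regression), pick(decoding))))
}
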