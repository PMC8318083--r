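# Shared statistical machinery: OLS, one-sample t, TFCE enhancement on
# graph x time grids, sign-flip max-statistic permutation inference, and
# partial correlation.

#' Ordinary least-squares fit
#'
#' QR-based least squares for a single response vector.  Rank-deficient
#' designs are refused with the offending (collinear) columns named, rather
#' than silently dropped.
#'
#' @param y numeric response vector (trials).
#' @param X design matrix (trials x predictors); column names recommended.
#' @return named coefficient vector (one per column of \code{X}).
#' @export
olsFit <- function(y, X) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must match nrow(X)")
  if (nrow(X) <= ncol(X)) stop("need more trials than predictors")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    if (is.null(bad)) bad <- qx$pivot[(qx$rank + 1L):ncol(X)]
    stop(sprintf("design matrix is rank deficient; collinear columns: %s",
                 paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qx, y)
  names(beta) <- colnames(X)
  beta
}

#' One-sample t statistic
#'
#' @param values numeric vector across subjects (length >= 2).
#' @param popmean null population mean.
#' @return t = (mean - popmean) / (sd / sqrt(n)); signed infinity with a
#'   warning when the sample variance is zero (0 if the mean also equals
#'   \code{popmean}).
#' @export
oneSampleT <- function(values, popmean = 0) {
  n <- length(values)
  if (n < 2L) stop("need at least two values")
  m <- mean(values) - popmean
  s <- sd(values)
  if (s == 0) {
    warning("zero variance in one-sample t; returning signed infinity")
    return(if (m == 0) 0 else sign(m) * Inf)
  }
  m / (s / sqrt(n))
}

#' First-order partial correlation
#'
#' \eqn{r_{xy.z} = (r_{xy} - r_{xz} r_{yz}) / \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}}
#' with \eqn{r} the Pearson product-moment correlation.  Any constant input
#' makes the quantity undefined; by convention 0 is returned with a warning so
#' degenerate cells do not propagate missingness into group tests.
#'
#' @param x,y,z equal-length numeric vectors (length >= 3).
#' @return partial correlation in \[-1, 1\].
#' @export
partialCorrelation <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("equal lengths required")
  if (n < 3L) stop("need at least three observations")
  if (sd(x) == 0 || sd(y) == 0 || sd(z) == 0) {
    warning("constant input to partialCorrelation; returning 0")
    return(0)
  }
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  den <- sqrt((1 - rxz^2) * (1 - ryz^2))
  if (den == 0) {
    warning("degenerate partial correlation (|r| = 1 with z); returning 0")
    return(0)
  }
  max(-1, min(1, (rxy - rxz * ryz) / den))
}

tail_code <- function(tail) {
  switch(tail, "one-sided-positive" = 1L, "two-sided" = 2L,
         stop("unknown tail"))
}

#' Threshold-free cluster enhancement
#'
#' Enhances a statistic map on a (spatial graph) x time grid: each point's
#' score is the integral over thresholds h of (component extent)^E * h^H,
#' taken over the spatiotemporal connected component containing the point
#' after thresholding at h.  Connectivity is the spatial graph within a time
#' sample plus the same source at adjacent samples.  The negative tail is
#' enhanced on the negated map and subtracted, so the output is signed.
#' The integral is evaluated by a midpoint rule with step \code{dh}
#' (per-map default: max |stat| in the tail divided by 100).
#'
#' @param stat numeric matrix \[source, time\] (a vector is treated as a
#'   single-time grid).
#' @param edges spatial adjacency (two-column 1-based edge matrix) over the
#'   rows of \code{stat}, or a \code{SourceSpace} whose sources match.
#' @param params a \code{\link{tfceParams}} object.
#' @param tail \code{"two-sided"} (default) or \code{"one-sided-positive"}.
#' @return numeric matrix of signed TFCE scores, same shape as \code{stat}.
#' @export
tfceEnhance <- function(stat, edges, params = tfceParams(),
                        tail = c("two-sided", "one-sided-positive")) {
  tail <- match.arg(tail)
  if (is.null(dim(stat))) stat <- matrix(stat, ncol = 1L)
  if (length(stat) == 0L) stop("empty grid")
  if (!all(is.finite(stat))) stop("stat must be finite")
  if (is(edges, "SourceSpace")) edges <- edges@edges
  csr <- adjacency_csr(edges, nrow(stat))
  dh <- if (is.na(params@dh)) -1 else params@dh
  out <- tfce_enhance_cpp(as.numeric(stat), nrow(stat), ncol(stat),
                          csr$ptr, csr$idx, params@E, params@H, dh,
                          params@h0, 100L, tail_code(tail))
  matrix(out, nrow = nrow(stat), ncol = ncol(stat))
}

#' Sign-flip permutation test with TFCE correction
#'
#' Group-level inference on per-subject maps over a (spatial graph) x time
#' grid.  The observed map is the TFCE enhancement of the pointwise one-sample
#' t statistic against \code{popmean}.  The null is generated by independently
#' flipping each subject's deviation from \code{popmean} (the conventional
#' one-sample sign-flip scheme; \code{nullMethod = "zero"} instead exchanges
#' each subject's value with \code{popmean} itself, a literal zero-exchange
#' variant for sensitivity analysis).  Family-wise p-values come from the
#' permutation distribution of the maximum (absolute) TFCE score over the
#' grid; \code{correction = "pointwise"} gives uncorrected per-point p-values.
#' P-values use the add-one estimator (1 + exceedances) / (1 + nPerm).
#'
#' @param maps numeric array \[subject, source, time\] (or subject x points
#'   matrix, then treated as single-time columns unless \code{gridDim} given).
#' @param popmean null mean (0 for coefficients, 0.5 for accuracies).
#' @param edges spatial adjacency over the source axis (edge matrix or
#'   \code{SourceSpace}).
#' @param params \code{\link{tfceParams}}.
#' @param nPerm number of random permutations (>= 1).
#' @param tail \code{"two-sided"} or \code{"one-sided-positive"}.
#' @param seed RNG seed for the sign draws (required).
#' @param correction \code{"max"} (family-wise, default) or
#'   \code{"pointwise"}.
#' @param nullMethod \code{"sign-flip"} (default) or \code{"zero"}.
#' @param alpha level used only to warn when \code{nPerm} is too small to
#'   reach it.
#' @param rowValues,colValues optional grid coordinates stored in the result.
#' @param meta named list of provenance merged into the result.
#' @return a \code{\linkS4class{StatResult}}.
#' @export
permutationTest <- function(maps, popmean, edges, params = tfceParams(),
                            nPerm = 1000L, tail = c("two-sided",
                                                    "one-sided-positive"),
                            seed, correction = c("max", "pointwise"),
                            nullMethod = c("sign-flip", "zero"),
                            alpha = 0.05, rowValues = NULL, colValues = NULL,
                            meta = list()) {
  tail <- match.arg(tail)
  correction <- match.arg(correction)
  nullMethod <- match.arg(nullMethod)
  if (length(dim(maps)) == 3L) {
    nS <- dim(maps)[2L]; nT <- dim(maps)[3L]
    m <- matrix(maps, nrow = dim(maps)[1L])
  } else {
    m <- as.matrix(maps)
    nS <- ncol(m); nT <- 1L
  }
  nSubj <- nrow(m)
  if (nSubj < 4L) stop("need at least four subjects")
  nPerm <- as.integer(nPerm)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  if (1 / (1 + nPerm) > alpha)
    warning(sprintf("nPerm = %d cannot reach alpha = %g", nPerm, alpha))
  if (missing(seed)) stop("an explicit seed is required")
  if (is(edges, "SourceSpace")) edges <- edges@edges
  csr <- adjacency_csr(edges, nS)
  signs <- with_seed(seed, matrix(sample(c(-1L, 1L), nPerm * nSubj,
                                         replace = TRUE),
                                  nrow = nPerm, ncol = nSubj))
  dh <- if (is.na(params@dh)) -1 else params@dh
  res <- perm_test_cpp(m - popmean, nS, nT, csr$ptr, csr$idx, params@E,
                       params@H, dh, params@h0, 100L, signs,
                       tail_code(tail),
                       if (nullMethod == "sign-flip") 0L else 1L)
  obs_tfce <- matrix(res$tfce, nS, nT)
  if (correction == "max") {
    ref <- if (tail == "one-sided-positive") obs_tfce else abs(obs_tfce)
    exceed <- matrix(findInterval(-as.numeric(ref), sort(-res$null_max)),
                     nS, nT)
    p <- (1 + exceed) / (1 + nPerm)
  } else {
    p <- (1 + matrix(res$pointwise_exceed, nS, nT)) / (1 + nPerm)
  }
  new("StatResult", stat = matrix(res$stat, nS, nT), tfce = obs_tfce, p = p,
      nPermutations = nPerm, tail = tail,
      rowValues = if (is.null(rowValues)) as.numeric(seq_len(nS)) else rowValues,
      colValues = if (is.null(colValues)) as.numeric(seq_len(nT)) else colValues,
      meta = c(meta, list(correction = correction, nullMethod = nullMethod,
                          seed = seed, E = params@E, H = params@H,
                          dh = params@dh, h0 = params@h0,
                          popmean = popmean)))
}
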