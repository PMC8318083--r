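# Seeded generator of trial-level source estimates with planted effects,
# lagged inter-region couplings, frequency covariates and structured noise.
# Defaults mirror the two-word study design: five conditions (2 x 2 plus a
# single-word baseline), epoch [-100, 1200) ms at 1000 Hz, second word at
# 600 ms, 60 (or 45) trials per condition.

# log10 word frequencies (per-million scale); drawn per two-word trial.
FREQ_MEAN <- 2
FREQ_SD <- 0.8

#' Frequency-mixing specification
#'
#' Describes how the per-trial log-frequency covariates are mixed into the
#' signal: a scalar gain (negative slope: more frequent words evoke less
#' activation) on a fixed spatial pattern over \code{regionMask}, within a
#' word-specific window.
#'
#' @param regionMask integer source indices receiving the frequency signal.
#' @param slope1,slope2 amplitude change per log10-frequency unit for word 1
#'   and word 2 (negative by default).
#' @param window1Ms,window2Ms half-open windows (ms) of the two responses.
#' @return list consumed by \code{\link{simulateDataset}}.
#' @export
freqEffectSpec <- function(regionMask, slope1 = -0.5, slope2 = -0.5,
                           window1Ms = c(100, 600), window2Ms = c(700, 1200)) {
  list(regionMask = as.integer(regionMask), slope1 = slope1, slope2 = slope2,
       window1Ms = as.numeric(window1Ms), window2Ms = as.numeric(window2Ms))
}

design_value <- function(predictor, condition) {
  assoc <- as.numeric(condition %in% c("HA-comp", "HA-list"))
  comp <- as.numeric(condition %in% c("HA-comp", "LA-comp"))
  switch(predictor,
         intercept = rep(1, length(condition)),
         association = assoc,
         composition = comp,
         interaction = assoc * comp,
         n_words = as.numeric(condition != "single"),
         stop(sprintf("unknown predictor '%s'", predictor)))
}

# temporally smoothed standard-normal pattern field [nSources, nTimes]
pattern_field <- function(n_src, n_time, smooth_samples, seed) {
  with_seed(seed, {
    w <- matrix(rnorm(n_src * n_time), n_src, n_time)
    if (smooth_samples >= 2L && n_time > 1L)
      w <- ma_smooth_rows(w, smooth_samples)
    w / sd(w)
  })
}

# moving-average smoothing along rows' time axis with edge truncation
ma_smooth_rows <- function(x, w) {
  h <- (w - 1L) %/% 2L
  n_time <- ncol(x)
  cs <- cbind(0, t(apply(x, 1L, cumsum)))
  lo <- pmax(seq_len(n_time) - h, 1L)
  hi <- pmin(seq_len(n_time) + h, n_time)
  (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1, each = nrow(x))
}

# spatial graph-diffusion smoothing operator (dense): x <- (x + nbr mean)/2
diffusion_operator <- function(edges, n_src, k) {
  if (k < 1L || nrow(edges) == 0L) return(NULL)
  A <- matrix(0, n_src, n_src)
  A[cbind(edges[, 1L], edges[, 2L])] <- 1
  A[cbind(edges[, 2L], edges[, 1L])] <- 1
  deg <- pmax(rowSums(A), 1)
  S <- 0.5 * diag(n_src) + 0.5 * A / deg
  out <- S
  if (k > 1L) for (i in seq_len(k - 1L)) out <- S %*% out
  out
}

#' Simulate a trial-level source-estimate dataset
#'
#' Generates one \code{\linkS4class{TrialTensor}} per subject under the
#' two-word design, with planted effects realized additively inside their
#' region x window, optional lagged inter-region couplings (applied to the
#' noise-free signal), frequency covariates (drawn for every two-word trial
#' and mixed in only via \code{freqEffect}), per-subject additive amplitude
#' offsets, and spatially/temporally correlated noise rescaled so its
#' empirical SD equals \code{noise@sensorSd}.  The single-word condition
#' carries no word-1 signal: intercept-type effects and word-1 frequency
#' signal are suppressed before the second word's onset for those trials.
#'
#' @param design a \code{\link{designSpec}}.
#' @param space a \code{SourceSpace} with >= 50 sources (regions used by
#'   couplings must be named masks).
#' @param effects list of \code{\link{plantedEffect}} objects.
#' @param couplings list of \code{\link{couplingSpec}} objects.
#' @param noise a \code{\link{noiseSpec}}.
#' @param seed integer seed; the output is fully determined by it.
#' @param freqEffect optional \code{\link{freqEffectSpec}}; NULL (default)
#'   draws covariates without mixing them into the signal.
#' @param dropout optional per-trial dropout rate in \[0, 1) emulating epoch
#'   rejection (at least two trials per condition are always kept).
#' @return list with \code{tensors} (per-subject \code{TrialTensor}s) and
#'   \code{truth} (a \code{\linkS4class{GroundTruth}}).
#' @export
simulateDataset <- function(design, space, effects = list(),
                            couplings = list(), noise = noiseSpec(),
                            seed, freqEffect = NULL, dropout = 0) {
  stopifnot(is(design, "DesignSpec"), is(space, "SourceSpace"))
  if (nSources(space) < 50L) stop("space must have at least 50 sources")
  if (missing(seed)) stop("a seed is required")
  step_ms <- 1000 / design@sampleRateHz
  n_time <- as.integer(round((design@epochEndMs - design@epochStartMs) / step_ms))
  times <- time_points(design@epochStartMs, step_ms, n_time)
  epoch_len <- design@epochEndMs - design@epochStartMs
  for (cp in couplings) {
    if (cp@lagMs > epoch_len)
      stop(sprintf("coupling lag %g ms exceeds the epoch length %g ms",
                   cp@lagMs, epoch_len))
  }
  n_src <- nSources(space)
  tpc <- design@trialsPerCondition
  cond <- rep(CONDITION_LEVELS, each = tpc)
  n_trials <- length(cond)
  two_word <- cond != "single"
  smooth_samples <- max(1L, as.integer(round(noise@temporalSmoothingMs / step_ms)))
  diffop <- if (noise@sensorSd > 0)
    diffusion_operator(space@edges, n_src, as.integer(noise@spatialCorrLength))
  else NULL

  tensors <- vector("list", design@nSubjects)
  for (s in seq_len(design@nSubjects)) {
    sseed <- derive_seed(seed, s)
    tensors[[s]] <- with_seed(sseed, {
      w1 <- ifelse(two_word, rnorm(n_trials, FREQ_MEAN, FREQ_SD), 0)
      w2 <- rnorm(n_trials, FREQ_MEAN, FREQ_SD)
      delta <- rnorm(1, 0, noise@subjectSd)
      sig <- array(0, c(n_trials, n_src, n_time))

      word2_on <- design@word2OnsetMs
      for (k in seq_along(effects)) {
        ef <- effects[[k]]
        win <- window_indices(ef@windowMs, design@epochStartMs, step_ms, n_time)
        if (length(win) == 0L) next
        amp <- ef@amplitude + delta
        if (ef@effectForm == "univariate-amplitude") {
          x <- design_value(ef@predictorName, cond)
          contrib <- outer(x * amp, rep(1, length(ef@regionMask)))
          for (ti in win) {
            # the single-word baseline has no word-1 response component
            keep <- if (ef@predictorName == "intercept" &&
                        times[ti] < word2_on) two_word else rep(TRUE, n_trials)
            sig[keep, ef@regionMask, ti] <-
              sig[keep, ef@regionMask, ti] + contrib[keep, ]
          }
        } else {
          pseed <- derive_seed(ef@patternSeed, s)
          if (ef@predictorName == "condition-patterns") {
            for (ci in seq_along(TWO_WORD_CONDITIONS)) {
              W <- amp * pattern_field(length(ef@regionMask), length(win),
                                       smooth_samples,
                                       derive_seed(pseed, ci))
              rows <- which(cond == TWO_WORD_CONDITIONS[ci])
              for (r in rows)
                sig[r, ef@regionMask, win] <- sig[r, ef@regionMask, win] + W
            }
          } else {
            pair <- strsplit(ef@predictorName, "_vs_", fixed = TRUE)[[1L]]
            if (length(pair) != 2L || !all(pair %in% CONDITION_LEVELS))
              stop(sprintf("bad pattern contrast '%s'", ef@predictorName))
            W <- amp * pattern_field(length(ef@regionMask), length(win),
                                     smooth_samples, pseed)
            for (r in which(cond == pair[1L]))
              sig[r, ef@regionMask, win] <- sig[r, ef@regionMask, win] + W
            for (r in which(cond == pair[2L]))
              sig[r, ef@regionMask, win] <- sig[r, ef@regionMask, win] - W
          }
        }
      }

      if (!is.null(freqEffect)) {
        m <- freqEffect$regionMask
        win1 <- window_indices(freqEffect$window1Ms, design@epochStartMs,
                               step_ms, n_time)
        win2 <- window_indices(freqEffect$window2Ms, design@epochStartMs,
                               step_ms, n_time)
        if (length(win1))
          sig[, m, win1] <- sig[, m, win1] + freqEffect$slope1 * w1
        if (length(win2))
          sig[, m, win2] <- sig[, m, win2] + freqEffect$slope2 * w2
      }

      for (ci in seq_along(couplings)) {
        cp <- couplings[[ci]]
        src <- regionMask(space, cp@sourceRegion)
        dst <- regionMask(space, cp@targetRegion)
        lag_smp <- as.integer(round(cp@lagMs / step_ms))
        win <- window_indices(cp@windowMs, design@epochStartMs, step_ms, n_time)
        win <- win[win - lag_smp >= 1L]
        if (length(win) == 0L) next
        P <- if (length(src) == length(dst)) NULL else
          with_seed(derive_seed(seed, 7777L + ci),
                    matrix(rnorm(length(dst) * length(src), 0,
                                 1 / sqrt(length(src))),
                           length(dst), length(src)))
        for (r in seq_len(n_trials)) {
          lagged <- sig[r, src, win - lag_smp, drop = TRUE]
          if (is.null(dim(lagged))) lagged <- matrix(lagged, nrow = length(src))
          add <- if (is.null(P)) cp@gain * lagged else cp@gain * (P %*% lagged)
          sig[r, dst, win] <- sig[r, dst, win] + add
        }
      }

      if (noise@sensorSd > 0) {
        eps <- array(rnorm(n_trials * n_src * n_time), c(n_trials, n_src, n_time))
        if (!is.null(diffop)) {
          em <- matrix(aperm(eps, c(2L, 1L, 3L)), nrow = n_src)
          em <- diffop %*% em
          eps <- aperm(array(em, c(n_src, n_trials, n_time)), c(2L, 1L, 3L))
        }
        if (smooth_samples >= 2L) {
          em <- matrix(eps, nrow = n_trials * n_src)
          eps <- array(ma_smooth_rows(em, smooth_samples),
                       c(n_trials, n_src, n_time))
        }
        eps <- eps * (noise@sensorSd / sd(eps))
        sig <- sig + eps
      }

      keep <- seq_len(n_trials)
      if (dropout > 0) {
        drop <- runif(n_trials) < dropout
        for (cl in CONDITION_LEVELS) {
          rows <- which(cond == cl)
          if (sum(!drop[rows]) < 2L) drop[rows[seq_len(2L)]] <- FALSE
        }
        keep <- which(!drop)
      }
      trialTensor(sig[keep, , , drop = FALSE], cond[keep], w1[keep], w2[keep],
                  subjectId = sprintf("S%02d", s),
                  timeStartMs = design@epochStartMs, timeStepMs = step_ms)
    })
  }

  overlap <- FALSE
  for (ef in effects) for (cp in couplings) {
    if (ef@windowMs[1] < cp@windowMs[2] && cp@windowMs[1] < ef@windowMs[2])
      overlap <- TRUE
  }
  truth <- new("GroundTruth", design = design, effects = effects,
               couplings = couplings,
               freqEffect = if (is.null(freqEffect)) list() else freqEffect,
               overlapFlag = overlap)
  list(tensors = tensors, truth = truth)
}

#' Planted amplitude for a target first-stage t statistic
#'
#' Given a realized design matrix and the trial noise SD, returns the
#' amplitude whose expected single-subject OLS t statistic for
#' \code{predictor} is \code{tTarget}:
#' \eqn{a = t \cdot \sigma \sqrt{[(X'X)^{-1}]_{jj}}}.
#'
#' @param X design matrix (as from \code{\link{buildDesign}}).
#' @param predictor column name.
#' @param sigma trial noise SD at a grid point.
#' @param tTarget desired t value (default 5).
#' @return amplitude in signal units.
#' @export
amplitudeForT <- function(X, predictor, sigma, tTarget = 5) {
  j <- match(predictor, colnames(X))
  if (is.na(j)) stop(sprintf("predictor '%s' not in design", predictor))
  tTarget * sigma * sqrt(solve(crossprod(X))[j, j])
}
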