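# Searchlight multivariate pattern classification: frequency regress-out,
# temporal decimation, pseudo-trial averaging, pairwise linear-SVM decoding
# with leave-one-pseudo-trial-pair-out cross-validation, and a group-level
# one-tailed TFCE permutation test against chance.

#' The four pairwise condition classifications
#'
#' Composition within each association level, and association within each
#' composition level.
#' @export
DECODING_PAIRS <- list(c("HA-comp", "HA-list"), c("LA-comp", "LA-list"),
                       c("HA-comp", "LA-comp"), c("HA-list", "LA-list"))

#' Regress word-frequency effects out of a trial tensor
#'
#' Fits the full design at every (source, time) point and subtracts the
#' fitted contribution of the two centered frequency columns, leaving the
#' condition structure untouched.
#'
#' @param tensor a \code{TrialTensor}.
#' @param coding factor coding for the auxiliary design.
#' @return a \code{TrialTensor} of residualized data.
#' @export
regressOutFrequency <- function(tensor, coding = "dummy") {
  stopifnot(is(tensor, "TrialTensor"))
  if (sd(tensor@word1LogFreq) == 0 || sd(tensor@word2LogFreq) == 0)
    stop("constant frequency column: nothing to regress out")
  X <- buildDesign(conditions(tensor), tensor@word1LogFreq,
                   tensor@word2LogFreq, coding = coding)
  d <- dim(tensor@data)
  Y <- matrix(tensor@data, nrow = d[1L])
  B <- qr.coef(qr(X), Y)
  fcols <- c("word1_logfreq", "word2_logfreq")
  fit <- X[, fcols, drop = FALSE] %*% B[fcols, , drop = FALSE]
  out <- tensor
  out@data <- array(Y - fit, d)
  out
}

#' Decimate the time axis
#'
#' Takes every \code{factor}-th sample (the data are assumed already
#' low-passed upstream); \code{method = "mean"} averages consecutive blocks
#' instead.  The new axis has \code{ceiling(n/factor)} samples and a step
#' multiplied by \code{factor}.
#'
#' @param tensor a \code{TrialTensor}.
#' @param factor integer >= 1 (and <= number of samples).
#' @param method \code{"subsample"} (default) or \code{"mean"}.
#' @return a decimated \code{TrialTensor}.
#' @export
decimateTrials <- function(tensor, factor, method = c("subsample", "mean")) {
  method <- match.arg(method)
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  n_time <- dim(tensor@data)[3L]
  if (factor > n_time) stop("factor exceeds the number of time samples")
  out <- tensor
  if (factor == 1L) return(out)
  idx <- seq(1L, n_time, by = factor)
  if (method == "subsample") {
    out@data <- tensor@data[, , idx, drop = FALSE]
  } else {
    d <- dim(tensor@data)
    new <- array(0, c(d[1L], d[2L], length(idx)))
    for (k in seq_along(idx)) {
      block <- idx[k]:min(idx[k] + factor - 1L, n_time)
      new[, , k] <- if (length(block) > 1L)
        apply(tensor@data[, , block, drop = FALSE], c(1L, 2L), mean)
      else tensor@data[, , block]
    }
    out@data <- new
  }
  out@timeStepMs <- tensor@timeStepMs * factor
  out
}

# random disjoint partition of n trials into nPseudo blocks,
# remainder assigned round-robin; returns list of index vectors
partition_blocks <- function(n, nPseudo) {
  perm <- sample.int(n)
  sizes <- rep(n %/% nPseudo, nPseudo)
  r <- n %% nPseudo
  if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  unname(split(perm, rep(seq_len(nPseudo), times = sizes)))
}

#' Pseudo-trials for one condition
#'
#' Randomly divides the condition's trials into \code{nPseudo} disjoint
#' blocks (remainder trials assigned round-robin so block sizes differ by at
#' most one) and returns the block means.
#'
#' @param trials numeric array \[trial, source, time\] of one condition.
#' @param nPseudo number of pseudo-trials (default 15).
#' @param seed RNG seed.
#' @return numeric array \[pseudo-trial, source, time\].
#' @export
makePseudotrials <- function(trials, nPseudo = 15L, seed) {
  d <- dim(trials)
  if (d[1L] < nPseudo)
    stop(sprintf("condition has %d trials, fewer than nPseudo = %d",
                 d[1L], nPseudo))
  blocks <- with_seed(seed, partition_blocks(d[1L], nPseudo))
  out <- array(0, c(nPseudo, d[2L], d[3L]))
  for (b in seq_len(nPseudo)) {
    ii <- blocks[[b]]
    out[b, , ] <- if (length(ii) > 1L)
      colMeans(array(trials[ii, , , drop = FALSE],
                     c(length(ii), d[2L], d[3L])))
    else trials[ii, , ]
  }
  out
}

#' Full pseudo-trial set
#'
#' \code{\link{makePseudotrials}} applied to each two-word condition of a
#' tensor, stacked into a \code{\linkS4class{PseudoTrialSet}}.
#'
#' @param tensor a (preprocessed) \code{TrialTensor}.
#' @param nPseudo pseudo-trials per condition.
#' @param seed RNG seed.
#' @param conditions condition labels (default: the four two-word conditions).
#' @return a \code{\linkS4class{PseudoTrialSet}}.
#' @export
buildPseudoTrialSet <- function(tensor, nPseudo = 15L, seed,
                                conditions = TWO_WORD_CONDITIONS) {
  d <- dim(tensor@data)
  out <- array(0, c(length(conditions), nPseudo, d[2L], d[3L]))
  for (ci in seq_along(conditions)) {
    rows <- which(tensor@condition == conditions[ci])
    out[ci, , , ] <- makePseudotrials(
      tensor@data[rows, , , drop = FALSE], nPseudo, derive_seed(seed, ci))
  }
  new("PseudoTrialSet", patterns = out, conditions = conditions,
      partitionSeed = as.integer(seed))
}

# standardize by training statistics; train/test are pseudo x feature
standardize_fold <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2L, sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(train, 2L, mu), 2L, sdv, "/"),
       test = sweep(sweep(test, 2L, mu), 2L, sdv, "/"))
}

svm_fold_accuracy <- function(trainA, trainB, testA, testB) {
  train <- rbind(trainA, trainB)
  test <- rbind(testA, testB)
  sf <- standardize_fold(train, test)
  y <- factor(rep(c("A", "B"), c(nrow(trainA), nrow(trainB))))
  fit <- e1071::svm(sf$train, y, kernel = "linear", cost = 1, scale = FALSE)
  pred <- stats::predict(fit, sf$test)
  mean(pred == factor(c("A", "B")))
}

#' Pairwise decoding accuracy for one feature set
#'
#' Leave-one-pseudo-trial-pair-out cross-validation: per repetition the
#' trials of each condition are re-partitioned into pseudo-trials, one
#' randomly selected pseudo-trial per condition is held out, a linear
#' maximum-margin classifier (SVM, unit cost) is trained on the remainder
#' with features standardized by training-fold statistics, and the held-out
#' pair is scored.  The accuracy is the mean over repetitions.
#'
#' @param featA,featB numeric matrices \[trial, feature\] for the two
#'   conditions (the flattened searchlight neighborhood).
#' @param nPseudo pseudo-trials per condition.
#' @param nReps cross-validation repartitions (default 100).
#' @param seed RNG seed.
#' @return mean accuracy in \[0, 1\]; degenerate (all-constant) features give
#'   0.5 with a warning.
#' @export
decodePair <- function(featA, featB, nPseudo = 15L, nReps = 100L, seed) {
  if (nrow(featA) == 0L || nrow(featB) == 0L) stop("empty feature sets")
  if (all(apply(rbind(featA, featB), 2L, sd) == 0)) {
    warning("all features constant; returning chance accuracy")
    return(0.5)
  }
  acc <- with_seed(seed, {
    vapply(seq_len(nReps), function(r) {
      pa <- do.call(rbind, lapply(partition_blocks(nrow(featA), nPseudo),
                                  function(ii) colMeans(featA[ii, , drop = FALSE])))
      pb <- do.call(rbind, lapply(partition_blocks(nrow(featB), nPseudo),
                                  function(ii) colMeans(featB[ii, , drop = FALSE])))
      ha <- sample.int(nPseudo, 1L)
      hb <- sample.int(nPseudo, 1L)
      svm_fold_accuracy(pa[-ha, , drop = FALSE], pb[-hb, , drop = FALSE],
                        pa[ha, , drop = FALSE], pb[hb, , drop = FALSE])
    }, numeric(1))
  })
  mean(acc)
}

#' Build a searchlight specification
#'
#' Neighborhoods are the \code{nSourcesPerLight} graph-nearest sources within
#' the mask (BFS hop distance on the mask-induced graph, ties broken by
#' source index) crossed with \code{nTimepointsPerLight} consecutive
#' decimated samples centered on the center (truncated at window edges).
#' Center density is controlled by \code{sourceStride}/\code{timeStride}.
#'
#' @param space a \code{SourceSpace}.
#' @param mask integer source indices of the analysis mask.
#' @param windowMs half-open analysis window (ms).
#' @param timesMs time points (ms) of the decimated data
#'   (e.g. \code{tensorTimes(tensor)}).
#' @param nSourcesPerLight,nTimepointsPerLight neighborhood sizes (defaults
#'   100 and 5).
#' @param sourceStride,timeStride keep every k-th mask source / window sample
#'   as a center.
#' @return a \code{\linkS4class{SearchlightSpec}}.
#' @export
searchlightSpec <- function(space, mask, windowMs, timesMs,
                            nSourcesPerLight = 100L, nTimepointsPerLight = 5L,
                            sourceStride = 1L, timeStride = 1L) {
  mask <- sort(as.integer(mask))
  sub_edges <- induced_edges(adjacency(space), mask)
  adj <- adjacency_list(sub_edges, length(mask))
  center_local <- seq(1L, length(mask), by = sourceStride)
  nbh <- lapply(center_local, function(cl)
    mask[graphNeighborhood(adj, cl, min(nSourcesPerLight, length(mask)))])
  wt <- which(timesMs >= windowMs[1] & timesMs < windowMs[2])
  if (length(wt) == 0L) stop("no decimated samples inside the window")
  ct <- wt[seq(1L, length(wt), by = timeStride)]
  new("SearchlightSpec", nSourcesPerLight = as.integer(nSourcesPerLight),
      nTimepointsPerLight = as.integer(nTimepointsPerLight),
      centerSources = mask[center_local], centerTimesMs = timesMs[ct],
      neighborhoods = nbh, sourceStride = as.integer(sourceStride),
      timeStride = as.integer(timeStride))
}

#' Time points of a tensor
#'
#' @param tensor a \code{TrialTensor}.
#' @return numeric vector of sample times (ms).
#' @export
tensorTimes <- function(tensor) {
  time_points(tensor@timeStartMs, tensor@timeStepMs, dim(tensor@data)[3L])
}

#' Searchlight decoding for one subject
#'
#' Runs the four pairwise classifiers (or a subset) at every searchlight
#' center.  Within a repetition, the pseudo-trial partition and the held-out
#' pseudo-trial per condition are shared across centers and pairs (the
#' repartition-then-scan scheme), and accuracies are averaged over
#' \code{nReps} repetitions.
#'
#' @param tensor a preprocessed (frequency-residualized, decimated)
#'   \code{TrialTensor}.
#' @param spec a \code{\link{searchlightSpec}}.
#' @param pairs list of condition pairs (default \code{\link{DECODING_PAIRS}}).
#' @param nPseudo pseudo-trials per condition (default 15).
#' @param nReps repetitions (default 100).
#' @param seed RNG seed.
#' @return list (one per pair) of accuracy matrices
#'   \[center source, center time\].
#' @export
searchlightDecode <- function(tensor, spec, pairs = DECODING_PAIRS,
                              nPseudo = 15L, nReps = 100L, seed) {
  stopifnot(is(tensor, "TrialTensor"), is(spec, "SearchlightSpec"))
  times <- tensorTimes(tensor)
  ct_idx <- match(spec@centerTimesMs, times)
  if (anyNA(ct_idx)) stop("spec center times not on the tensor time axis")
  n_cs <- length(spec@centerSources)
  n_ct <- length(ct_idx)
  half <- (spec@nTimepointsPerLight - 1L) %/% 2L
  n_time <- length(times)
  cond_rows <- lapply(TWO_WORD_CONDITIONS,
                      function(cl) which(tensor@condition == cl))
  names(cond_rows) <- TWO_WORD_CONDITIONS
  d <- dim(tensor@data)
  acc <- lapply(pairs, function(p) matrix(0, n_cs, n_ct))

  with_seed(seed, {
    for (rep in seq_len(nReps)) {
      pseudo <- lapply(cond_rows, function(rows) {
        blocks <- partition_blocks(length(rows), nPseudo)
        ps <- array(0, c(nPseudo, d[2L], d[3L]))
        for (b in seq_len(nPseudo)) {
          ii <- rows[blocks[[b]]]
          ps[b, , ] <- if (length(ii) > 1L)
            colMeans(array(tensor@data[ii, , , drop = FALSE],
                           c(length(ii), d[2L], d[3L])))
          else tensor@data[ii, , ]
        }
        ps
      })
      held <- lapply(TWO_WORD_CONDITIONS,
                     function(cl) sample.int(nPseudo, 1L))
      names(held) <- TWO_WORD_CONDITIONS
      for (si in seq_len(n_cs)) {
        nb <- spec@neighborhoods[[si]]
        for (ti in seq_len(n_ct)) {
          tt <- max(1L, ct_idx[ti] - half):min(n_time, ct_idx[ti] + half)
          for (pi in seq_along(pairs)) {
            a <- pairs[[pi]][1L]; b <- pairs[[pi]][2L]
            fa <- matrix(pseudo[[a]][, nb, tt], nrow = nPseudo)
            fb <- matrix(pseudo[[b]][, nb, tt], nrow = nPseudo)
            ha <- held[[a]]; hb <- held[[b]]
            acc[[pi]][si, ti] <- acc[[pi]][si, ti] +
              svm_fold_accuracy(fa[-ha, , drop = FALSE],
                                fb[-hb, , drop = FALSE],
                                fa[ha, , drop = FALSE],
                                fb[hb, , drop = FALSE])
          }
        }
      }
    }
  })
  lapply(acc, function(m) m / nReps)
}

#' Group searchlight decoding across subjects
#'
#' @param tensors list of preprocessed per-subject tensors.
#' @param spec a \code{SearchlightSpec}.
#' @param pairs condition pairs.
#' @param nPseudo,nReps,seed as in \code{\link{searchlightDecode}} (subject
#'   seeds are derived from \code{seed}).
#' @return list of \code{\linkS4class{AccuracyMap}} objects, one per pair.
#' @export
groupSearchlight <- function(tensors, spec, pairs = DECODING_PAIRS,
                             nPseudo = 15L, nReps = 100L, seed) {
  per_subj <- lapply(seq_along(tensors), function(s)
    searchlightDecode(tensors[[s]], spec, pairs, nPseudo, nReps,
                      derive_seed(seed, s)))
  lapply(seq_along(pairs), function(pi) {
    arr <- array(0, c(length(tensors), length(spec@centerSources),
                      length(spec@centerTimesMs)))
    for (s in seq_along(tensors)) arr[s, , ] <- per_subj[[s]][[pi]]
    new("AccuracyMap", accuracy = arr, pair = pairs[[pi]], chance = 0.5,
        spec = spec, nReps = as.integer(nReps))
  })
}

# adjacency between searchlight center sources: connected iff hop distance
# on the mask-induced graph is within the center stride
center_adjacency <- function(space, spec, mask) {
  centers <- spec@centerSources
  if (length(centers) <= 1L) return(matrix(integer(0), ncol = 2L))
  sub_edges <- induced_edges(adjacency(space), mask)
  g <- igraph::graph_from_edgelist(sub_edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(mask) - igraph::vcount(g)))
  cl <- match(centers, mask)
  dmat <- igraph::distances(g, v = cl, to = cl)
  sel <- which(upper.tri(dmat) & dmat >= 1 & dmat <= spec@sourceStride,
               arr.ind = TRUE)
  matrix(as.integer(sel), ncol = 2L)
}

#' Group-level decoding test against chance
#'
#' One-sample one-tailed t test of subject accuracies against the 50% chance
#' level at every searchlight center, with TFCE and sign-flip max-statistic
#' permutation correction.
#'
#' @param map an \code{AccuracyMap} (subjects stacked).
#' @param space the parent \code{SourceSpace}.
#' @param mask the analysis mask the searchlight ran in.
#' @param params \code{\link{tfceParams}}.
#' @param nPerm permutations.
#' @param seed RNG seed.
#' @param ... passed to \code{\link{permutationTest}}.
#' @return a \code{\linkS4class{StatResult}} on the center grid.
#' @export
groupDecodingTest <- function(map, space, mask, params = tfceParams(),
                              nPerm = 1000L, seed, ...) {
  stopifnot(is(map, "AccuracyMap"))
  edges <- center_adjacency(space, map@spec, sort(as.integer(mask)))
  permutationTest(map@accuracy, popmean = 0.5, edges = edges, params = params,
                  nPerm = nPerm, tail = "one-sided-positive", seed = seed,
                  rowValues = as.numeric(map@spec@centerSources),
                  colValues = map@spec@centerTimesMs,
                  meta = list(pair = paste(map@pair, collapse = " vs "),
                              chance = map@chance), ...)
}
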