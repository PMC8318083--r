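# internal helpers shared across stages

#' @useDynLib megstats, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats rnorm runif sd cor prcomp predict
#' @importFrom utils head
NULL

# Evaluate expr with a local, restorable RNG state.  All stochastic stages
# funnel through this so a caller-supplied seed fully determines the output
# without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single finite seed is required")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seeds; kept below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483629) + 1L
}

# Spatial adjacency as 0-based CSR for the C++ grid routines.
# edges: 2-column integer matrix of 1-based undirected edges.
adjacency_csr <- function(edges, n_sources) {
  if (is.null(edges) || nrow(edges) == 0L) {
    return(list(ptr = rep.int(0L, n_sources + 1L), idx = integer(0)))
  }
  from <- c(edges[, 1L], edges[, 2L])
  to <- c(edges[, 2L], edges[, 1L])
  ord <- order(from, to)
  from <- from[ord]; to <- to[ord]
  counts <- tabulate(from, nbins = n_sources)
  list(ptr = as.integer(c(0L, cumsum(counts))), idx = as.integer(to - 1L))
}

# Adjacency as a list of 1-based neighbor vectors.
adjacency_list <- function(edges, n_sources) {
  out <- vector("list", n_sources)
  for (i in seq_len(n_sources)) out[[i]] <- integer(0)
  if (!is.null(edges) && nrow(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1L]; b <- edges[r, 2L]
      out[[a]] <- c(out[[a]], b)
      out[[b]] <- c(out[[b]], a)
    }
    out <- lapply(out, function(v) sort(unique(v)))
  }
  out
}

# Induced subgraph on `keep` (1-based source indices), re-indexed 1..length(keep).
induced_edges <- function(edges, keep) {
  if (is.null(edges) || nrow(edges) == 0L)
    return(matrix(integer(0), ncol = 2L))
  map <- integer(max(c(edges, keep)))
  map[keep] <- seq_along(keep)
  sel <- edges[, 1L] %in% keep & edges[, 2L] %in% keep
  e <- edges[sel, , drop = FALSE]
  cbind(map[e[, 1L]], map[e[, 2L]])
}

#' Dice overlap between two logical masks
#'
#' Computes \eqn{2|A \cap B| / (|A| + |B|)} for two logical arrays of the same
#' shape; used to score how well a detected significant set recovers a planted
#' region-by-window set.
#'
#' @param a,b logical vectors/arrays of equal length.
#' @return Dice coefficient in \[0, 1\] (1 if both are empty).
#' @export
diceOverlap <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  stopifnot(length(a) == length(b))
  denom <- sum(a) + sum(b)
  if (denom == 0L) return(1)
  2 * sum(a & b) / denom
}

ms_to_index <- function(ms, start_ms, step_ms) {
  as.integer(round((ms - start_ms) / step_ms)) + 1L
}

# Half-open window [start, end) in ms -> 1-based sample indices.
window_indices <- function(window_ms, start_ms, step_ms, n_time) {
  times <- start_ms + (seq_len(n_time) - 1L) * step_ms
  which(times >= window_ms[1] & times < window_ms[2])
}

time_points <- function(start_ms, step_ms, n_time) {
  start_ms + (seq_len(n_time) - 1L) * step_ms
}
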