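# Independent oracles and fixture builders shared across the suite.

# Brute-force TFCE oracle: literal right-endpoint threshold sweep
# (h = h0 + dh, h0 + 2 dh, ... <= max) with per-threshold connected-component
# labeling on the spatiotemporal graph via igraph.  Enhances one (positive)
# tail; callers combine tails.
oracle_tfce <- function(stat, edges, E = 0.5, H = 2, dh, h0 = 0) {
  nS <- nrow(stat); nT <- ncol(stat); n <- nS * nT
  el <- list()
  if (nrow(edges) > 0) for (t in seq_len(nT)) el[[t]] <- edges + (t - 1) * nS
  if (nT > 1) {
    i <- seq_len(n - nS)
    el[[length(el) + 1]] <- cbind(i, i + nS)
  }
  allE <- do.call(rbind, el)
  out <- numeric(n)
  v <- as.numeric(stat)
  if (max(v) <= h0) return(matrix(out, nS, nT))
  for (h in seq(h0 + dh, max(v), by = dh)) {
    sup <- which(v >= h)
    if (length(sup) == 0) break
    loc <- integer(n); loc[sup] <- seq_along(sup)
    a <- loc[allE[, 1]]; b <- loc[allE[, 2]]
    keep <- a > 0L & b > 0L
    g <- igraph::make_empty_graph(length(sup), directed = FALSE)
    g <- igraph::add_edges(g, rbind(a[keep], b[keep]))
    cm <- igraph::components(g)$membership
    sizes <- tabulate(cm)
    out[sup] <- out[sup] + sizes[cm]^E * h^H * dh
  }
  matrix(out, nS, nT)
}

# signed two-sided oracle with per-tail automatic dh = max(tail)/100,
# refined by `refine` (the module's per-tail default divided by `refine`)
oracle_tfce_two_sided <- function(stat, edges, E = 0.5, H = 2, refine = 10) {
  pos <- pmax(stat, 0); neg <- pmax(-stat, 0)
  out <- matrix(0, nrow(stat), ncol(stat))
  if (max(pos) > 0)
    out <- out + oracle_tfce(pos, edges, E, H, dh = max(pos) / 100 / refine)
  if (max(neg) > 0)
    out <- out - oracle_tfce(neg, edges, E, H, dh = max(neg) / 100 / refine)
  out
}

chain_edges <- function(n) {
  if (n < 2) return(matrix(integer(0), ncol = 2))
  cbind(seq_len(n - 1), seq_len(n - 1) + 1)
}

# small lattice space with the region layout used throughout the tests
test_space <- function(nrow = 8, ncol = 8) {
  latticeSourceSpace(nrow, ncol,
                     regions = list(A = c(1, 4, 1, 3), B = c(5, 8, 1, 3),
                                    mask = c(1, nrow, 1, 6)))
}

# TrialTensor from an explicit array with default labels/covariates
quick_tensor <- function(data, condition = NULL, w1 = NULL, w2 = NULL,
                         startMs = 0, stepMs = 10) {
  n <- dim(data)[1]
  if (is.null(condition))
    condition <- rep_len(CONDITION_LEVELS, n)
  if (is.null(w1)) w1 <- seq(1, 3, length.out = n)
  if (is.null(w2)) w2 <- seq(3, 1, length.out = n)
  trialTensor(data, condition, w1, w2, "T01", startMs, stepMs)
}

induced_edges_for_test <- function(space, mask) {
  megstats:::induced_edges(adjacency(space), sort(as.integer(mask)))
}

# planted-set logical grid for Dice scoring on a masked result grid
planted_grid <- function(mask, region, timesMs, windowMs) {
  g <- matrix(FALSE, length(mask), length(timesMs))
  g[match(intersect(region, mask), mask),
    timesMs >= windowMs[1] & timesMs < windowMs[2]] <- TRUE
  g
}
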