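# Word-pair association scoring from distributional embeddings: cosine
# similarity between the two words' vectors, a PCA-reduced variant, and the
# high/low/excluded labeling thresholds.

#' Read a GloVe-style embedding table
#'
#' Whitespace text format: one token per line followed by d floating-point
#' values.  All vectors must share the dimension; zero-norm vectors are
#' refused by the class validity.
#'
#' @param path file path.
#' @param sourceTag provenance string stored with the table.
#' @return an \code{\linkS4class{EmbeddingTable}}.
#' @export
readGloveEmbeddings <- function(path, sourceTag = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  dims <- lengths(parts) - 1L
  if (length(unique(dims)) != 1L)
    stop("inconsistent embedding dimensions across lines")
  tokens <- vapply(parts, `[`, character(1), 1L)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(dims[1L])))
  rownames(vecs) <- tokens
  new("EmbeddingTable", vectors = vecs, sourceTag = sourceTag)
}

#' Cosine similarity
#'
#' @param u,v equal-length numeric vectors with non-zero norms.
#' @return \eqn{u \cdot v / (\|u\| \|v\|)} in \[-1, 1\].
#' @export
cosineSimilarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal dimension")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-norm vector")
  sum(u * v) / (nu * nv)
}

lookup_vectors <- function(tokens, table) {
  miss <- setdiff(unique(tokens), rownames(table@vectors))
  if (length(miss))
    stop(sprintf("token(s) not in vocabulary: %s", paste(miss, collapse = ", ")))
  table@vectors[tokens, , drop = FALSE]
}

#' Raw cosine similarity per word pair
#'
#' @param pairs two-column character matrix (or data.frame) of token pairs.
#' @param table an \code{EmbeddingTable}.
#' @return numeric vector of cosines.
#' @export
pairSimilarity <- function(pairs, table) {
  pairs <- as.matrix(pairs)
  u <- lookup_vectors(pairs[, 1L], table)
  v <- lookup_vectors(pairs[, 2L], table)
  vapply(seq_len(nrow(pairs)),
         function(i) cosineSimilarity(u[i, ], v[i, ]), numeric(1))
}

#' PCA-reduced cosine similarity per word pair
#'
#' Principal components are fitted on the centered vectors of the stimulus
#' vocabulary (the distinct tokens appearing in \code{pairs}, by default);
#' cosines are computed in the space of the first \code{nPcs} components.
#'
#' @param pairs two-column character matrix of token pairs.
#' @param table an \code{EmbeddingTable}.
#' @param nPcs number of components (<= embedding dimension and <= number of
#'   distinct fitted tokens).
#' @param fitTokens tokens defining the PCA fitting population (default: all
#'   distinct tokens of \code{pairs}).
#' @return numeric vector of projected cosines.
#' @export
pcaSimilarity <- function(pairs, table, nPcs = 30L, fitTokens = NULL) {
  pairs <- as.matrix(pairs)
  if (is.null(fitTokens)) fitTokens <- unique(as.vector(pairs))
  V <- lookup_vectors(fitTokens, table)
  if (nPcs > ncol(V) || nPcs > length(fitTokens))
    stop("nPcs exceeds the embedding dimension or the fitted vocabulary")
  pc <- prcomp(V, center = TRUE, scale. = FALSE)
  proj <- function(tok) {
    x <- sweep(lookup_vectors(tok, table), 2L, pc$center)
    x %*% pc$rotation[, seq_len(nPcs), drop = FALSE]
  }
  u <- proj(pairs[, 1L]); v <- proj(pairs[, 2L])
  vapply(seq_len(nrow(pairs)),
         function(i) cosineSimilarity(u[i, ], v[i, ]), numeric(1))
}

#' Label word pairs by association strength
#'
#' @param scores cosine per pair (finite).
#' @param params an \code{\link{associationParams}}: scores above
#'   \code{highThreshold} are \code{"high"}, below \code{lowThreshold}
#'   \code{"low"}, the closed band between them \code{"excluded"}.
#' @return character vector of labels.
#' @export
labelPairs <- function(scores, params = associationParams()) {
  if (!all(is.finite(scores))) stop("scores must be finite")
  ifelse(scores > params@highThreshold, "high",
         ifelse(scores < params@lowThreshold, "low", "excluded"))
}

#' Association table for a stimulus list
#'
#' Convenience wrapper producing the per-pair summary: raw cosine, PCA-space
#' cosine, and the high/low/excluded label from the raw cosine.
#'
#' @param pairs two-column character matrix of (word1, word2).
#' @param table an \code{EmbeddingTable}.
#' @param params an \code{\link{associationParams}}.
#' @return data.frame: word1, word2, cosine, pcaCosine, label.
#' @export
associationTable <- function(pairs, table, params = associationParams()) {
  pairs <- as.matrix(pairs)
  raw <- pairSimilarity(pairs, table)
  nP <- min(params@nPcs, ncol(table@vectors), length(unique(as.vector(pairs))))
  data.frame(word1 = pairs[, 1L], word2 = pairs[, 2L], cosine = raw,
             pcaCosine = pcaSimilarity(pairs, table, nP),
             label = labelPairs(raw, params), stringsAsFactors = FALSE)
}
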