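# Array-container format: raw little-endian doubles in <base>.bin plus a
# structured-text (JSON) metadata sidecar <base>.json carrying shape, labels,
# covariates, time axis, schema version and the producing config hash.
# Round-trips are bit-identical; truncated files fail closed.

TRIALS_SCHEMA <- "megstats-trials"
STATRESULT_SCHEMA <- "megstats-statresult"
SCHEMA_VERSION <- 1L

container_paths <- function(path) {
  base <- sub("\\.(json|bin)$", "", path)
  list(json = paste0(base, ".json"), bin = paste0(base, ".bin"))
}

write_container <- function(meta, values, path) {
  p <- container_paths(path)
  meta$nValues <- length(values)
  jsonlite::write_json(meta, p$json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  con <- file(p$bin, "wb")
  on.exit(close(con))
  writeBin(as.numeric(values), con, size = 8L, endian = "little")
  invisible(p)
}

read_container <- function(path, schema, known_fields) {
  p <- container_paths(path)
  if (!file.exists(p$json) || !file.exists(p$bin))
    stop(sprintf("container '%s' is incomplete (missing .json or .bin)", path))
  meta <- jsonlite::read_json(p$json, simplifyVector = TRUE)
  if (!identical(meta$schema, schema))
    stop(sprintf("schema mismatch: expected '%s', found '%s'", schema,
                 meta$schema %||% "<none>"))
  if (!identical(as.integer(meta$version), SCHEMA_VERSION))
    stop(sprintf("unsupported container version '%s'", meta$version))
  extra <- setdiff(names(meta), c(known_fields, "nValues"))
  if (length(extra))
    warning(sprintf("ignoring unknown container field(s): %s",
                    paste(extra, collapse = ", ")))
  n <- as.integer(meta$nValues %||% prod(meta$dims))
  if (file.info(p$bin)$size != 8 * n)
    stop(sprintf("binary payload truncated: expected %d values", n))
  con <- file(p$bin, "rb")
  on.exit(close(con))
  values <- readBin(con, "numeric", n = n, size = 8L, endian = "little")
  list(meta = meta, values = values)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a TrialTensor container
#'
#' @param tensor a \code{TrialTensor}.
#' @param path base path (the \code{.bin}/\code{.json} pair is derived).
#' @param configHash optional provenance hash embedded in the sidecar.
#' @return invisibly, the file paths.
#' @export
writeTrials <- function(tensor, path, configHash = NULL) {
  stopifnot(is(tensor, "TrialTensor"))
  meta <- list(schema = TRIALS_SCHEMA, version = SCHEMA_VERSION,
               dims = dim(tensor@data), condition = tensor@condition,
               subjectId = tensor@subjectId)
  if (!is.null(configHash)) meta$configHash <- configHash
  # all numeric payload lives in the binary file so round-trips are exact:
  # time axis (2), word1/word2 covariates (2 * nTrials), then the tensor
  payload <- c(tensor@timeStartMs, tensor@timeStepMs, tensor@word1LogFreq,
               tensor@word2LogFreq, as.numeric(tensor@data))
  invisible(write_container(meta, payload, path))
}

#' Read a TrialTensor container
#'
#' @param path base path as given to \code{\link{writeTrials}}.
#' @return a \code{TrialTensor}.
#' @export
readTrials <- function(path) {
  known <- c("schema", "version", "dims", "condition", "subjectId",
             "configHash")
  r <- read_container(path, TRIALS_SCHEMA, known)
  d <- r$meta$dims
  n <- d[1L]
  ax <- r$values[1:2]
  w1 <- r$values[2L + seq_len(n)]
  w2 <- r$values[2L + n + seq_len(n)]
  dat <- array(r$values[-(seq_len(2L + 2L * n))], d)
  trialTensor(dat, r$meta$condition, w1, w2, r$meta$subjectId, ax[1L], ax[2L])
}

#' Write a GroundTruth record as structured text
#'
#' JSON serialization of everything the generator planted (effects,
#' couplings, frequency mixing, overlap flag, design), for provenance and
#' recovery scoring.
#'
#' @param truth a \code{GroundTruth}.
#' @param path output file path (JSON).
#' @return invisibly, the path.
#' @export
writeGroundTruth <- function(truth, path) {
  stopifnot(is(truth, "GroundTruth"))
  as_rec <- function(x) {
    sl <- methods::slotNames(class(x))
    stats::setNames(lapply(sl, function(s) methods::slot(x, s)), sl)
  }
  rec <- list(
    design = as_rec(truth@design),
    effects = lapply(truth@effects, as_rec),
    couplings = lapply(truth@couplings, as_rec),
    freqEffect = truth@freqEffect,
    overlapFlag = truth@overlapFlag)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a StatResult container
#'
#' Stores the stat/tfce/p grids with a sidecar recording the tail, the
#' permutation count, grid coordinates and the test's provenance metadata.
#'
#' @param result a \code{StatResult}.
#' @param path base path.
#' @param configHash optional provenance hash.
#' @return invisibly, the file paths.
#' @export
writeStatResult <- function(result, path, configHash = NULL) {
  stopifnot(is(result, "StatResult"))
  meta <- list(schema = STATRESULT_SCHEMA, version = SCHEMA_VERSION,
               dims = c(dim(result@stat), 3L),
               nPermutations = result@nPermutations, tail = result@tail,
               rowValues = result@rowValues, colValues = result@colValues,
               meta = result@meta)
  if (!is.null(configHash)) meta$configHash <- configHash
  invisible(write_container(meta, c(result@stat, result@tfce, result@p), path))
}

#' Read a StatResult container
#'
#' @param path base path as given to \code{\link{writeStatResult}}.
#' @return a \code{StatResult}.
#' @export
readStatResult <- function(path) {
  known <- c("schema", "version", "dims", "nPermutations", "tail",
             "rowValues", "colValues", "meta", "configHash")
  r <- read_container(path, STATRESULT_SCHEMA, known)
  d <- r$meta$dims
  arr <- array(r$values, d)
  slab <- function(k) matrix(arr[, , k], d[1L], d[2L])
  new("StatResult", stat = slab(1L), tfce = slab(2L), p = slab(3L),
      nPermutations = as.integer(r$meta$nPermutations), tail = r$meta$tail,
      rowValues = as.numeric(r$meta$rowValues),
      colValues = as.numeric(r$meta$colValues),
      meta = as.list(r$meta$meta))
}
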