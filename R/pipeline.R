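# End-to-end pipeline driver: simulate -> regress -> decode -> connect, with
# shared preprocessing (frequency regress-out + decimation) applied exactly
# once, full provenance logging, and deterministic reruns under a fixed
# config.

#' Hash of a run configuration
#'
#' Canonical-JSON MD5 digest embedded in every output sidecar so results can
#' be traced to the exact configuration that produced them.
#'
#' @param config configuration list.
#' @return hex digest string.
#' @export
configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Read and validate a run configuration
#'
#' YAML run configurations must name an output directory and an explicit
#' seed for every stochastic stage (simulate, regression, decoding,
#' connectivity); configurations without them are refused at validation.
#'
#' @param path YAML file path (or an already-parsed list).
#' @return validated configuration list.
#' @export
readRunConfig <- function(path) {
  config <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(config$outdir)) stop("config must name an outdir")
  needed <- c("simulate", "regression", "decoding", "connectivity")
  have <- names(config$seeds %||% list())
  miss <- setdiff(needed, have)
  if (length(miss))
    stop(sprintf("config missing seed(s) for stage(s): %s",
                 paste(miss, collapse = ", ")))
  config
}

pipeline_log <- function(state, ...) {
  line <- sprintf(...)
  message("[megstats] ", line)
  state$log <- c(state$log, line)
  state
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> mass regression -> searchlight decoding ->
#' directed connectivity on one configuration.  Preprocessing for the
#' multivariate stages (frequency regress-out, temporal decimation) runs
#' exactly once and is shared by decoding and connectivity.  All stochastic
#' stages draw only from the config's named seeds, so a rerun with the same
#' config reproduces every output bit-for-bit.  Outputs (containers, cluster
#' summaries, a provenance log recording seeds, parameters, package version
#' and the config hash) are written under \code{config$outdir}.
#'
#' @param config list or YAML path accepted by \code{\link{readRunConfig}}.
#' @return invisibly, a report list: output manifest, cluster summaries per
#'   inference, and the provenance record.
#' @export
runPipeline <- function(config) {
  config <- readRunConfig(config)
  hash <- configHash(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  state <- list(log = character(0))
  manifest <- character(0)
  inferences <- list()
  stage <- "setup"
  report <- tryCatch({
    # ---- source space -------------------------------------------------
    sp <- config$space
    regions <- lapply(sp$regions, function(r) unlist(r))
    space <- latticeSourceSpace(sp$nrow, sp$ncol, regions = regions)
    mask <- regionMask(space, sp$analysisMask)

    # ---- simulate -----------------------------------------------------
    stage <- "simulate"
    sim <- config$simulate
    design <- designSpec(nSubjects = sim$nSubjects,
                         trialsPerCondition = sim$trialsPerCondition,
                         sampleRateHz = sim$sampleRateHz %||% 1000)
    effects <- lapply(sim$effects, function(e)
      plantedEffect(e$predictor, regionMask(space, e$region),
                    unlist(e$windowMs), e$amplitude,
                    effectForm = e$form %||% "univariate-amplitude",
                    patternSeed = e$patternSeed %||% 1L))
    couplings <- lapply(sim$couplings, function(cp)
      couplingSpec(cp$sourceRegion, cp$targetRegion, cp$lagMs, cp$gain,
                   unlist(cp$windowMs)))
    noise <- noiseSpec(sensorSd = sim$noise$sensorSd %||% 1,
                       spatialCorrLength = sim$noise$spatialCorrLength %||% 2,
                       subjectSd = sim$noise$subjectSd %||% 0.2,
                       temporalSmoothingMs = sim$noise$temporalSmoothingMs %||% 20)
    freq <- if (!is.null(sim$freqEffect))
      freqEffectSpec(regionMask(space, sim$freqEffect$region),
                     slope1 = sim$freqEffect$slope1 %||% -0.5,
                     slope2 = sim$freqEffect$slope2 %||% -0.5)
    else NULL
    ds <- simulateDataset(design, space, effects, couplings, noise,
                          seed = config$seeds$simulate, freqEffect = freq)
    state <- pipeline_log(state, "simulated %d subjects (%d trials each)",
                          length(ds$tensors), dim(ds$tensors[[1]]@data)[1])
    for (s in seq_along(ds$tensors)) {
      p <- file.path(outdir, sprintf("trials_%02d", s))
      writeTrials(ds$tensors[[s]], p, configHash = hash)
      manifest <- c(manifest, paste0(p, c(".json", ".bin")))
    }
    gt_path <- file.path(outdir, "ground_truth.json")
    writeGroundTruth(ds$truth, gt_path)
    manifest <- c(manifest, gt_path)

    # ---- shared preprocessing (once) ---------------------------------
    stage <- "preprocess"
    dec_factor <- config$preprocess$decimate %||% 5L
    prep <- lapply(ds$tensors, function(tt)
      decimateTrials(regressOutFrequency(tt), dec_factor))
    state <- pipeline_log(state,
                          "preprocessed: frequency regressed out, decimated x%d",
                          dec_factor)

    # ---- mass regression ---------------------------------------------
    stage <- "regress"
    rg <- config$regression
    betas <- massRegression(ds$tensors, mask, unlist(rg$windowMs))
    summaries <- list()
    for (k in seq_along(rg$predictors)) {
      pred <- rg$predictors[[k]]
      res <- secondStage(betas, pred, space, tfceParams(),
                         nPerm = rg$nPerm,
                         seed = derive_seed(config$seeds$regression, k))
      pth <- file.path(outdir, sprintf("regression_%s", pred))
      writeStatResult(res, pth, configHash = hash)
      manifest <- c(manifest, paste0(pth, c(".json", ".bin")))
      cl <- significantClusters(res, induced_edges(adjacency(space), mask),
                                alpha = rg$alpha %||% 0.05)
      summaries[[pred]] <- cl
      inferences[[length(inferences) + 1L]] <-
        list(stage = "regression", predictor = pred, test = "one-sample t",
             tail = res@tail, nPerm = res@nPermutations, correction = "max")
      state <- pipeline_log(state,
                            "regression '%s': %d significant cluster(s)",
                            pred, nrow(cl))
    }

    # ---- searchlight decoding ----------------------------------------
    stage <- "decode"
    dc <- config$decoding
    sl <- searchlightSpec(space, mask, unlist(dc$windowMs),
                          tensorTimes(prep[[1]]),
                          nSourcesPerLight = dc$nSourcesPerLight %||% 100L,
                          nTimepointsPerLight = dc$nTimepointsPerLight %||% 5L,
                          sourceStride = dc$sourceStride %||% 1L,
                          timeStride = dc$timeStride %||% 1L)
    maps <- groupSearchlight(prep, sl, DECODING_PAIRS,
                             nPseudo = dc$nPseudo %||% 15L,
                             nReps = dc$nReps %||% 100L,
                             seed = config$seeds$decoding)
    dec_results <- list()
    for (pi in seq_along(maps)) {
      res <- groupDecodingTest(maps[[pi]], space, mask, tfceParams(),
                               nPerm = dc$nPerm,
                               seed = derive_seed(config$seeds$decoding,
                                                  100L + pi))
      nm <- paste(maps[[pi]]@pair, collapse = "_")
      pth <- file.path(outdir, sprintf("decoding_%s", nm))
      writeStatResult(res, pth, configHash = hash)
      manifest <- c(manifest, paste0(pth, c(".json", ".bin")))
      dec_results[[nm]] <- res
      inferences[[length(inferences) + 1L]] <-
        list(stage = "decoding", pair = nm, test = "one-sample t vs 0.5",
             tail = res@tail, nPerm = res@nPermutations, correction = "max")
      state <- pipeline_log(state, "decoding %s: min p = %.4g", nm,
                            min(res@p))
    }

    # ---- directed connectivity ---------------------------------------
    stage <- "connect"
    cn <- config$connectivity
    roiA <- regionMask(space, cn$roiA)
    roiB <- regionMask(space, cn$roiB)
    ab <- vector("list", length(prep)); ba <- vector("list", length(prep))
    for (s in seq_along(prep)) {
      sseed <- derive_seed(config$seeds$connectivity, s)
      rA <- computeRDMSeries(prep[[s]], roiA, "condition",
                             nPseudo = cn$nPseudo %||% 15L, seed = sseed,
                             regionLabel = cn$roiA)
      rB <- computeRDMSeries(prep[[s]], roiB, "condition",
                             nPseudo = cn$nPseudo %||% 15L,
                             seed = derive_seed(sseed, 2L),
                             regionLabel = cn$roiB)
      ab[[s]] <- directedFlow(rA, rB, unlist(cn$tWindowMs),
                              dtMinMs = cn$dtStepMs %||% 5,
                              dtMaxMs = cn$dtMaxMs %||% 600,
                              dtStepMs = cn$dtStepMs %||% 5)
      ba[[s]] <- directedFlow(rB, rA, unlist(cn$tWindowMs),
                              dtMinMs = cn$dtStepMs %||% 5,
                              dtMaxMs = cn$dtMaxMs %||% 600,
                              dtStepMs = cn$dtStepMs %||% 5)
    }
    conn <- directionContrastTest(ab, ba, tfceParams(), nPerm = cn$nPerm,
                                  seed = derive_seed(config$seeds$connectivity,
                                                     999L))
    pth <- file.path(outdir, "connectivity_contrast")
    writeStatResult(conn, pth, configHash = hash)
    manifest <- c(manifest, paste0(pth, c(".json", ".bin")))
    inferences[[length(inferences) + 1L]] <-
      list(stage = "connectivity",
           direction = conn@meta$direction, test = "one-sample t",
           tail = conn@tail, nPerm = conn@nPermutations, correction = "max")
    state <- pipeline_log(state, "connectivity contrast: min p = %.4g",
                          min(conn@p))

    # ---- provenance ---------------------------------------------------
    stage <- "provenance"
    prov <- list(configHash = hash,
                 packageVersion =
                   as.character(utils::packageVersion("megstats")),
                 seeds = config$seeds, inferences = inferences,
                 log = state$log)
    prov_path <- file.path(outdir, "provenance.json")
    jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    manifest <- c(manifest, prov_path)
    # human-readable cluster summary (extent, window, peak)
    sum_path <- file.path(outdir, "summary.txt")
    con <- file(sum_path, "w")
    for (pred in names(summaries)) {
      cl <- summaries[[pred]]
      writeLines(sprintf("regression '%s': %d significant cluster(s)",
                         pred, nrow(cl)), con)
      if (nrow(cl) > 0) {
        writeLines(sprintf(
          "  cluster %d: %d points over %d sources, %g-%g ms, peak t = %.2f, min p = %.4g",
          cl$cluster, cl$nPoints, cl$nRows, cl$windowStart, cl$windowEnd,
          cl$peakStat, cl$minP), con)
      }
    }
    close(con)
    manifest <- c(manifest, sum_path)
    list(manifest = manifest, clusters = summaries, provenance = prov)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s [partial outputs: %s]",
                 stage, conditionMessage(e),
                 if (length(manifest)) paste(manifest, collapse = ", ")
                 else "<none>"), call. = FALSE)
  })
  invisible(report)
}
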