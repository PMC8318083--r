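# Searchlight decoding: preprocessing operators, pseudo-trial partitioning,
# the pairwise classifier, and the group test against chance.

test_that("regressOutFrequency removes only the frequency contribution", {
  sp <- test_space()
  des <- designSpec(nSubjects = 1, trialsPerCondition = 5, sampleRateHz = 50)
  # no planted frequency signal, noiseless: residuals equal the input
  ef <- plantedEffect("composition", regionMask(sp, "B"), c(700, 1000), 1)
  ds <- simulateDataset(des, sp, effects = list(ef),
                        noise = noiseSpec(sensorSd = 0, subjectSd = 0),
                        seed = 20)
  tt <- ds$tensors[[1]]
  expect_equal(trialData(regressOutFrequency(tt)), trialData(tt),
               tolerance = 1e-10)

  # pure frequency signal: residual condition-mean differences vanish
  ds2 <- simulateDataset(des, sp, noise = noiseSpec(sensorSd = 0,
                                                    subjectSd = 0),
                         seed = 21,
                         freqEffect = freqEffectSpec(regionMask(sp, "mask"),
                                                     slope1 = -0.5,
                                                     slope2 = -0.9))
  r2 <- regressOutFrequency(ds2$tensors[[1]])
  cm <- function(x, cl) apply(trialData(x)[conditions(x) == cl, , ,
                                           drop = FALSE], c(2, 3), mean)
  dd <- cm(r2, "HA-comp") - cm(r2, "LA-list")
  expect_lt(max(abs(dd)), 0.05)

  # refitting the design on the residualized data leaves no frequency signal
  ds3 <- simulateDataset(des, sp, noise = noiseSpec(), seed = 22,
                         freqEffect = freqEffectSpec(regionMask(sp, "mask")))
  tt3 <- ds3$tensors[[1]]
  r3 <- regressOutFrequency(tt3)
  X3 <- buildDesign(conditions(tt3), tt3@word1LogFreq, tt3@word2LogFreq)
  Y <- matrix(trialData(r3), nrow = dim(trialData(r3))[1])
  B3 <- qr.coef(qr(X3), Y)
  expect_lt(max(abs(B3[c("word1_logfreq", "word2_logfreq"), ])), 1e-8)

  tt3@word2LogFreq <- rep(1, length(tt3@word2LogFreq))
  expect_error(regressOutFrequency(tt3), "constant frequency")
})

test_that("decimation lengths, identity and constancy", {
  arr <- array(rnorm(2 * 3 * 1300), c(2, 3, 1300))
  tt <- quick_tensor(arr, condition = c("HA-comp", "LA-comp"),
                     w1 = c(1, 2), w2 = c(2, 1), startMs = -100, stepMs = 1)
  d5 <- decimateTrials(tt, 5)
  expect_equal(dim(trialData(d5))[3], 260)
  expect_equal(unname(timeAxis(d5)["stepMs"]), 5)
  expect_equal(trialData(decimateTrials(tt, 1)), arr)
  const <- quick_tensor(array(3, c(2, 3, 10)),
                        condition = c("HA-comp", "LA-comp"),
                        w1 = c(1, 2), w2 = c(2, 1))
  expect_true(all(trialData(decimateTrials(const, 3)) == 3))
  expect_equal(dim(trialData(decimateTrials(const, 3)))[3], 4)
  expect_error(decimateTrials(const, 11), "exceeds")
  # block-mean variant preserves a constant signal too
  expect_true(all(trialData(decimateTrials(const, 3, "mean")) == 3))
})

test_that("pseudo-trial partitions: block sizes, means, determinism", {
  arr60 <- array(rnorm(60 * 4 * 3), c(60, 4, 3))
  ps <- makePseudotrials(arr60, 15, seed = 30)
  expect_equal(dim(ps), c(15, 4, 3))
  # 60 trials over 15 blocks of 4: the pseudo-trial mean equals the trial mean
  expect_equal(apply(ps, c(2, 3), mean), apply(arr60, c(2, 3), mean),
               tolerance = 1e-12)
  arr45 <- array(rnorm(45 * 4 * 3), c(45, 4, 3))
  ps45 <- makePseudotrials(arr45, 15, seed = 30)
  expect_equal(apply(ps45, c(2, 3), mean), apply(arr45, c(2, 3), mean),
               tolerance = 1e-12)
  expect_identical(makePseudotrials(arr60, 15, seed = 7),
                   makePseudotrials(arr60, 15, seed = 7))
  expect_error(makePseudotrials(array(0, c(10, 2, 2)), 15), "fewer")
  # remainder round-robin: 17 trials into 5 blocks -> sizes 4,4,3,3,3
  blocks <- megstats:::with_seed(1, megstats:::partition_blocks(17, 5))
  expect_equal(sort(lengths(blocks), decreasing = TRUE), c(4, 4, 3, 3, 3))
  expect_equal(sort(unlist(blocks)), 1:17)
})

test_that("decodePair separates separable classes and stays at chance otherwise", {
  set.seed(40)
  # well-separated Gaussian patterns
  mu <- rnorm(30, 0, 2)
  fa <- matrix(rnorm(30 * 30, rep(mu, each = 30), 0.5), 30)
  fb <- matrix(rnorm(30 * 30, rep(-mu, each = 30), 0.5), 30)
  expect_gte(decodePair(fa, fb, nPseudo = 10, nReps = 20, seed = 1), 0.95)

  # identical class distributions: accuracy centered at chance
  accs <- vapply(1:15, function(r) {
    fa <- matrix(rnorm(24 * 12), 24)
    fb <- matrix(rnorm(24 * 12), 24)
    decodePair(fa, fb, nPseudo = 8, nReps = 12, seed = r)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.06)

  expect_warning(a0 <- decodePair(matrix(1, 10, 4), matrix(1, 10, 4),
                                  nPseudo = 5, nReps = 5, seed = 2),
                 "constant")
  expect_equal(a0, 0.5)
})

test_that("decoding accuracy is invariant to global data scaling", {
  set.seed(41)
  mu <- rnorm(12)
  fa <- matrix(rnorm(20 * 12, rep(mu, each = 20), 1), 20)
  fb <- matrix(rnorm(20 * 12, rep(-mu, each = 20), 1), 20)
  a1 <- decodePair(fa, fb, nPseudo = 10, nReps = 10, seed = 3)
  a2 <- decodePair(100 * fa, 100 * fb, nPseudo = 10, nReps = 10, seed = 3)
  expect_equal(a1, a2, tolerance = 1e-8)
})

test_that("searchlight neighborhoods tile deterministically and stay in the mask", {
  sp <- test_space()
  mask <- regionMask(sp, "mask")
  s1 <- searchlightSpec(sp, mask, c(600, 1200), seq(-100, 1195, by = 20),
                        nSourcesPerLight = 10, nTimepointsPerLight = 3,
                        sourceStride = 5, timeStride = 4)
  s2 <- searchlightSpec(sp, mask, c(600, 1200), seq(-100, 1195, by = 20),
                        nSourcesPerLight = 10, nTimepointsPerLight = 3,
                        sourceStride = 5, timeStride = 4)
  expect_identical(s1@neighborhoods, s2@neighborhoods)
  expect_true(all(unlist(s1@neighborhoods) %in% mask))
  expect_true(all(lengths(s1@neighborhoods) == 10))
  expect_true(all(s1@centerTimesMs >= 600 & s1@centerTimesMs < 1200))
  # k nearest by hops with index tie-break, center included
  nb <- graphNeighborhood(sp, mask[1], 4)
  expect_true(mask[1] %in% nb)
  expect_equal(length(nb), 4)
})

test_that("searchlight recovery: planted pattern found in its region and pair", {
  sp <- test_space()
  mask <- regionMask(sp, "mask")
  ef <- plantedEffect("HA-comp_vs_LA-comp", regionMask(sp, "A"),
                      c(600, 1200), 0.9, "multivariate-pattern", 5)
  ds <- simulateDataset(designSpec(nSubjects = 6, trialsPerCondition = 16,
                                   sampleRateHz = 100),
                        sp, effects = list(ef), noise = noiseSpec(), seed = 42)
  prep <- lapply(ds$tensors, function(tt)
    decimateTrials(regressOutFrequency(tt), 2))
  sl <- searchlightSpec(sp, mask, c(600, 1200), tensorTimes(prep[[1]]),
                        nSourcesPerLight = 12, nTimepointsPerLight = 3,
                        sourceStride = 6, timeStride = 10)
  maps <- groupSearchlight(prep, sl, DECODING_PAIRS, nPseudo = 8, nReps = 4,
                           seed = 43)
  inA <- maps[[3]]@spec@centerSources %in% regionMask(sp, "A")
  # centers whose whole neighborhood avoids the planted region
  far <- !vapply(maps[[3]]@spec@neighborhoods,
                 function(nb) any(nb %in% regionMask(sp, "A")), logical(1))
  # the planted pair decodes in region-A centers, not in disjoint ones
  expect_gt(mean(maps[[3]]@accuracy[, inA, ]), 0.8)
  expect_lt(abs(mean(maps[[3]]@accuracy[, far, ]) - 0.5), 0.08)
  # the untouched pair stays at chance everywhere
  expect_lt(abs(mean(maps[[4]]@accuracy) - 0.5), 0.08)
  # determinism
  one <- searchlightDecode(prep[[1]], sl, DECODING_PAIRS[3], nPseudo = 8,
                           nReps = 2, seed = 44)
  two <- searchlightDecode(prep[[1]], sl, DECODING_PAIRS[3], nPseudo = 8,
                           nReps = 2, seed = 44)
  expect_identical(one, two)
})

test_that("group decoding test: chance maps give nothing, below-chance never fires", {
  sp <- test_space()
  mask <- regionMask(sp, "mask")
  sl <- searchlightSpec(sp, mask, c(600, 1200), seq(-100, 1195, by = 20),
                        nSourcesPerLight = 8, nTimepointsPerLight = 3,
                        sourceStride = 8, timeStride = 6)
  nC <- length(sl@centerSources); nT <- length(sl@centerTimesMs)
  flat <- new("AccuracyMap", accuracy = array(0.5, c(6, nC, nT)),
              pair = c("HA-comp", "LA-comp"), chance = 0.5, spec = sl,
              nReps = 10L)
  r0 <- groupDecodingTest(flat, sp, mask, nPerm = 99, seed = 50)
  expect_true(all(pValues(r0) == 1))
  below <- new("AccuracyMap",
               accuracy = array(runif(6 * nC * nT, 0.2, 0.45), c(6, nC, nT)),
               pair = c("HA-comp", "LA-comp"), chance = 0.5, spec = sl,
               nReps = 10L)
  rb <- groupDecodingTest(below, sp, mask, nPerm = 99, seed = 51)
  expect_true(all(pValues(rb) > 0.05))
  expect_identical(rb@tail, "one-sided-positive")
})
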