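# Two-stage mass regression: design coding, first-stage identities,
# second-stage inference, and covariate protection.

test_that("buildDesign codes the factors with the single-word origin", {
  cond <- rep(c("HA-comp", "LA-comp", "HA-list", "LA-list", "single"), 3)
  X <- buildDesign(cond, rnorm(15), rnorm(15))
  expect_identical(colnames(X),
                   c("intercept", "association", "composition", "interaction",
                     "n_words", "word1_logfreq", "word2_logfreq"))
  fac <- c("association", "composition", "interaction", "n_words")
  expect_equal(unname(X[which(cond == "HA-comp")[1], fac]), c(1, 1, 1, 1))
  expect_equal(unname(X[which(cond == "single")[1], fac]), c(0, 0, 0, 0))
  expect_equal(unname(X[which(cond == "LA-list")[1], fac]), c(0, 0, 0, 1))
  expect_equal(unname(X[which(cond == "LA-comp")[1], fac]), c(0, 1, 0, 1))
  # interaction column is the elementwise product
  expect_equal(X[, "interaction"], X[, "association"] * X[, "composition"])
  # covariates centered
  expect_equal(sum(X[, "word1_logfreq"]), 0, tolerance = 1e-12)
  expect_error(buildDesign(c("HA-comp", "weird"), rnorm(2), rnorm(2)),
               "weird")
})

test_that("balanced designs give an interaction column orthogonal to the intercept after centering", {
  cond <- rep(c("HA-comp", "LA-comp", "HA-list", "LA-list", "single"),
              each = 6)
  X <- buildDesign(cond, rnorm(30), rnorm(30), coding = "effect")
  # under +/-0.5 coding a balanced design makes the interaction column sum to
  # zero, i.e. orthogonal to the intercept
  expect_equal(sum(X[, "interaction"]), 0, tolerance = 1e-12)
  # dummy coding: centering the column achieves the same orthogonality
  Xd <- buildDesign(cond, rnorm(30), rnorm(30))
  ic <- Xd[, "interaction"] - mean(Xd[, "interaction"])
  expect_equal(sum(ic * Xd[, "intercept"]), 0, tolerance = 1e-12)
})

test_that("first stage recovers planted coefficients exactly in noiseless data", {
  sp <- test_space()
  a <- 1.8
  ef <- plantedEffect("interaction", regionMask(sp, "A"), c(640, 760), a)
  ds <- simulateDataset(designSpec(nSubjects = 1, trialsPerCondition = 4,
                                   sampleRateHz = 100),
                        sp, effects = list(ef),
                        noise = noiseSpec(sensorSd = 0, subjectSd = 0),
                        seed = 10)
  tt <- ds$tensors[[1]]
  mask <- regionMask(sp, "mask")
  X <- buildDesign(conditions(tt), tt@word1LogFreq, tt@word2LogFreq)
  B <- firstStage(tt, X, mask, c(0, 1200))
  times <- attr(B, "timesMs")
  win <- times >= 640 & times < 760
  inA <- match(regionMask(sp, "A"), mask)
  expect_equal(max(abs(B["interaction", inA, win] - a)), 0, tolerance = 1e-9)
  off <- B["interaction", , ]
  off[inA, win] <- 0
  expect_lt(max(abs(off)), 1e-9)
  # the planted-contrast estimate is coding-invariant
  Xe <- buildDesign(conditions(tt), tt@word1LogFreq, tt@word2LogFreq,
                    coding = "effect")
  Be <- firstStage(tt, Xe, mask, c(0, 1200))
  expect_equal(Be["interaction", inA, win], B["interaction", inA, win],
               tolerance = 1e-9)
})

test_that("first stage is linear in the data and row-exchange invariant", {
  sp <- test_space()
  ds <- simulateDataset(designSpec(nSubjects = 1, trialsPerCondition = 3,
                                   sampleRateHz = 50),
                        sp, effects = list(
                          plantedEffect("association", regionMask(sp, "A"),
                                        c(200, 600), 0.7)),
                        noise = noiseSpec(subjectSd = 0), seed = 11)
  tt <- ds$tensors[[1]]
  mask <- regionMask(sp, "mask")
  X <- buildDesign(conditions(tt), tt@word1LogFreq, tt@word2LogFreq)
  B1 <- firstStage(tt, X, mask, c(0, 600))
  tt3 <- tt; tt3@data <- tt@data * 3
  expect_equal(firstStage(tt3, X, mask, c(0, 600)), 3 * B1,
               tolerance = 1e-10, ignore_attr = TRUE)
  perm <- sample(dim(tt@data)[1])
  ttp <- trialTensor(tt@data[perm, , ], conditions(tt)[perm],
                     tt@word1LogFreq[perm], tt@word2LogFreq[perm],
                     subjectId(tt), tt@timeStartMs, tt@timeStepMs)
  Bp <- firstStage(ttp, X[perm, ], mask, c(0, 600))
  expect_equal(Bp, B1, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("second stage: null input, planted recovery, sign symmetry", {
  sp <- test_space()
  mask <- regionMask(sp, "mask")
  # all-zero betas: nothing significant
  bs0 <- new("BetaStack", beta = array(0, c(6, 2, 10, 5)),
             predictors = c("intercept", "interaction"),
             subjects = sprintf("S%d", 1:6), sources = mask[1:10],
             timesMs = seq(0, 40, by = 10))
  r0 <- secondStage(bs0, "interaction", sp, nPerm = 99, seed = 1)
  expect_true(all(pValues(r0) == 1))
  expect_error(secondStage(bs0, "composition", sp, nPerm = 99, seed = 1),
               "not in the BetaStack")

  # planted interaction recovered where planted, nowhere else
  ds <- simulateDataset(designSpec(nSubjects = 10, trialsPerCondition = 8,
                                   sampleRateHz = 100),
                        sp, effects = list(
                          plantedEffect("interaction", regionMask(sp, "A"),
                                        c(640, 760), 1.6)),
                        noise = noiseSpec(), seed = 12)
  bs <- massRegression(ds$tensors, mask, c(0, 1200))
  res <- secondStage(bs, "interaction", sp, nPerm = 200, seed = 13)
  sig <- significantPoints(res)
  planted <- planted_grid(mask, regionMask(sp, "A"), bs@timesMs, c(640, 760))
  expect_gte(diceOverlap(sig, planted), 0.5)
  expect_gt(mean(statMap(res)[sig]), 0)

  # negating every subject's betas negates the map, two-sided p unchanged
  bsn <- bs; bsn@beta <- -bs@beta
  resn <- secondStage(bsn, "interaction", sp, nPerm = 200, seed = 13)
  expect_equal(statMap(resn), -statMap(res), tolerance = 1e-10)
  expect_equal(pValues(resn), pValues(res), tolerance = 1e-12)
})

test_that("frequency covariates protect condition coefficients from a nuisance signal", {
  sp <- test_space()
  des <- designSpec(nSubjects = 6, trialsPerCondition = 8, sampleRateHz = 50)
  ef <- plantedEffect("composition", regionMask(sp, "B"), c(700, 1000), 1)
  mk <- function(freq) simulateDataset(
    des, sp, effects = list(ef), noise = noiseSpec(sensorSd = 0.3),
    seed = 14, freqEffect = freq)
  clean <- mk(NULL)
  noisy <- mk(freqEffectSpec(regionMask(sp, "B"), slope1 = -0.6,
                             slope2 = -0.8, window2Ms = c(700, 1000)))
  mask <- regionMask(sp, "B")
  b1 <- massRegression(clean$tensors, mask, c(700, 1000))
  b2 <- massRegression(noisy$tensors, mask, c(700, 1000))
  j <- match("composition", b1@predictors)
  k <- match("word2_logfreq", b1@predictors)
  # frequency beta moves to the planted slope; composition beta does not move
  expect_equal(mean(b2@beta[, k, , ]), -0.8, tolerance = 0.05)
  expect_equal(mean(b2@beta[, j, , ]), mean(b1@beta[, j, , ]),
               tolerance = 0.05)
})

test_that("significantClusters reports extent, window and peak", {
  sp <- test_space()
  mask <- regionMask(sp, "mask")
  ds <- simulateDataset(designSpec(nSubjects = 8, trialsPerCondition = 8,
                                   sampleRateHz = 100),
                        sp, effects = list(
                          plantedEffect("interaction", regionMask(sp, "A"),
                                        c(640, 760), 2)),
                        noise = noiseSpec(), seed = 15)
  bs <- massRegression(ds$tensors, mask, c(0, 1200))
  res <- secondStage(bs, "interaction", sp, nPerm = 200, seed = 16)
  cl <- significantClusters(res, induced_edges_for_test(sp, mask))
  expect_gt(nrow(cl), 0)
  expect_true(all(cl$minP <= 0.05))
  expect_gte(cl$windowStart[1], 600)
  expect_lte(cl$windowEnd[1], 800)
  expect_gt(cl$peakStat[1], 0)
})
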