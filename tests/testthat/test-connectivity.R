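# RDM series, lagged partial-correlation flow, and the direction contrast.

# tensor whose four two-word conditions carry fixed 4-source patterns,
# constant over trials and time
pattern_tensor <- function(patterns, n_trials = 4, n_time = 6) {
  conds <- rep(names(patterns), each = n_trials)
  arr <- array(0, c(length(conds), 4, n_time))
  for (i in seq_along(conds)) arr[i, , ] <- patterns[[conds[i]]]
  trialTensor(arr, conds, rnorm(length(conds)), rnorm(length(conds)),
              "T01", 0, 10)
}

test_that("RDM entries follow 1 - Pearson r on hand-computed patterns", {
  pats <- list("HA-comp" = c(1, 2, 3, 4),
               "LA-comp" = c(2, 4, 6, 8),          # identical direction: r = 1
               "HA-list" = c(4, 3, 2, 1),          # reversed: r = -1 vs first
               "LA-list" = c(1, 3, 2, 5))
  tt <- pattern_tensor(pats)
  rs <- computeRDMSeries(tt, 1:4, "condition", nPseudo = 2, seed = 1)
  # pair order: (1,2) (1,3) (1,4) (2,3) (2,4) (3,4) over the condition order
  expect_equal(rs@itemLabels, c("HA-comp", "LA-comp", "HA-list", "LA-list"))
  hand <- function(a, b) 1 - cor(a, b)
  expect_equal(rs@rdm[1, 1], 0, tolerance = 1e-12)           # identical
  expect_equal(rs@rdm[2, 1], 2, tolerance = 1e-12)           # opposite
  expect_equal(rs@rdm[3, 1], hand(pats[[1]], pats[[4]]), tolerance = 1e-12)
  expect_equal(rs@rdm[4, 1], hand(pats[[2]], pats[[3]]), tolerance = 1e-12)
  expect_equal(rs@rdm[6, 1], hand(pats[[3]], pats[[4]]), tolerance = 1e-12)
  # constant over time here
  expect_equal(rs@rdm[, 3], rs@rdm[, 1], tolerance = 1e-12)
  expect_error(computeRDMSeries(tt, 1:2, "condition", nPseudo = 2, seed = 1),
               "at least 3")
})

test_that("constant item patterns are imputed with a warning", {
  pats <- list("HA-comp" = c(0, 0, 0, 0), "LA-comp" = c(1, 2, 1, 3),
               "HA-list" = c(2, 1, 0, 4), "LA-list" = c(5, 1, 2, 0))
  tt <- pattern_tensor(pats)
  expect_warning(rs <- computeRDMSeries(tt, 1:4, "condition", nPseudo = 2,
                                        seed = 1),
                 "constant item pattern")
  expect_equal(rs@rdm[1, 1], 1)  # imputed as zero correlation
})

test_that("RDMs and flow grids are invariant to positive rescaling", {
  sp <- test_space()
  ds <- simulateDataset(designSpec(nSubjects = 1, trialsPerCondition = 6,
                                   sampleRateHz = 100),
                        sp, effects = list(
                          plantedEffect("condition-patterns",
                                        regionMask(sp, "A"), c(600, 1200), 1,
                                        "multivariate-pattern", 9)),
                        noise = noiseSpec(sensorSd = 0.3, subjectSd = 0),
                        seed = 60)
  tt <- ds$tensors[[1]]
  tts <- tt; tts@data <- tt@data * 4.2
  r1 <- computeRDMSeries(tt, regionMask(sp, "A"), "condition",
                         nPseudo = 3, seed = 2)
  r2 <- computeRDMSeries(tts, regionMask(sp, "A"), "condition",
                         nPseudo = 3, seed = 2)
  expect_equal(r1@rdm, r2@rdm, tolerance = 1e-12)
  # pseudo-trial granularity exposed as well
  rp <- computeRDMSeries(tt, regionMask(sp, "A"), "pseudo-trial",
                         nPseudo = 3, seed = 2)
  expect_equal(nrow(rp@rdm), choose(12, 2))
})

test_that("directedFlow: degenerate target, planted lag, role symmetry", {
  set.seed(61)
  times <- seq(0, 590, by = 10)
  nT <- length(times)
  mkseries <- function(m, label) new("RDMSeries", region = label, rdm = m,
                                     itemLabels = paste0("c", 1:4),
                                     timesMs = times)
  # constant target RDM: zero grid by the undefined-as-zero convention
  src <- mkseries(matrix(runif(6 * nT, 0, 2), 6), "A")
  dst0 <- mkseries(matrix(1, 6, nT), "B")
  expect_warning(f0 <- directedFlow(src, dst0, c(300, 590), 10, 100, 10),
                 NA)
  expect_true(all(f0@pc == 0, na.rm = TRUE))

  # dst is an exact lag-L copy of src plus jitter: pc peaks at dt = L
  L <- 5  # samples of 10 ms
  clamp2 <- function(m) pmin(pmax(m, 0), 2)
  peaks <- vapply(1:8, function(r) {
    A <- matrix(runif(6 * nT, 0.3, 1.7), 6)
    B <- clamp2(cbind(matrix(runif(6 * L, 0.3, 1.7), 6),
                      A[, 1:(nT - L)]) + matrix(rnorm(6 * nT, 0, 0.15), 6))
    fl <- directedFlow(mkseries(A, "A"), mkseries(B, "B"),
                       c(300, 590), 10, 150, 10)
    mean_by_dt <- rowMeans(fl@pc, na.rm = TRUE)
    fl@dtMs[which.max(mean_by_dt)]
  }, numeric(1))
  expect_gte(mean(peaks == 50), 0.8)

  # swapping src and dst swaps the causal roles, not the axes
  A <- matrix(runif(6 * nT, 0, 2), 6); B <- matrix(runif(6 * nT, 0, 2), 6)
  fab <- directedFlow(mkseries(A, "A"), mkseries(B, "B"), c(300, 590))
  fba <- directedFlow(mkseries(B, "B"), mkseries(A, "A"), c(300, 590))
  expect_identical(dim(fab@pc), dim(fba@pc))
  expect_identical(fab@direction, c("A", "B"))
  expect_identical(fba@direction, c("B", "A"))
  expect_false(isTRUE(all.equal(fab@pc, fba@pc)))
})

test_that("direction contrast is antisymmetric and null when directions match", {
  set.seed(62)
  times <- seq(0, 290, by = 10)
  mk <- function(m, lab) new("RDMSeries", region = lab, rdm = m,
                             itemLabels = paste0("c", 1:4), timesMs = times)
  ab <- list(); ba <- list()
  for (s in 1:6) {
    A <- matrix(runif(6 * length(times), 0, 2), 6)
    B <- matrix(runif(6 * length(times), 0, 2), 6)
    ab[[s]] <- directedFlow(mk(A, "A"), mk(B, "B"), c(150, 290), 10, 100, 10)
    ba[[s]] <- directedFlow(mk(B, "B"), mk(A, "A"), c(150, 290), 10, 100, 10)
  }
  # identical lists in both roles: contrast exactly zero, nothing significant
  r0 <- directionContrastTest(ab, ab, nPerm = 99, seed = 3)
  expect_true(all(statMap(r0) == 0))
  expect_true(all(pValues(r0) == 1))
  # antisymmetry of the group contrast map
  r1 <- directionContrastTest(ab, ba, nPerm = 99, seed = 3)
  r2 <- directionContrastTest(ba, ab, nPerm = 99, seed = 3)
  expect_equal(statMap(r1), -statMap(r2), tolerance = 1e-10)
})

test_that("fROI assembly unions significant sources of two results", {
  mk <- function(p, rows) new("StatResult", stat = matrix(0, 4, 3),
                              tfce = matrix(0, 4, 3), p = p,
                              nPermutations = 99L, tail = "two-sided",
                              rowValues = rows, colValues = 1:3, meta = list())
  p1 <- matrix(1, 4, 3); p1[2, 1] <- 0.01
  p2 <- matrix(1, 4, 3); p2[c(3, 4), 2] <- 0.02
  roi <- froiFromResults(mk(p1, c(10, 20, 30, 40)), mk(p2, c(10, 20, 30, 40)))
  expect_equal(roi, c(20, 30, 40))
  expect_equal(froiFromResults(mk(p1, 1:4), NULL), 2L)
})
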