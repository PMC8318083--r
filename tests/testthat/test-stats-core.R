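# Shared statistical machinery against independent oracles.

test_that("olsFit recovers exact fits and matches the normal-equations solve", {
  set.seed(11)
  X <- cbind(intercept = 1, a = rnorm(20), b = rnorm(20), c = rnorm(20))
  beta <- c(2, -1, 0.5, 3)
  expect_equal(unname(olsFit(X %*% beta, X)), beta, tolerance = 1e-12)

  for (r in 1:25) {
    X <- cbind(1, matrix(rnorm(20 * 3), 20, 3))
    y <- rnorm(20)
    oracle <- solve(t(X) %*% X) %*% t(X) %*% y
    expect_equal(unname(olsFit(y, X)), as.numeric(oracle), tolerance = 1e-8)
    # residuals orthogonal to the design columns
    resid <- y - X %*% olsFit(y, X)
    expect_lt(max(abs(t(X) %*% resid)), 1e-8)
  }

  y <- rnorm(10)
  expect_equal(unname(olsFit(y, matrix(1, 10, 1))), mean(y))
})

test_that("olsFit refuses rank-deficient designs naming the collinear columns", {
  X <- cbind(a = rep(1, 10), b = 1:10, dup = 2 * (1:10))
  expect_error(olsFit(rnorm(10), X), "dup")
  expect_error(olsFit(rnorm(3), matrix(rnorm(12), 3, 4)),
               "more trials than predictors")
})

test_that("oneSampleT follows the textbook formula and flags zero variance", {
  expect_equal(oneSampleT(c(-1, 1), 0), 0)
  set.seed(21)
  for (r in 1:20) {
    x <- rnorm(10); mu <- rnorm(1)
    expect_equal(oneSampleT(x, mu),
                 (mean(x) - mu) / (sd(x) / sqrt(10)), tolerance = 1e-12)
  }
  expect_warning(t0 <- oneSampleT(c(1, 1, 1, 1), 1), "zero variance")
  expect_equal(t0, 0)
  expect_warning(tp <- oneSampleT(c(2, 2, 2), 1), "zero variance")
  expect_identical(tp, Inf)
})

test_that("partialCorrelation matches the residual-regression oracle", {
  set.seed(31)
  # z orthogonalized against x and y: equals the plain correlation
  x <- rnorm(30); y <- rnorm(30); z <- rnorm(30)
  z <- residuals(lm(z ~ x + y))
  expect_equal(partialCorrelation(x, y, z), cor(x, y), tolerance = 1e-12)
  # y identical to z: everything partialled out
  expect_warning(pyy <- partialCorrelation(x, y, y), "degenerate")
  expect_equal(pyy, 0)
  # residual-regression oracle on random triples
  for (r in 1:100) {
    x <- rnorm(10); y <- rnorm(10); z <- rnorm(10)
    rx <- residuals(lm(x ~ z)); ry <- residuals(lm(y ~ z))
    expect_equal(partialCorrelation(x, y, z), cor(rx, ry), tolerance = 1e-10)
  }
  expect_warning(p0 <- partialCorrelation(rep(1, 5), rnorm(5), rnorm(5)),
                 "constant")
  expect_equal(p0, 0)
})

test_that("partialCorrelation is symmetric in x,y and affine-invariant", {
  set.seed(41)
  for (r in 1:20) {
    x <- rnorm(12); y <- rnorm(12); z <- rnorm(12)
    expect_equal(partialCorrelation(x, y, z), partialCorrelation(y, x, z),
                 tolerance = 1e-12)
    expect_equal(partialCorrelation(2.5 * x - 3, y, z),
                 partialCorrelation(x, 0.1 * y + 7, -2 * z + 1),
                 tolerance = 1e-10)
  }
})

test_that("tfceEnhance: zero maps, closed-form single point, signed tails", {
  edges <- chain_edges(5)
  expect_true(all(tfceEnhance(matrix(0, 5, 4), edges) == 0))

  # isolated point of height h: integral of 1^E x^H = h^3/3 for H = 2
  for (h in c(1, 3.7)) {
    m <- matrix(0, 5, 5); m[3, 3] <- h
    out <- tfceEnhance(m, chain_edges(5))
    expect_equal(out[3, 3], h^3 / 3, tolerance = 0.02 * h^3 / 3)
    expect_true(all(out[-13] == 0))
  }

  # negative tail: enhanced on -stat and negated
  set.seed(51)
  m <- matrix(rnorm(60), 6, 10)
  expect_equal(tfceEnhance(-m, chain_edges(6)),
               -tfceEnhance(m, chain_edges(6)), tolerance = 1e-12)
})

test_that("tfceEnhance matches the brute-force threshold sweep", {
  set.seed(61)
  for (r in 1:5) {
    stat <- matrix(rnorm(15 * 20), 15, 20)
    edges <- chain_edges(15)
    mod <- tfceEnhance(stat, edges)
    ora <- oracle_tfce_two_sided(stat, edges)
    expect_lt(max(abs(mod - ora)) / max(abs(ora)), 0.01)
  }
})

test_that("tfceEnhance is monotone under pointwise increases (fixed dh)", {
  set.seed(71)
  params <- tfceParams(dh = 0.05)
  for (r in 1:10) {
    a <- matrix(abs(rnorm(8 * 12)), 8, 12)
    b <- a + matrix(runif(8 * 12, 0, 0.5), 8, 12)
    ta <- tfceEnhance(a, chain_edges(8), params, tail = "one-sided-positive")
    tb <- tfceEnhance(b, chain_edges(8), params, tail = "one-sided-positive")
    expect_true(all(tb - ta >= -1e-10))
  }
})

test_that("tfceEnhance commutes with consistent grid relabeling", {
  set.seed(81)
  nS <- 10
  edges <- rbind(chain_edges(nS), c(1, 5), c(3, 9))
  stat <- matrix(rnorm(nS * 6), nS, 6)
  perm <- sample(nS)
  # relabel sources: old row i becomes new row perm[i], edges mapped alike
  stat2 <- matrix(0, nS, ncol(stat))
  stat2[perm, ] <- stat
  edges2 <- cbind(perm[edges[, 1]], perm[edges[, 2]])
  out1 <- tfceEnhance(stat, edges)
  out2 <- tfceEnhance(stat2, edges2)
  expect_equal(out2[perm, ], out1, tolerance = 1e-12)
})

test_that("permutationTest: planted point, determinism, tail behavior", {
  set.seed(91)
  nSubj <- 8; nS <- 6; nT <- 8
  maps <- array(rnorm(nSubj * nS * nT, 0, 0.1), c(nSubj, nS, nT))
  maps[, 3, 4] <- maps[, 3, 4] + 50  # huge consistent effect at one point
  res <- permutationTest(maps, 0, chain_edges(nS), nPerm = 99, seed = 7)
  expect_equal(pValues(res)[3, 4], 1 / 100)
  res2 <- permutationTest(maps, 0, chain_edges(nS), nPerm = 99, seed = 7)
  expect_identical(pValues(res), pValues(res2))

  # below-chance maps are never significant under the positive one-sided tail
  neg <- array(rnorm(nSubj * nS * nT, -1, 0.2), c(nSubj, nS, nT))
  resn <- permutationTest(neg, 0, chain_edges(nS), nPerm = 99, seed = 8,
                          tail = "one-sided-positive")
  expect_true(all(pValues(resn) > 0.5))

  expect_warning(permutationTest(maps, 0, chain_edges(nS), nPerm = 10,
                                 seed = 1),
                 "cannot reach alpha")
})

test_that("permutationTest p-values are super-uniform under the null", {
  set.seed(101)
  nSim <- 60; hits <- 0
  for (r in seq_len(nSim)) {
    maps <- array(rnorm(8 * 6 * 6), c(8, 6, 6))
    res <- permutationTest(maps, 0, chain_edges(6), nPerm = 99,
                           seed = 1000 + r)
    if (min(pValues(res)) <= 0.05) hits <- hits + 1
  }
  # family-wise rate within the binomial 95% interval around <= 0.05
  expect_lte(hits, qbinom(0.975, nSim, 0.05) + 1)
})

test_that("the zero-exchange null variant runs and controls the planted point", {
  set.seed(111)
  maps <- array(rnorm(8 * 5 * 5, 0, 0.1), c(8, 5, 5))
  maps[, 2, 2] <- maps[, 2, 2] + 20
  res <- permutationTest(maps, 0, chain_edges(5), nPerm = 99, seed = 5,
                         nullMethod = "zero")
  expect_equal(pValues(res)[2, 2], 1 / 100)
  # pointwise correction available
  resp <- permutationTest(maps, 0, chain_edges(5), nPerm = 99, seed = 5,
                          correction = "pointwise")
  expect_equal(pValues(resp)[2, 2], 1 / 100)
  expect_true(all(pValues(resp) <= pValues(res) + 1e-12 |
                    pValues(res) < 1))
})
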