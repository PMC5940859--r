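test_that("RDA R2 matches hand-computable and perfect-fit cases", {
  x <- 1:8
  # response exactly linear in the predictor
  Y <- cbind(2 * x + 3, -0.5 * x)
  expect_equal(rdaR2(Y, x)@r2, 1, tolerance = 1e-12)
  # response orthogonal to the centred predictor
  y0 <- c(1, 2, 1, -1, 0, 3, -2, 1)
  Yo <- cbind(resid(lm(y0 ~ x)))
  expect_lt(rdaR2(Yo, x)@r2, 1e-12)
  # n = 4 worked example: one column is centred x, one orthogonal
  x4 <- 1:4
  Y4 <- cbind(c(-1.5, -0.5, 0.5, 1.5), c(1, -1, -1, 1))
  fit <- rdaR2(Y4, x4)
  expect_equal(fit@r2, 5 / 9, tolerance = 1e-12)
  expect_equal(fit@adjR2, 1 / 3, tolerance = 1e-12)
  expect_error(rdaR2(matrix(1, 8, 2), x), "zero variance")
})

test_that("RDA equals the per-column OLS brute-force oracle", {
  set.seed(101)
  for (i in 1:30) {
    n <- sample(8:25, 1)
    m <- sample(2:8, 1)
    Y <- matrix(rnorm(n * m), n, m)
    x <- rnorm(n)
    expect_equal(rdaR2(Y, x)@r2, olsR2Oracle(Y, x), tolerance = 1e-10)
  }
})

test_that("RDA agrees with an independent constrained-ordination program", {
  skip_if_not_installed("vegan")
  set.seed(55)
  Y <- matrix(rnorm(15 * 6), 15, 6)
  x1 <- rnorm(15); x2 <- rnorm(15)
  fit <- rdaR2(Y, cbind(x1, x2))
  v <- vegan::rda(Y ~ x1 + x2)
  expect_equal(fit@r2, vegan::RsquareAdj(v)$r.squared, tolerance = 1e-10)
  expect_equal(fit@adjR2, vegan::RsquareAdj(v)$adj.r.squared,
               tolerance = 1e-10)
  vp <- vegan::varpart(Y, ~x1, ~x2)
  ind <- vp$part$indfract$Adj.R.squared  # rows: X1|X2, X2|X1, shared, resid
  part <- partitionFishingTemperature(Y, x1, x2)
  expect_equal(part@fracFishing, ind[1], tolerance = 1e-10)
  expect_equal(part@fracTemperature, ind[2], tolerance = 1e-10)
  expect_equal(part@fracShared, ind[3], tolerance = 1e-10)
})

test_that("Ezekiel adjustment follows its closed form", {
  expect_equal(adjustR2(1, 10, 3), 1)
  expect_equal(adjustR2(0, 10, 1), -0.125)
  expect_equal(adjustR2(5 / 9, 4, 1), 1 / 3, tolerance = 1e-12)
  expect_error(adjustR2(0.5, 4, 3), "insufficient degrees")
})

test_that("the partition identity and degenerate designs behave", {
  set.seed(202)
  for (i in 1:20) {
    n <- sample(10:30, 1)
    Y <- matrix(rnorm(n * 4), n, 4)
    xf <- rnorm(n); xt <- rnorm(n)
    p <- partitionFishingTemperature(Y, xf, xt)
    expect_equal(p@fracFishing + p@fracShared + p@fracTemperature,
                 p@totalAdjR2, tolerance = 1e-10)
    expect_equal(p@fracResidual, 1 - p@totalAdjR2, tolerance = 1e-12)
  }
  # complete collinearity: identical forcings put everything in the
  # shared fraction
  n <- 20
  Y <- matrix(rnorm(n * 3), n, 3)
  x <- rnorm(n)
  p <- partitionFishingTemperature(Y, x, x)
  expect_equal(p@fracFishing, 0, tolerance = 1e-10)
  expect_equal(p@fracTemperature, 0, tolerance = 1e-10)
  expect_equal(p@fracShared, rdaR2(Y, x)@adjR2, tolerance = 1e-10)
})

test_that("orthogonal forcings recover their own marginal fractions", {
  # Y built as xf v1' + xt v2' + noise with xf orthogonal to xt: on the
  # raw R2 scale the joint fit is exactly additive, and the adjusted pure
  # fractions approach the marginal adjusted R2s (they differ only through
  # the n/(n - p - 1) correction, which shrinks with n)
  set.seed(88)
  n <- 200
  xf <- rep(c(1, -1), n / 2)
  xt <- rep(c(1, 1, -1, -1), n / 4)
  stopifnot(sum(xf * xt) == 0)
  v1 <- c(1, 0, -1, 0.5); v2 <- c(0, 1, 0.5, -1)
  Y <- outer(xf, v1) + outer(xt, v2) + matrix(rnorm(n * 4, sd = 2), n, 4)
  r2f <- rdaR2(Y, xf)@r2
  r2t <- rdaR2(Y, xt)@r2
  r2ft <- rdaR2(Y, cbind(xf, xt))@r2
  expect_equal(r2ft, r2f + r2t, tolerance = 1e-10)   # exact additivity
  p <- partitionFishingTemperature(Y, xf, xt)
  expect_lt(abs(p@fracFishing - rdaR2(Y, xf)@adjR2), 0.01)
  expect_lt(abs(p@fracTemperature - rdaR2(Y, xt)@adjR2), 0.01)
  expect_lt(abs(p@fracShared), 0.01)
  # against the OLS oracle as well
  expect_equal(r2f, olsR2Oracle(Y, xf), tolerance = 1e-10)
})

test_that("the permutation test is seeded, sharp on signal, honest on null", {
  set.seed(9)
  n <- 30
  Y <- matrix(rnorm(n * 4), n, 4)
  xf <- rnorm(n); xc <- rnorm(n)
  p1 <- permutationTestFraction(Y, xf, xc, nPerm = 199, seed = 3)
  p2 <- permutationTestFraction(Y, xf, xc, nPerm = 199, seed = 3)
  expect_identical(p1, p2)
  # perfect signal attains the minimum p
  v <- c(2, -1, 0.5, 1)
  Ysig <- outer(xf, v) + matrix(rnorm(n * 4, sd = 1e-4), n, 4)
  expect_equal(permutationTestFraction(Ysig, xf, xc, nPerm = 199, seed = 1),
               1 / 200)
  # degenerate focal: constant forcing explains nothing
  expect_warning(pc <- permutationTestFraction(Y, rep(1, n), xc,
                                               nPerm = 99, seed = 1),
                 "degenerate")
  expect_identical(pc, 1)
  expect_error(permutationTestFraction(Y, xf, xc, nPerm = 50), ">= 99")
})

test_that("the permutation test matches vegan's partial RDA test", {
  skip_if_not_installed("vegan")
  set.seed(31)
  n <- 25
  Y <- matrix(rnorm(n * 5), n, 5)
  xf <- seq_len(n) / n + rnorm(n, sd = 0.3)
  xc <- rnorm(n)
  Y <- Y + outer(xf, rep(0.8, 5))
  mine <- rdaR2(Y, xf, xc)
  va <- vegan::anova.cca(vegan::rda(Y, xf, xc), permutations = 499)
  expect_equal(mine@pseudoF, va$F[1], tolerance = 1e-8)
  p <- permutationTestFraction(Y, xf, xc, nPerm = 499, seed = 10)
  expect_lt(abs(p - va$`Pr(>F)`[1]), 0.05)
})

test_that("lag selection maximises effect size with parsimony tie-breaks", {
  # single candidate
  st <- simulateStock(SimConfig(nYears = 15L, seed = 21L))
  expect_identical(selectLagModel(st, lagCandidates = 0L, nPerm = 0L)@lag, 0L)
  # constant temperature: all lags tie at the fishing-only fit; smallest
  # lag wins
  cts <- matrix(rexp(14 * 4) + 1, 14, 4)
  stC <- makeStock(cts, F = seq(0.1, 0.8, length.out = 16),
                   temperature = rep(8, 16), years = 2002:2015,
                   forcingYears = 2000:2015)
  suppressWarnings(pC <- selectLagModel(stC, nPerm = 0L))
  expect_identical(pC@lag, 0L)
  expect_equal(pC@fracTemperature, 0, tolerance = 1e-10)
  # default candidate sets depend on the sampling interval
  expect_identical(defaultLagCandidates(1L), c(0L, 1L, 3L))
  expect_identical(defaultLagCandidates(2L), c(0L, 2L, 3L))
  expect_identical(defaultLagCandidates(3L, restrictMultiYear = TRUE),
                   c(2L, 3L))
})
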