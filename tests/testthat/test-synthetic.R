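test_that("forcing simulators honour their deterministic limits", {
  cfg0 <- SimConfig(nYears = 30L, tempSd = 0, seed = 4L)
  expect_equal(simulateTemperature(cfg0), rep(cfg0@tempMean, 30))
  cfgF <- SimConfig(nYears = 30L, fWalkSd = 0, fStart = 0.1, fEnd = 0.7)
  expect_equal(simulateFishing(cfgF), seq(0.1, 0.7, length.out = 30))
  cfgC <- SimConfig(nYears = 30L, fWalkSd = 0, fStart = 0.3, fEnd = 0.3)
  expect_equal(simulateFishing(cfgC), rep(0.3, 30))
  # reflection keeps F nonnegative under large noise
  cfgN <- SimConfig(nYears = 200L, fStart = 0.01, fEnd = 0.01,
                    fWalkSd = 0.3, seed = 9L)
  expect_true(all(simulateFishing(cfgN) >= 0))
  # same seed, same series
  expect_identical(simulateTemperature(SimConfig(seed = 5L)),
                   simulateTemperature(SimConfig(seed = 5L)))
})

test_that("the AR(1) temperature process has the configured memory", {
  cfg <- SimConfig(nYears = 5000L, tempRho = 0, tempSd = 0.5, seed = 2L)
  x <- simulateTemperature(cfg)
  expect_lt(abs(cor(x[-1], x[-5000])), 0.05)
  cfgR <- SimConfig(nYears = 5000L, tempRho = 0.7, tempSd = 0.5, seed = 2L)
  xr <- simulateTemperature(cfgR)
  expect_equal(cor(xr[-1], xr[-5000]), 0.7, tolerance = 0.05)
})

test_that("simulated stocks are reproducible, well-formed multinomials", {
  cfg <- SimConfig(nYears = 12L, seed = 33L)
  s1 <- simulateStock(cfg)
  s2 <- simulateStock(cfg)
  expect_identical(counts(composition(s1)), counts(composition(s2)))
  expect_identical(forcing(s1)@temperature, forcing(s2)@temperature)
  # every survey year measures exactly nSample fish
  expect_true(all(rowSums(counts(composition(s1))) == cfg@nSample))
  expect_true(all(counts(composition(s1)) >= 0))
  # forcing carries the true series
  expect_identical(forcing(s1)@F, simulateFishing(cfg))
  # different seeds differ
  expect_false(identical(counts(composition(s1)),
                         counts(composition(simulateStock(SimConfig(
                           nYears = 12L, seed = 34L))))))
})

test_that("harder fishing truncates the observed size structure", {
  # increasing a constant F lowers the long-run mean of L95 and mean
  # length, averaged across seeds
  meanSBI <- function(Fconst) {
    l95 <- ml <- numeric(50)
    for (i in 1:50) {
      st <- simulateStock(SimConfig(nYears = 20L, betaT = 0,
                                    fStart = Fconst, fEnd = Fconst,
                                    fWalkSd = 0, nSample = 1000L,
                                    seed = 500L + i))
      s <- computeSBITable(composition(st))
      l95[i] <- mean(s$L95); ml[i] <- mean(s$meanLength)
    }
    c(mean(l95), mean(ml))
  }
  lo <- meanSBI(0.05)
  hi <- meanSBI(0.8)
  expect_lt(hi[1], lo[1])
  expect_lt(hi[2], lo[2])
})

test_that("batch simulation writes readable stocks and a manifest", {
  d <- withr::local_tempdir()
  cfg <- SimConfig(nYears = 10L, seed = 60L)
  man <- simulateStockBatch(cfg, 3, d)
  expect_identical(nrow(man), 3L)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  st <- readStockSeries(man$composition[2], man$meta[2], man$forcing[2])
  expect_s4_class(st, "StockSeries")
  expect_identical(length(unique(man$stock)), 3L)
})
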