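test_that("construction enforces the composition invariants", {
  expect_s4_class(makeComp(matrix(1, 3, 4)), "LengthComposition")
  # all-zero year rejected
  m <- matrix(1, 3, 4); m[2, ] <- 0
  expect_error(makeComp(m), "positive total")
  # negative counts rejected
  m <- matrix(1, 3, 4); m[1, 2] <- -2
  expect_error(makeComp(m), "nonnegative")
  # non-increasing edges rejected
  expect_error(LengthComposition(2000:2001, c(10, 30, 20), matrix(1, 2, 2)),
               "strictly increasing")
  # fewer than 2 bins rejected
  expect_error(LengthComposition(2000:2001, c(10, 20), matrix(1, 2, 1)),
               "at least 2 bins")
  expect_error(ForcingSeries(2000:2002, mu = c(0.2, 1.2, 0.1),
                             temperature = rep(8, 3)),
               "mu must lie")
  expect_error(StockMeta("x", M = 0.2, K = 0.3, Linf = 50, A50 = 3,
                         L50 = 60),
               "L50 must be smaller")
})

test_that("CSV/YAML round trip re-reads to an equal object", {
  st <- simulateStock(SimConfig(nYears = 10L, seed = 11L))
  d <- withr::local_tempdir()
  paths <- writeStockSeries(st, d)
  st2 <- readStockSeries(paths$composition, paths$meta, paths$forcing)
  expect_identical(counts(composition(st2)), counts(composition(st)))
  expect_identical(binEdges(composition(st2)), binEdges(composition(st)))
  expect_equal(forcing(st2)@F, forcing(st)@F)
  expect_equal(forcing(st2)@temperature, forcing(st)@temperature)
  expect_identical(stockMeta(st2)@M, stockMeta(st)@M)
  # identity fixture: 3 years x 4 bins of ones survives tidy round trip
  lc <- makeComp(matrix(1, 3, 4))
  stU <- StockSeries(stockMeta(st), lc,
                     ForcingSeries(2000:2002, F = rep(0.1, 3),
                                   temperature = rep(8, 3)))
  stU@meta@stockId <- "unit"
  p2 <- writeStockSeries(stU, d)
  back <- readStockSeries(p2$composition, p2$meta, p2$forcing)
  expect_equal(unname(counts(composition(back))), matrix(1, 3, 4))
  # malformed input errors
  bad <- file.path(d, "bad.csv")
  write.csv(data.frame(yr = 1, x = 2), bad, row.names = FALSE)
  expect_error(readStockSeries(bad, p2$meta, p2$forcing), "columns")
})

test_that("proportions normalise rows and reject degenerate years", {
  lc <- makeComp(matrix(c(2, 2, 4), 1, 3))
  expect_equal(unname(counts(toProportions(lc))[1, ]),
               c(0.25, 0.25, 0.5))
  # idempotence
  p <- toProportions(lc)
  expect_equal(counts(toProportions(p)), counts(p))
  # Hellinger = sqrt of proportions
  expect_equal(unname(counts(hellingerTransform(lc))[1, ]),
               sqrt(c(0.25, 0.25, 0.5)))
  # proportion rows sum to 1 within 1e-12 on random compositions
  set.seed(42)
  for (i in 1:20) {
    m <- matrix(rexp(6 * 5), 6, 5)
    expect_true(all(abs(rowSums(counts(toProportions(makeComp(m)))) - 1) <
                      1e-12))
  }
})

test_that("year alignment applies the temperature lag and keeps order", {
  # composition 1990-1999, forcing 1989-1999, lag 1: all years retained,
  # temperature shifted back one year
  cts <- matrix(rexp(10 * 3) + 1, 10, 3)
  Fv <- seq(0.1, 0.4, length.out = 11)
  Tv <- 1:11
  st <- makeStock(cts, F = Fv, temperature = Tv, years = 1990:1999,
                  forcingYears = 1989:1999)
  a <- alignYears(st, 1L)
  expect_identical(a$years, 1990:1999)
  expect_equal(a$xTemp, Tv[1:10])       # T(1989)..T(1998)
  expect_equal(a$xFish, Fv[2:11])       # F never lagged
  # lag 0 with identical year sets keeps everything
  st0 <- makeStock(cts, F = Fv[-1], temperature = Tv[-1], years = 1990:1999)
  a0 <- alignYears(st0, 0L)
  expect_identical(a0$years, 1990:1999)
  # lag 3 with forcing starting at the first composition year drops 3 rows
  a3 <- alignYears(st0, 3L, minYears = 7L)
  expect_identical(a3$years, 1993:1999)
  expect_equal(a3$xTemp, Tv[2 + 0:6])  # T(1990)..T(1996)
  # insufficient aligned years errors
  expect_error(alignYears(st0, 3L, minYears = 8L), "aligned year")
  # alignment is order-preserving and loses no complete year
  expect_true(all(diff(a$years) > 0))
})

test_that("bins empty across all retained years are dropped", {
  cts <- cbind(matrix(rexp(8 * 3) + 1, 8, 3), 0)
  st <- makeStock(cts, F = seq(0.1, 0.8, length.out = 8),
                  temperature = rnorm(8, 8))
  a <- alignYears(st, 0L)
  expect_identical(ncol(a$Y), 3L)
  expect_true(all(abs(rowSums(a$Y) - 1) < 1e-12))
})
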