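test_that("paired comparisons guard degenerate and grouped inputs", {
  tab <- table2Fixture()
  out <- pairedEffectComparisons(tab)
  expect_identical(nrow(out), 3L)
  expect_true(all(out$n == 28))
  # identical columns: zero-variance differences give t = NA, p = 1
  d <- data.frame(fracFishing = c(0.1, 0.2, 0.3),
                  fracShared = c(0.1, 0.2, 0.3),
                  fracTemperature = c(0, 0, 0.1))
  o <- pairedEffectComparisons(d)
  row <- o[o$pair == "fishing-shared", ]
  expect_true(is.na(row$t)); expect_equal(row$p, 1)
  # small groups are skipped with a warning
  d$region <- c("WestUS", "WestUS", "Alaska")
  w <- capture_warnings(pairedEffectComparisons(d, "region"))
  expect_match(w, "fewer than 3", all = TRUE)
  # power grows with the shift between columns
  set.seed(5)
  noise <- rnorm(40, sd = 0.05)
  pv <- vapply(c(0.01, 0.3), function(delta) {
    dd <- data.frame(fracFishing = 0.2 + delta + noise,
                     fracShared = 0.2 + rnorm(40, sd = 0.05),
                     fracTemperature = 0.2 + noise * 0)
    pairedEffectComparisons(dd)$p[1]
  }, numeric(1))
  expect_lt(pv[2], pv[1])
})

test_that("fraction regression recovers exact slopes and handles degeneracy", {
  set.seed(2)
  meta <- data.frame(cvFM = runif(20, 0.1, 0.9))
  meta$fracTemperature <- 0.1 + 0.122 * meta$cvFM
  r <- suppressWarnings(fractionRegression(meta, "temperature", "cvFM"))
  expect_equal(r$coef, 0.122, tolerance = 1e-10)
  expect_lt(r$p, 1e-10)
  # permuted covariate carries no signal
  meta$shuffled <- sample(meta$cvFM)
  meta$fracFishing <- 0.1 + 0.122 * meta$cvFM + rnorm(20, sd = 0.02)
  rs <- fractionRegression(meta, "fishing", "shuffled")
  expect_gt(rs$p, 0.01)
  # constant response rule
  metaC <- data.frame(fracFishing = rep(0.2, 10), x = rnorm(10))
  expect_equal(fractionRegression(metaC, "fishing", "x"),
               list(coef = 0, p = 1))
  expect_error(fractionRegression(meta, "fishing", "nope"), "not found")
  metaZ <- data.frame(fracFishing = rnorm(10), z = rep(1, 10))
  expect_error(fractionRegression(metaZ, "fishing", "z"), "zero variance")
})

test_that("the mixed model collapses to OLS when habitat is uninformative", {
  set.seed(12)
  meta <- data.frame(cvFM = runif(24, 0.1, 1),
                     habitat = "demersal")
  meta$fracTemperature <- 0.05 + 0.2 * meta$cvFM + rnorm(24, sd = 0.03)
  lm1 <- fractionLmm(meta, "temperature", "cvFM")
  ols <- fractionRegression(meta, "temperature", "cvFM")
  expect_identical(lm1$method, "ols")
  expect_equal(lm1$coef, ols$coef)
  # balanced design with the covariate orthogonal to habitat means: LMM
  # and OLS slopes agree
  hab <- rep(c("pelagic", "demersal", "benthic"), each = 12)
  x <- rep(scale(rnorm(12))[, 1], 3)  # identical within each habitat
  y <- 0.1 + 0.25 * x +
    rep(c(0.1, -0.1, 0), each = 12) + rnorm(36, sd = 0.02)
  meta2 <- data.frame(fracFishing = y, x = x, habitat = hab)
  l2 <- fractionLmm(meta2, "fishing", "x")
  o2 <- fractionRegression(meta2, "fishing", "x")
  expect_equal(l2$coef, o2$coef, tolerance = 1e-6)
})

test_that("the mixed model recovers a known cross-habitat slope", {
  # habitat intercept offsets {+0.1, -0.1, 0}, slope 0.2, 60 stocks;
  # the Wald 95% interval should cover the true slope in >= 90% of fits
  set.seed(31)
  nRep <- 200
  covered <- 0
  for (i in seq_len(nRep)) {
    hab <- rep(c("pelagic", "demersal", "benthic"), each = 20)
    x <- rnorm(60)
    y <- 0.2 * x + rep(c(0.1, -0.1, 0), each = 20) + rnorm(60, sd = 0.1)
    meta <- data.frame(fracFishing = y, x = x, habitat = hab)
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(fracFishing ~ x + (1 | habitat), data = meta)))
    cf <- summary(fit)$coefficients
    lo <- cf["x", "Estimate"] - 1.96 * cf["x", "Std. Error"]
    hi <- cf["x", "Estimate"] + 1.96 * cf["x", "Std. Error"]
    covered <- covered + (lo <= 0.2 && 0.2 <= hi)
  }
  expect_gte(covered / nRep, 0.9)
})

test_that("the efficiency comparison counts strict wins exactly", {
  # 8 wins out of 10: exact binomial tail (45 + 10 + 1) / 1024
  vp <- data.frame(stock = letters[1:10], effect = "fishing",
                   p = c(rep(0.01, 8), rep(0.9, 2)))
  sb <- data.frame(stock = letters[1:10], effect = "fishing",
                   sbi = "L95", p = c(rep(0.5, 8), rep(0.5, 2)))
  r <- pvalueEfficiencyComparison(vp, sb)
  expect_equal(r$probSuccess, 0.8)
  expect_equal(r$binomP, 56 / 1024, tolerance = 1e-12)
  # ties never count as wins
  sbT <- transform(sb, p = vp$p)
  rT <- pvalueEfficiencyComparison(vp, sbT)
  expect_equal(rT$probSuccess, 0)
  # uniformly smaller partition p: probability 1, binomial p = 0.5^n
  sbW <- transform(sb, p = vp$p + 0.01)
  rW <- pvalueEfficiencyComparison(vp, sbW)
  expect_equal(rW$probSuccess, 1)
  expect_equal(rW$binomP, 0.5^10, tolerance = 1e-12)
  expect_error(pvalueEfficiencyComparison(
    data.frame(stock = "x", effect = "fishing", p = 0.1),
    data.frame(stock = "y", effect = "fishing", sbi = "L95", p = 0.1)),
    "no matched")
})

test_that("the omnibus repeated-measures ANOVA detects effect differences", {
  tab <- table2Fixture()
  a <- effectAnova(tab)
  expect_identical(a$df1, 2)
  expect_identical(a$df2, 54)
  expect_lt(a$p, 0.01)
})
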