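#' Paired comparisons of explained fractions across stocks
#'
#' For every group of stocks (all stocks, or grouped by region or habitat)
#' with at least three members, runs paired t-tests across stocks for each
#' of the three effect pairs: fishing vs temperature, fishing vs shared
#' ("interaction"), and temperature vs shared.  Zero variance of the paired
#' differences is NaN-guarded: \code{t = NA}, \code{p = 1}.
#'
#' @param meta Data frame with one row per stock and columns
#'   \code{fracFishing}, \code{fracShared}, \code{fracTemperature} plus the
#'   grouping column when requested.  The fixture path feeds the clamped
#'   (reported) fractions so results match the printed partition table.
#' @param groupBy \code{"none"} (all stocks), \code{"region"} or
#'   \code{"habitat"}.
#' @param alternative Passed to [stats::t.test()]; \code{"two.sided"}
#'   (default), or \code{"greater"} to test that the first effect of the
#'   pair explains \emph{more} than the second (the directional reading of
#'   "significantly higher").
#' @return Data frame with columns \code{group}, \code{pair}, \code{n},
#'   \code{t}, \code{p}.  Groups smaller than 3 are skipped with a warning.
#' @examples
#' tab <- table2Fixture()
#' pairedEffectComparisons(tab, alternative = "greater")
#' @export
pairedEffectComparisons <- function(meta,
                                    groupBy = c("none", "region", "habitat"),
                                    alternative = "two.sided") {
  groupBy <- match.arg(groupBy)
  groups <- if (groupBy == "none") list(all = meta)
            else split(meta, meta[[groupBy]])
  pairs <- list(
    `fishing-temperature` = c("fracFishing", "fracTemperature"),
    `fishing-shared` = c("fracFishing", "fracShared"),
    `temperature-shared` = c("fracTemperature", "fracShared"))
  out <- list()
  for (g in names(groups)) {
    d <- groups[[g]]
    if (nrow(d) < 3L) {
      warning("group '", g, "' has fewer than 3 stocks; skipped")
      next
    }
    for (pr in names(pairs)) {
      a <- d[[pairs[[pr]][1]]]
      b <- d[[pairs[[pr]][2]]]
      if (stats::sd(a - b) == 0) {
        tt <- NA_real_; pv <- 1
      } else {
        ht <- stats::t.test(a, b, paired = TRUE, alternative = alternative)
        tt <- unname(ht$statistic); pv <- ht$p.value
      }
      out[[length(out) + 1L]] <- data.frame(group = g, pair = pr,
                                            n = nrow(d), t = tt, p = pv)
    }
  }
  do.call(rbind, out)
}

#' Univariate regression of an explained fraction on a stock covariate
#'
#' OLS of the per-stock fishing (or temperature) fraction on a single
#' life-history or forcing covariate; the building block of the cross-stock
#' covariate screen.
#'
#' @param meta Data frame with one row per stock.
#' @param response \code{"fishing"} or \code{"temperature"} (columns
#'   \code{fracFishing} / \code{fracTemperature}).
#' @param covariate Name of the covariate column.
#' @return List with \code{coef} (slope) and \code{p} (two-sided); a
#'   constant response returns \code{coef = 0}, \code{p = 1}.
#' @export
fractionRegression <- function(meta, response = c("fishing", "temperature"),
                               covariate) {
  response <- match.arg(response)
  y <- meta[[if (response == "fishing") "fracFishing" else "fracTemperature"]]
  x <- meta[[covariate]]
  if (is.null(x)) stop("covariate '", covariate, "' not found")
  if (anyNA(x)) stop("covariate '", covariate, "' has missing values")
  if (stats::sd(x) == 0) stop("covariate '", covariate, "' has zero variance")
  if (stats::sd(y) == 0) return(list(coef = 0, p = 1))
  cf <- summary(stats::lm(y ~ x))$coefficients
  list(coef = unname(cf["x", 1]), p = unname(cf["x", 4]))
}

#' Mixed-model regression of a fraction with habitat as random intercept
#'
#' Linear mixed model \code{fraction ~ covariate + (1 | habitat)}, REML
#' fit via \pkg{lme4}, with the fixed-slope p-value from the Satterthwaite
#' degrees-of-freedom approximation (\pkg{lmerTest}).  When only one
#' habitat level is present, or the random-effect variance collapses to
#' zero (singular fit), the model falls back to OLS and flags it.
#'
#' @inheritParams fractionRegression
#' @return List with \code{coef}, \code{p}, and \code{method}
#'   (\code{"lmm"} or \code{"ols"}).
#' @export
fractionLmm <- function(meta, response = c("fishing", "temperature"),
                        covariate) {
  response <- match.arg(response)
  y <- meta[[if (response == "fishing") "fracFishing" else "fracTemperature"]]
  x <- meta[[covariate]]
  if (is.null(x)) stop("covariate '", covariate, "' not found")
  hab <- factor(meta$habitat)
  if (nlevels(droplevels(hab)) < 2L) {
    r <- fractionRegression(meta, response, covariate)
    return(list(coef = r$coef, p = r$p, method = "ols"))
  }
  d <- data.frame(y = y, x = x, habitat = hab)
  fit <- suppressMessages(
    lmerTest::lmer(y ~ x + (1 | habitat), data = d, REML = TRUE))
  if (lme4::isSingular(fit, tol = 1e-05)) {
    r <- fractionRegression(meta, response, covariate)
    return(list(coef = r$coef, p = r$p, method = "ols"))
  }
  cf <- summary(fit)$coefficients
  list(coef = unname(cf["x", "Estimate"]),
       p = unname(cf["x", "Pr(>|t|)"]), method = "lmm")
}

#' Efficiency comparison: partition p-values versus SBI regression p-values
#'
#' Pairs each stock-and-effect permutation p-value from variation
#' partitioning with the corresponding forcing term's p-value from each of
#' the univariate SBI regressions (five pairs per stock per effect), counts
#' a success when the partition p is \emph{strictly} smaller (ties count as
#' failures), and tests the success probability against 0.5 with a
#' one-sided exact binomial test (alternative "greater").
#'
#' @param varpartP Data frame with columns \code{stock}, \code{effect}
#'   (\code{"fishing"}/\code{"temperature"}), \code{p}.
#' @param sbiP Data frame with columns \code{stock}, \code{effect},
#'   \code{sbi}, \code{p}.
#' @return List with \code{probSuccess}, \code{binomP}, \code{nPairs},
#'   \code{nSuccess}.
#' @examples
#' vp <- data.frame(stock = "s", effect = "fishing", p = 0.01)
#' sb <- data.frame(stock = "s", effect = "fishing",
#'                  sbi = c("L95", "meanLength"), p = c(0.5, 0.2))
#' pvalueEfficiencyComparison(vp, sb)
#' @export
pvalueEfficiencyComparison <- function(varpartP, sbiP) {
  m <- merge(sbiP, varpartP, by = c("stock", "effect"),
             suffixes = c(".sbi", ".vp"))
  m <- m[!is.na(m$p.sbi) & !is.na(m$p.vp), ]
  if (nrow(m) == 0L) stop("no matched (stock, effect) pairs")
  nSuccess <- sum(m$p.vp < m$p.sbi)
  bt <- stats::binom.test(nSuccess, nrow(m), p = 0.5,
                          alternative = "greater")
  list(probSuccess = nSuccess / nrow(m), binomP = bt$p.value,
       nPairs = nrow(m), nSuccess = nSuccess)
}

#' One-way repeated-measures ANOVA across the three effect fractions
#'
#' Companion to [pairedEffectComparisons()]: a repeated-measures ANOVA of
#' fraction ~ effect with stock as the blocking factor, for readers who
#' want the omnibus test behind the pairwise comparisons.  Not part of the
#' reproduction path.
#'
#' @param meta Data frame with \code{fracFishing}, \code{fracShared},
#'   \code{fracTemperature}.
#' @return List with \code{F}, \code{df1}, \code{df2}, \code{p}.
#' @export
effectAnova <- function(meta) {
  n <- nrow(meta)
  d <- data.frame(
    val = c(meta$fracFishing, meta$fracTemperature, meta$fracShared),
    effect = factor(rep(c("fishing", "temperature", "shared"), each = n)),
    stock = factor(rep(seq_len(n), 3)))
  fit <- stats::aov(val ~ effect + Error(stock / effect), data = d)
  tab <- summary(fit)[["Error: stock:effect"]][[1]]
  list(F = tab["effect", "F value"], df1 = tab["effect", "Df"],
       df2 = tab["Residuals", "Df"], p = tab["effect", "Pr(>F)"])
}
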