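#' Embedded 28-stock partition table
#'
#' The published per-stock variation-partitioning results for 28 exploited
#' stocks of the West US, Alaska and North Sea regions: clamped
#' three-decimal adjusted-R-squared fractions for fishing, the shared
#' ("interaction") component and temperature, the total adjusted
#' R-squared, the significance flags of the two testable fractions
#' (\code{"*"} p < 0.05, \code{"**"} p < 0.01), and the selected
#' temperature lag (years).  This table is the desk-scale input for the
#' cross-stock summary statistics and paired comparisons; the raw survey
#' data behind it are not shipped.
#'
#' The \code{habitat} column is a package-supplied classification from
#' standard species ecology (clupeids, sardine, mackerel, Norway pout and
#' pollock pelagic; flatfishes benthic; gadoids, rockfishes, lingcod and
#' thornyhead demersal); it exercises habitat-grouped comparisons and is
#' not part of the published table.
#'
#' @return Data frame with columns \code{stock}, \code{region},
#'   \code{habitat}, \code{fracFishing}, \code{fracShared},
#'   \code{fracTemperature}, \code{totalAdjR2}, \code{sigFishing},
#'   \code{sigTemperature}, \code{lag}.
#' @examples
#' tab <- table2Fixture()
#' mean(tab$fracFishing) * 100   # average % explained by fishing
#' @export
table2Fixture <- function() {
  path <- system.file("extdata", "partition_table_28stocks.csv",
                      package = "SizeVarPart", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(sigFishing = "character",
                                        sigTemperature = "character"))
  tab$sigFishing[is.na(tab$sigFishing)] <- ""
  tab$sigTemperature[is.na(tab$sigTemperature)] <- ""
  tab
}

#' Summary statistics of the embedded partition table
#'
#' The headline cross-stock numbers: mean percent of size-structure
#' variation explained by fishing, counts of stocks with a significant
#' fishing or temperature fraction (p < 0.05), and the maximum total
#' adjusted R-squared (percent).
#'
#' @param tab Partition table in [table2Fixture()] layout.
#' @return List with \code{meanFishingPct}, \code{nFishingSignificant},
#'   \code{nTemperatureSignificant}, \code{maxTotalAdjR2Pct}.
#' @export
partitionTableSummary <- function(tab = table2Fixture()) {
  list(meanFishingPct = 100 * mean(tab$fracFishing),
       nFishingSignificant = sum(tab$sigFishing != ""),
       nTemperatureSignificant = sum(tab$sigTemperature != ""),
       maxTotalAdjR2Pct = 100 * max(tab$totalAdjR2))
}

#' Embedded cross-stock covariate regression table
#'
#' The published univariate-regression screen of the fishing and
#' temperature fractions against eight stock covariates (age and length at
#' maturity, asymptotic length, growth rate, mean and CV of the mortality
#' ratio F/M, mean and CV of temperature): slope and two-sided p-value per
#' covariate and response.  Embedded for display and comparison; the
#' per-stock covariate values needed to recompute it are not shipped.
#'
#' @return Data frame with columns \code{response}, \code{covariate},
#'   \code{coef}, \code{p}.
#' @export
table3Fixture <- function() {
  cov <- c("A50", "L50", "Linf", "K", "meanFM", "cvFM", "meanTemp",
           "cvTemp")
  data.frame(
    response = rep(c("fishing", "temperature"), each = 8),
    covariate = rep(cov, 2),
    coef = c(0.014, -0.001, 0.000, -0.089, -0.004, 0.075, 0.009, -0.022,
             0.000, 0.001, 0.000, 0.040, 0.004, 0.122, -0.003, -0.017),
    p = c(0.125, 0.622, 0.596, 0.509, 0.840, 0.511, 0.163, 0.459,
          0.975, 0.523, 0.927, 0.599, 0.673, 0.048, 0.343, 0.308))
}
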