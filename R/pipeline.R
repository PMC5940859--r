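#' Full per-stock analysis
#'
#' Orchestrates one stock end to end: converts exploitation rates to
#' fishing mortality where \code{F} is missing (type II fishery inversion,
#' using the stock's \code{M}), selects the temperature lag by largest
#' total adjusted R-squared and runs the permutation tests
#' ([selectLagModel()]), computes the five size-based indicators for every
#' composition year, and regresses each indicator on temperature, fishing
#' and their product over the lag-0 aligned years.
#'
#' With \code{outDir} set, writes \code{<id>_partition.csv} (one row in the
#' partition-table column order: stock, fishing, interaction, temperature,
#' total, p_fishing, p_temperature, lag), \code{<id>_sbi.csv},
#' \code{<id>_sbi_regression.csv}, and a JSON provenance sidecar with the
#' seed and settings.
#'
#' @param stock A \linkS4class{StockSeries}.
#' @param nPerm Permutations for significance tests.
#' @param lagCandidates Optional integer vector; default per the stock's
#'   sampling interval ([defaultLagCandidates()]).
#' @param transform \code{"proportions"} or \code{"hellinger"}.
#' @param minYears Minimum aligned years.
#' @param seed Integer seed (permutation tests).
#' @param outDir Optional output directory.
#' @return List with \code{partition} (\linkS4class{PartitionResult}),
#'   \code{sbi} (data frame), \code{sbiRegressions} (data frame).
#' @examples
#' st <- simulateStock(SimConfig(nYears = 15L, seed = 5L))
#' res <- runStockAnalysis(st, nPerm = 99)
#' res$partition
#' @export
runStockAnalysis <- function(stock, nPerm = 1000L, lagCandidates = NULL,
                             transform = c("proportions", "hellinger"),
                             minYears = 8L, seed = 1L, outDir = NULL) {
  transform <- match.arg(transform)
  m <- stockMeta(stock)
  fs <- forcing(stock)
  needF <- is.na(fs@F) & !is.na(fs@mu)
  if (any(needF)) {
    fs@F[needF] <- exploitationToF(fs@mu[needF], m@M)
    stock@forcing <- fs
  }
  part <- selectLagModel(stock, lagCandidates = lagCandidates,
                         nPerm = nPerm, seed = seed, minYears = minYears,
                         transform = transform)
  sbiTab <- computeSBITable(composition(stock))
  al0 <- alignYears(stock, 0L, minYears = minYears)
  sbiReg <- sbiRegressionTable(sbiTab, al0$years, al0$xFish, al0$xTemp)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    id <- stockId(stock)
    f <- reportedFractions(part)
    utils::write.csv(data.frame(
      stock = id, fishing = f[["fishing"]], interaction = f[["shared"]],
      temperature = f[["temperature"]], total = f[["total"]],
      p_fishing = part@pFishing, p_temperature = part@pTemperature,
      lag = part@lag),
      file.path(outDir, paste0(id, "_partition.csv")), row.names = FALSE)
    utils::write.csv(sbiTab, file.path(outDir, paste0(id, "_sbi.csv")),
                     row.names = FALSE)
    utils::write.csv(sbiReg,
                     file.path(outDir, paste0(id, "_sbi_regression.csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(stock = id, seed = seed, n_perm = nPerm,
           transform = transform, min_years = minYears,
           lag = part@lag, timestamp = format(Sys.time(), tz = "UTC")),
      file.path(outDir, paste0(id, "_provenance.json")),
      auto_unbox = TRUE)
  }
  list(partition = part, sbi = sbiTab, sbiRegressions = sbiReg)
}

#' Analyse a batch of stocks, tolerating per-stock failures
#'
#' Runs [runStockAnalysis()] over a list of stocks; a stock whose analysis
#' fails (e.g. too few aligned years) is recorded with its error message
#' and the batch continues.
#'
#' @param stocks List of \linkS4class{StockSeries}.
#' @param ... Passed to [runStockAnalysis()].
#' @return List with \code{results} (named list of per-stock results) and
#'   \code{failures} (named character vector of error messages).
#' @export
runStockBatch <- function(stocks, ...) {
  results <- list()
  failures <- character()
  for (st in stocks) {
    id <- stockId(st)
    r <- tryCatch(runStockAnalysis(st, ...), error = function(e)
      conditionMessage(e))
    if (is.character(r)) failures[[id]] <- r else results[[id]] <- r
  }
  list(results = results, failures = failures)
}

#' Build the cross-stock meta table
#'
#' One row per successfully analysed stock: reported (clamped) fractions,
#' permutation p-values, chosen lag, region, habitat, life-history traits,
#' and long-term forcing indices (mean and CV of the mortality ratio F/M
#' and of temperature, over the lag-0 aligned years).
#'
#' @param stocks Named list of \linkS4class{StockSeries} (names = stock
#'   ids).
#' @param results Named list of [runStockAnalysis()] results for (a subset
#'   of) the same ids.
#' @return Data frame keyed by \code{stock}.
#' @export
buildMetaTable <- function(stocks, results) {
  names(stocks) <- vapply(stocks, stockId, character(1))
  rows <- lapply(names(results), function(id) {
    st <- stocks[[id]]
    if (is.null(st)) stop("no StockSeries supplied for '", id, "'")
    part <- results[[id]]$partition
    m <- stockMeta(st)
    al <- alignYears(st, 0L, minYears = 2L)
    fm <- longTermIndices(mortalityRatioSeries(al$xFish, m@M))
    tp <- longTermIndices(al$xTemp)
    f <- reportedFractions(part)
    data.frame(stock = id, region = m@region, habitat = m@habitat,
               fracFishing = f[["fishing"]], fracShared = f[["shared"]],
               fracTemperature = f[["temperature"]],
               totalAdjR2 = f[["total"]], pFishing = part@pFishing,
               pTemperature = part@pTemperature, lag = part@lag,
               K = m@K, Linf = m@Linf, A50 = m@A50, L50 = m@L50,
               meanFM = fm$mean, cvFM = fm$cv, meanTemp = tp$mean,
               cvTemp = tp$cv)
  })
  do.call(rbind, rows)
}

#' Cross-stock meta-analysis
#'
#' Runs the full cross-stock stage on at least three analysed stocks:
#' paired effect comparisons (overall and, where groups allow, by region
#' and habitat), the univariate covariate screen and its mixed-model
#' check for both responses, and the p-value efficiency comparison of
#' variation partitioning against the univariate indicators.
#'
#' @param stocks Named list of \linkS4class{StockSeries}.
#' @param results Named list of [runStockAnalysis()] results.
#' @param outDir Optional directory for CSV outputs (meta table, paired
#'   comparisons, covariate screen, efficiency comparison).
#' @return List with \code{meta} (data frame), \code{paired},
#'   \code{covariateScreen}, \code{efficiency}.
#' @export
runMetaAnalysis <- function(stocks, results, outDir = NULL) {
  if (length(results) < 3L)
    stop("meta-analysis needs at least 3 successfully analysed stocks")
  meta <- buildMetaTable(stocks, results)

  paired <- pairedEffectComparisons(meta, "none")
  for (g in c("region", "habitat")) {
    if (length(unique(meta[[g]])) > 1L) {
      pg <- withCallingHandlers(
        pairedEffectComparisons(meta, g),
        warning = function(w) invokeRestart("muffleWarning"))
      if (!is.null(pg)) paired <- rbind(paired, pg)
    }
  }

  covs <- c("K", "Linf", "A50", "L50", "meanFM", "cvFM", "meanTemp",
            "cvTemp")
  naFit <- list(coef = NA_real_, p = NA_real_, method = "failed")
  screen <- do.call(rbind, lapply(c("fishing", "temperature"),
    function(resp) do.call(rbind, lapply(covs, function(cv) {
      # a covariate can be degenerate in a batch (e.g. identical traits);
      # record it rather than aborting the cross-stock stage
      ols <- tryCatch(fractionRegression(meta, resp, cv),
                      error = function(e) naFit)
      lmm <- tryCatch(fractionLmm(meta, resp, cv),
                      error = function(e) naFit)
      data.frame(response = resp, covariate = cv, coef = ols$coef,
                 p = ols$p, lmmCoef = lmm$coef, lmmP = lmm$p,
                 lmmMethod = lmm$method %||% "ols")
    }))))

  vpP <- do.call(rbind, lapply(names(results), function(id) {
    part <- results[[id]]$partition
    data.frame(stock = id, effect = c("fishing", "temperature"),
               p = c(part@pFishing, part@pTemperature))
  }))
  sbiP <- do.call(rbind, lapply(names(results), function(id) {
    sr <- results[[id]]$sbiRegressions
    sr <- sr[sr$term %in% c("fishing", "temperature"), ]
    data.frame(stock = id, effect = sr$term, sbi = sr$sbi, p = sr$p)
  }))
  efficiency <- pvalueEfficiencyComparison(vpP, sbiP)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(meta, file.path(outDir, "meta_table.csv"),
                     row.names = FALSE)
    utils::write.csv(paired, file.path(outDir, "paired_comparisons.csv"),
                     row.names = FALSE)
    utils::write.csv(screen, file.path(outDir, "covariate_screen.csv"),
                     row.names = FALSE)
    jsonlite::write_json(efficiency,
                         file.path(outDir, "efficiency_comparison.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(meta = meta, paired = paired, covariateScreen = screen,
       efficiency = efficiency)
}
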