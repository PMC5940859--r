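#' LengthComposition: annual length-frequency matrix of one stock
#'
#' Holds the survey (or fishery) length frequencies of a single stock as a
#' years-by-bins matrix of nonnegative frequencies, together with the
#' calendar years and the length-bin edges.  Bins are half-open
#' \eqn{[lower, upper)} intervals in centimetres; \code{binEdges} stores the
#' strictly increasing lower edges plus one terminal upper edge, so a matrix
#' with \eqn{m} bins carries \eqn{m + 1} edges.
#'
#' Validity requires: strictly increasing edges with at least two bins,
#' strictly increasing years, a counts matrix of matching dimensions with no
#' negative or missing entries, and a positive total in every year (an
#' all-zero year carries no size-structure information and is rejected at
#' construction).
#'
#' @slot years Integer vector of calendar years (strictly increasing; gaps
#'   allowed for stocks surveyed every 2--3 years).
#' @slot binEdges Numeric vector of bin edges in cm.
#' @slot counts Numeric matrix, \code{length(years)} rows by
#'   \code{length(binEdges) - 1} columns.
#'
#' @seealso [LengthComposition()] for the constructor,
#'   [toProportions()], [computeSBITable()]
#' @export
setClass("LengthComposition",
  representation(years = "integer", binEdges = "numeric", counts = "matrix"))

setValidity("LengthComposition", function(object) {
  msg <- character()
  e <- object@binEdges
  if (length(e) < 3L)
    msg <- c(msg, "need at least 2 bins (>= 3 bin edges)")
  if (anyNA(e) || any(diff(e) <= 0))
    msg <- c(msg, "binEdges must be strictly increasing and non-missing")
  y <- object@years
  if (length(y) < 1L || anyNA(y) || any(diff(y) <= 0))
    msg <- c(msg, "years must be non-empty, non-missing and strictly increasing")
  cts <- object@counts
  if (!is.numeric(cts))
    msg <- c(msg, "counts must be numeric")
  else {
    if (nrow(cts) != length(y) || ncol(cts) != length(e) - 1L)
      msg <- c(msg, "counts must be length(years) x (length(binEdges) - 1)")
    if (anyNA(cts) || any(cts < 0))
      msg <- c(msg, "counts must be nonnegative and non-missing")
    else if (nrow(cts) == length(y) && any(rowSums(cts) <= 0))
      msg <- c(msg, "every year must have a positive total count")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LengthComposition
#'
#' @param years Integer-like vector of calendar years.
#' @param binEdges Numeric bin edges (lower edges plus terminal upper edge).
#' @param counts Numeric matrix of frequencies, years in rows.
#' @return A validated \linkS4class{LengthComposition}.
#' @examples
#' lc <- LengthComposition(2001:2003, c(10, 20, 30, 40),
#'                         matrix(1, 3, 3))
#' counts(lc)
#' @export
LengthComposition <- function(years, binEdges, counts) {
  counts <- as.matrix(counts)
  dimnames(counts) <- list(as.character(years),
                           paste0("L", binEdges[-length(binEdges)]))
  new("LengthComposition", years = as.integer(years),
      binEdges = as.numeric(binEdges), counts = counts)
}

setMethod("show", "LengthComposition", function(object) {
  cat("LengthComposition:", length(object@years), "years (",
      min(object@years), "-", max(object@years), "), ",
      ncol(object@counts), " bins [", min(object@binEdges), ", ",
      max(object@binEdges), ") cm\n", sep = "")
})

#' ForcingSeries: annual fishing and temperature forcing of one stock
#'
#' Annual fishing pressure (instantaneous fishing mortality \code{F} in
#' 1/yr, or exploitation rate \code{mu} in \eqn{[0, 1)}) and temperature
#' (degrees C).  At least one of \code{F}/\code{mu} must be present in every
#' year; \code{NA} marks a missing value.
#'
#' @slot years Integer vector, strictly increasing.
#' @slot F Numeric, instantaneous fishing mortality (1/yr) or \code{NA}.
#' @slot mu Numeric, exploitation rate in \eqn{[0, 1)} or \code{NA}.
#' @slot temperature Numeric, degrees C (may contain \code{NA}).
#'
#' @seealso [ForcingSeries()], [exploitationToF()]
#' @export
setClass("ForcingSeries",
  representation(years = "integer", F = "numeric", mu = "numeric",
                 temperature = "numeric"))

setValidity("ForcingSeries", function(object) {
  msg <- character()
  y <- object@years
  n <- length(y)
  if (n < 1L || anyNA(y) || any(diff(y) <= 0))
    msg <- c(msg, "years must be non-empty, non-missing and strictly increasing")
  for (s in c("F", "mu", "temperature"))
    if (length(slot(object, s)) != n)
      msg <- c(msg, sprintf("slot '%s' must have one value per year", s))
  if (any(object@F < 0, na.rm = TRUE))
    msg <- c(msg, "F must be >= 0 where present")
  if (any(object@mu < 0 | object@mu >= 1, na.rm = TRUE))
    msg <- c(msg, "mu must lie in [0, 1) where present")
  if (length(object@F) == n && any(is.na(object@F) & is.na(object@mu)))
    msg <- c(msg, "every year needs F or mu")
  if (length(msg)) msg else TRUE
})

#' Construct a ForcingSeries
#'
#' @param years Integer-like vector of calendar years.
#' @param F Annual instantaneous fishing mortality (1/yr); \code{NA} allowed
#'   where \code{mu} is given.
#' @param mu Annual exploitation rate in \eqn{[0, 1)}; default all \code{NA}.
#' @param temperature Annual temperature (degrees C).
#' @return A validated \linkS4class{ForcingSeries}.
#' @export
ForcingSeries <- function(years, F = rep(NA_real_, length(years)),
                          mu = rep(NA_real_, length(years)),
                          temperature) {
  new("ForcingSeries", years = as.integer(years), F = as.numeric(F),
      mu = as.numeric(mu), temperature = as.numeric(temperature))
}

setMethod("show", "ForcingSeries", function(object) {
  cat("ForcingSeries:", length(object@years), "years (",
      min(object@years), "-", max(object@years), "); F present in ",
      sum(!is.na(object@F)), ", mu in ", sum(!is.na(object@mu)),
      ", temperature in ", sum(!is.na(object@temperature)), "\n", sep = "")
})

#' StockMeta: metadata and life-history traits of one stock
#'
#' @slot stockId Character identifier.
#' @slot region One of \code{"WestUS"}, \code{"Alaska"}, \code{"NorthSea"},
#'   \code{"other"}.
#' @slot habitat One of \code{"pelagic"}, \code{"demersal"}, \code{"benthic"}.
#' @slot samplingInterval Integer, survey interval in years (>= 1).
#' @slot M Natural mortality (1/yr, constant for the stock).
#' @slot K von Bertalanffy growth rate (1/yr).
#' @slot Linf Asymptotic length (cm).
#' @slot A50 Age at 50\% maturity (yr).
#' @slot L50 Length at 50\% maturity (cm); must be below \code{Linf}.
#' @export
setClass("StockMeta",
  representation(stockId = "character", region = "character",
                 habitat = "character", samplingInterval = "integer",
                 M = "numeric", K = "numeric", Linf = "numeric",
                 A50 = "numeric", L50 = "numeric"))

.regions <- c("WestUS", "Alaska", "NorthSea", "other")
.habitats <- c("pelagic", "demersal", "benthic")

setValidity("StockMeta", function(object) {
  msg <- character()
  if (length(object@stockId) != 1L || !nzchar(object@stockId))
    msg <- c(msg, "stockId must be a single non-empty string")
  if (!object@region %in% .regions)
    msg <- c(msg, paste("region must be one of:", paste(.regions, collapse = ", ")))
  if (!object@habitat %in% .habitats)
    msg <- c(msg, paste("habitat must be one of:", paste(.habitats, collapse = ", ")))
  if (length(object@samplingInterval) != 1L || is.na(object@samplingInterval) ||
      object@samplingInterval < 1L)
    msg <- c(msg, "samplingInterval must be an integer >= 1")
  for (s in c("M", "K", "Linf"))
    if (!isTRUE(slot(object, s) > 0))
      msg <- c(msg, sprintf("%s must be > 0", s))
  if (!isTRUE(object@L50 < object@Linf))
    msg <- c(msg, "L50 must be smaller than Linf")
  if (length(msg)) msg else TRUE
})

#' Construct a StockMeta
#'
#' @param stockId Stock identifier string.
#' @param region Region label (\code{"WestUS"}, \code{"Alaska"},
#'   \code{"NorthSea"} or \code{"other"}).
#' @param habitat Habitat type (\code{"pelagic"}, \code{"demersal"},
#'   \code{"benthic"}).
#' @param samplingInterval Survey interval in years.
#' @param M Natural mortality (1/yr).
#' @param K,Linf,A50,L50 Life-history traits: von Bertalanffy growth rate
#'   (1/yr), asymptotic length (cm), age and length at 50\% maturity.
#' @return A validated \linkS4class{StockMeta}.
#' @export
StockMeta <- function(stockId, region = "other", habitat = "demersal",
                      samplingInterval = 1L, M, K, Linf, A50, L50) {
  new("StockMeta", stockId = as.character(stockId), region = region,
      habitat = habitat, samplingInterval = as.integer(samplingInterval),
      M = as.numeric(M), K = as.numeric(K), Linf = as.numeric(Linf),
      A50 = as.numeric(A50), L50 = as.numeric(L50))
}

setMethod("show", "StockMeta", function(object) {
  cat("StockMeta '", object@stockId, "': ", object@region, "/",
      object@habitat, "; M=", object@M, ", K=", object@K, ", Linf=",
      object@Linf, " cm, A50=", object@A50, " yr, L50=", object@L50,
      " cm\n", sep = "")
})

#' StockSeries: the unit of analysis
#'
#' Bundles one stock's length composition, forcing series and metadata.
#' Validity requires a non-empty overlap between composition and forcing
#' years; the per-analysis minimum (default 8 aligned years) is enforced at
#' alignment time, where the temperature lag is known.
#'
#' @slot meta A \linkS4class{StockMeta}.
#' @slot composition A \linkS4class{LengthComposition}.
#' @slot forcing A \linkS4class{ForcingSeries}.
#' @seealso [alignYears()], [runStockAnalysis()], [simulateStock()]
#' @export
setClass("StockSeries",
  representation(meta = "StockMeta", composition = "LengthComposition",
                 forcing = "ForcingSeries"))

setValidity("StockSeries", function(object) {
  ov <- intersect(object@composition@years, object@forcing@years)
  if (length(ov) == 0L)
    "composition and forcing years do not overlap"
  else TRUE
})

#' Construct a StockSeries
#'
#' @param meta A \linkS4class{StockMeta}.
#' @param composition A \linkS4class{LengthComposition}.
#' @param forcing A \linkS4class{ForcingSeries}.
#' @return A validated \linkS4class{StockSeries}.
#' @export
StockSeries <- function(meta, composition, forcing) {
  new("StockSeries", meta = meta, composition = composition,
      forcing = forcing)
}

setMethod("show", "StockSeries", function(object) {
  cat("StockSeries '", object@meta@stockId, "'\n", sep = "")
  show(object@composition)
  show(object@forcing)
})

#' RDAFit: summary of one redundancy-analysis fit
#'
#' @slot r2 Fraction of the total (column-centred) response sum of squares
#'   explained by the predictors (after removing any conditioning set).
#' @slot adjR2 Ezekiel-adjusted R-squared (may be negative).
#' @slot n Number of rows.
#' @slot p Number of predictor columns.
#' @slot q Number of conditioning columns (0 for a plain RDA).
#' @slot pseudoF Constrained-ordination test statistic,
#'   \eqn{(SS_{exp}/p) / (SS_{res}/(n-p-q-1))}.
#' @seealso [rdaR2()]
#' @export
setClass("RDAFit",
  representation(r2 = "numeric", adjR2 = "numeric", n = "integer",
                 p = "integer", q = "integer", pseudoF = "numeric"))

setMethod("show", "RDAFit", function(object) {
  cat(sprintf("RDAFit: R2 = %.4f, adjR2 = %.4f (n = %d, p = %d, q = %d), pseudo-F = %.3f\n",
              object@r2, object@adjR2, object@n, object@p, object@q,
              object@pseudoF))
})

#' PartitionResult: two-set variation partition of a size composition
#'
#' Adjusted-R-squared fractions of the year-to-year variation in length
#' composition attributed to fishing alone, temperature alone, their shared
#' component, and the residual.  Fractions are stored unclamped (the shared
#' fraction, and small pure fractions, can be negative); use
#' [reportedFractions()] for the clamped three-decimal report convention.
#' The shared fraction has no permutation test.
#'
#' @slot fracFishing Pure fishing fraction (adjusted).
#' @slot fracShared Shared fishing-temperature fraction (adjusted).
#' @slot fracTemperature Pure temperature fraction (adjusted).
#' @slot fracResidual \code{1 - totalAdjR2}.
#' @slot totalAdjR2 Adjusted R-squared of the joint model; equals
#'   \code{fracFishing + fracShared + fracTemperature} to rounding.
#' @slot pFishing,pTemperature Permutation p-values of the pure fractions
#'   (\code{NA} when not computed).
#' @slot lag Temperature lag (years) used.
#' @slot nYears Number of aligned years.
#' @seealso [partitionFishingTemperature()], [selectLagModel()]
#' @export
setClass("PartitionResult",
  representation(fracFishing = "numeric", fracShared = "numeric",
                 fracTemperature = "numeric", fracResidual = "numeric",
                 totalAdjR2 = "numeric", pFishing = "numeric",
                 pTemperature = "numeric", lag = "integer",
                 nYears = "integer"))

setValidity("PartitionResult", function(object) {
  tot <- object@fracFishing + object@fracShared + object@fracTemperature
  if (abs(tot - object@totalAdjR2) > 1e-08)
    "fractions do not sum to totalAdjR2"
  else TRUE
})

setMethod("show", "PartitionResult", function(object) {
  f <- reportedFractions(object)
  cat(sprintf("PartitionResult (lag %d, %d years):\n", object@lag,
              object@nYears))
  cat(sprintf("  fishing     %.3f  (p = %s)\n", f[["fishing"]],
              format(object@pFishing, digits = 3)))
  cat(sprintf("  shared      %.3f  (not testable)\n", f[["shared"]]))
  cat(sprintf("  temperature %.3f  (p = %s)\n", f[["temperature"]],
              format(object@pTemperature, digits = 3)))
  cat(sprintf("  total adjR2 %.3f\n", object@totalAdjR2))
})

#' SimConfig: parameters of the synthetic stock generator
#'
#' All parameters of the seeded age-structured simulator.  Defaults describe
#' a moderately long-lived demersal stock sampled annually for 35 years by a
#' survey with the fishery's size selectivity, under a fishing ramp from 0.1
#' to 0.8 per year and AR(1) temperature forcing recruitment at a 1-year
#' lag.  See the package vignette for the rationale behind each default.
#'
#' @slot nYears Number of simulated survey years.
#' @slot Amax Maximum age tracked (plus group omitted; cohorts older than
#'   \code{Amax} are dropped).  \code{NA} = choose so that cumulative
#'   natural survival falls below 1\%, capped at 40.
#' @slot Linf,K,a0 von Bertalanffy parameters (cm, 1/yr, yr).
#' @slot cvLength CV of length-at-age (lognormal-ish spread, applied as a
#'   normal sd \code{cvLength * meanLength}).
#' @slot M Natural mortality (1/yr).
#' @slot selL50,selSlope Logistic fishery selectivity in length: length at
#'   50\% selection (cm) and slope (1/cm).
#' @slot surveyL50,surveySlope Survey selectivity; \code{NA} = reuse the
#'   fishery selectivity.
#' @slot R0 Mean recruitment (numbers).
#' @slot betaT Log-scale recruitment response per degree C of temperature
#'   anomaly.
#' @slot sigmaR Lognormal recruitment sd (log scale).
#' @slot recLag Years between the temperature anomaly and the recruitment it
#'   forces.
#' @slot tempMean,tempRho,tempSd AR(1) temperature process: mean (degrees
#'   C), autocorrelation in (-1, 1), innovation sd.
#' @slot fStart,fEnd,fWalkSd Fishing trajectory: linear ramp endpoints
#'   (1/yr) plus reflected Gaussian random-walk noise.
#' @slot nSample Individuals measured per survey year (multinomial size).
#' @slot binWidth Length-bin width (cm).
#' @slot seed Integer RNG seed.
#' @seealso [simulateStock()], [simulateTemperature()], [simulateFishing()]
#' @export
setClass("SimConfig",
  representation(nYears = "integer", Amax = "integer", Linf = "numeric",
                 K = "numeric", a0 = "numeric", cvLength = "numeric",
                 M = "numeric", selL50 = "numeric", selSlope = "numeric",
                 surveyL50 = "numeric", surveySlope = "numeric",
                 R0 = "numeric", betaT = "numeric", sigmaR = "numeric",
                 recLag = "integer", tempMean = "numeric",
                 tempRho = "numeric", tempSd = "numeric",
                 fStart = "numeric", fEnd = "numeric", fWalkSd = "numeric",
                 nSample = "integer", binWidth = "numeric",
                 seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nYears < 2L) msg <- c(msg, "nYears must be >= 2")
  for (s in c("Linf", "K", "cvLength", "M", "selSlope", "R0", "binWidth"))
    if (!isTRUE(slot(object, s) > 0))
      msg <- c(msg, sprintf("%s must be > 0", s))
  if (abs(object@tempRho) >= 1) msg <- c(msg, "tempRho must lie in (-1, 1)")
  if (object@nSample < 100L) msg <- c(msg, "nSample must be >= 100")
  for (s in c("sigmaR", "tempSd", "fWalkSd", "fStart", "fEnd"))
    if (slot(object, s) < 0)
      msg <- c(msg, sprintf("%s must be >= 0", s))
  if (object@recLag < 0L) msg <- c(msg, "recLag must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' @param nYears,Amax,Linf,K,a0,cvLength,M,selL50,selSlope,surveyL50,surveySlope
#'   See \linkS4class{SimConfig}.
#' @param R0,betaT,sigmaR,recLag,tempMean,tempRho,tempSd See
#'   \linkS4class{SimConfig}.
#' @param fStart,fEnd,fWalkSd,nSample,binWidth,seed See
#'   \linkS4class{SimConfig}.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- SimConfig(seed = 7L)
#' cfg
#' @export
SimConfig <- function(nYears = 35L, Amax = NA_integer_, Linf = 60,
                      K = 0.25, a0 = -0.5, cvLength = 0.12, M = 0.25,
                      selL50 = 35, selSlope = 0.25, surveyL50 = NA_real_,
                      surveySlope = NA_real_, R0 = 1e6, betaT = 0.25,
                      sigmaR = 0.4, recLag = 1L, tempMean = 8,
                      tempRho = 0.5, tempSd = 0.6, fStart = 0.1,
                      fEnd = 0.8, fWalkSd = 0.05, nSample = 5000L,
                      binWidth = 2, seed = 1L) {
  if (is.na(Amax))
    Amax <- min(as.integer(ceiling(log(100) / M)), 40L)
  new("SimConfig", nYears = as.integer(nYears), Amax = as.integer(Amax),
      Linf = Linf, K = K, a0 = a0, cvLength = cvLength, M = M,
      selL50 = selL50, selSlope = selSlope, surveyL50 = surveyL50,
      surveySlope = surveySlope, R0 = R0, betaT = betaT, sigmaR = sigmaR,
      recLag = as.integer(recLag), tempMean = tempMean, tempRho = tempRho,
      tempSd = tempSd, fStart = fStart, fEnd = fEnd, fWalkSd = fWalkSd,
      nSample = as.integer(nSample), binWidth = binWidth,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d years, ages 0-%d, Linf=%g K=%g M=%g; F %g->%g; betaT=%g lag %d; nSample=%d, bins %g cm; seed %d\n",
              object@nYears, object@Amax, object@Linf, object@K, object@M,
              object@fStart, object@fEnd, object@betaT, object@recLag,
              object@nSample, object@binWidth, object@seed))
})
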