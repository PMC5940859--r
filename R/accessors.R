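#' @describeIn LengthComposition Calendar years.
#' @param x,... See the generic.
#' @export
setMethod("years", "LengthComposition", function(x, ...) x@years)

#' @describeIn LengthComposition Bin edges (cm).
#' @export
setMethod("binEdges", "LengthComposition", function(x, ...) x@binEdges)

#' @describeIn LengthComposition Frequency matrix (years by bins).
#' @export
setMethod("counts", "LengthComposition", function(x, ...) x@counts)

#' @describeIn ForcingSeries Calendar years.
#' @param x,... See the generic.
#' @export
setMethod("years", "ForcingSeries", function(x, ...) x@years)

#' @describeIn StockSeries The length composition.
#' @param x,... See the generic.
#' @export
setMethod("composition", "StockSeries", function(x, ...) x@composition)

#' @describeIn StockSeries The forcing series.
#' @export
setMethod("forcing", "StockSeries", function(x, ...) x@forcing)

#' @describeIn StockSeries The stock metadata.
#' @export
setMethod("stockMeta", "StockSeries", function(x, ...) x@meta)

#' @describeIn StockSeries The stock identifier.
#' @export
setMethod("stockId", "StockSeries", function(x, ...) x@meta@stockId)

#' @describeIn StockMeta The stock identifier.
#' @param x,... See the generic.
#' @export
setMethod("stockId", "StockMeta", function(x, ...) x@stockId)

#' @describeIn PartitionResult Clamped, three-decimal fractions as reported
#'   in partition tables (\code{fishing}, \code{shared}, \code{temperature},
#'   \code{total}); totals keep the unclamped arithmetic.
#' @param x,... See the generic.
#' @export
setMethod("reportedFractions", "PartitionResult", function(x, ...) {
  c(fishing = round(max(x@fracFishing, 0), 3),
    shared = round(max(x@fracShared, 0), 3),
    temperature = round(max(x@fracTemperature, 0), 3),
    total = round(max(x@totalAdjR2, 0), 3))
})
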