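#' Read a stock from delimited text files
#'
#' Reads one stock's length composition from a tidy CSV with columns
#' \code{year}, \code{bin_lower}, \code{count}; its forcing series from a
#' CSV with columns \code{year}, then \code{F} and/or \code{mu}, and
#' \code{T}; and its metadata from a YAML file whose keys match
#' \linkS4class{StockMeta} (\code{stock_id}, \code{region}, \code{habitat},
#' \code{sampling_interval_years}, \code{M}, \code{K}, \code{L_inf},
#' \code{A_50}, \code{L_50}) plus \code{terminal_edge}, the upper edge of
#' the last length bin.  Bin edges are assembled from the sorted distinct
#' \code{bin_lower} values plus the declared terminal edge; a year/bin pair
#' absent from the file is a zero count.
#'
#' @param path Composition CSV path.
#' @param metaPath Metadata YAML path.
#' @param forcingPath Forcing CSV path.
#' @return A validated \linkS4class{StockSeries}.
#' @seealso [writeStockSeries()] writes the same three files.
#' @examples
#' d <- tempfile(); dir.create(d)
#' st <- simulateStock(SimConfig(nYears = 12L, seed = 1L))
#' paths <- writeStockSeries(st, d)
#' st2 <- readStockSeries(paths$composition, paths$meta, paths$forcing)
#' stockId(st2)
#' @export
readStockSeries <- function(path, metaPath, forcingPath) {
  comp <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "bin_lower", "count")
  if (!all(need %in% names(comp)))
    stop("composition file must have columns: ", paste(need, collapse = ", "))
  if (any(is.na(comp$count)) || any(comp$count < 0))
    stop("negative or missing counts in composition file")
  if (anyDuplicated(comp[c("year", "bin_lower")]))
    stop("duplicate (year, bin_lower) rows in composition file")

  ml <- yaml::read_yaml(metaPath)
  needMeta <- c("stock_id", "M", "K", "L_inf", "A_50", "L_50",
                "terminal_edge")
  miss <- setdiff(needMeta, names(ml))
  if (length(miss))
    stop("metadata is missing fields: ", paste(miss, collapse = ", "))
  meta <- StockMeta(stockId = ml$stock_id,
                    region = ml$region %||% "other",
                    habitat = ml$habitat %||% "demersal",
                    samplingInterval = ml$sampling_interval_years %||% 1L,
                    M = ml$M, K = ml$K, Linf = ml$L_inf, A50 = ml$A_50,
                    L50 = ml$L_50)

  lowers <- sort(unique(comp$bin_lower))
  edges <- c(lowers, ml$terminal_edge)
  yrs <- sort(unique(comp$year))
  cts <- matrix(0, length(yrs), length(lowers))
  cts[cbind(match(comp$year, yrs), match(comp$bin_lower, lowers))] <-
    comp$count
  lc <- LengthComposition(yrs, edges, cts)

  fc <- utils::read.csv(forcingPath, stringsAsFactors = FALSE)
  if (!all(c("year", "T") %in% names(fc)) ||
      !any(c("F", "mu") %in% names(fc)))
    stop("forcing file must have columns year, T and F and/or mu")
  fc <- fc[order(fc$year), , drop = FALSE]
  fs <- ForcingSeries(fc$year,
                      F = if ("F" %in% names(fc)) fc$F else NA,
                      mu = if ("mu" %in% names(fc)) fc$mu else NA,
                      temperature = fc$T)
  StockSeries(meta, lc, fs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a stock to delimited text files
#'
#' Inverse of [readStockSeries()]: writes \code{<id>_composition.csv} (tidy
#' year/bin_lower/count; zero cells are kept so interior bins that happen
#' to be empty survive the round trip), \code{<id>_meta.yaml} and
#' \code{<id>_forcing.csv} into \code{dir}.
#'
#' @param stock A \linkS4class{StockSeries}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the three file paths.
#' @export
writeStockSeries <- function(stock, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- stockId(stock)
  lc <- composition(stock)
  e <- binEdges(lc)
  cts <- counts(lc)
  tidy <- data.frame(
    year = rep(years(lc), times = ncol(cts)),
    bin_lower = rep(e[-length(e)], each = nrow(cts)),
    count = as.vector(cts))
  tidy <- tidy[order(tidy$year, tidy$bin_lower), ]
  compPath <- file.path(dir, paste0(id, "_composition.csv"))
  utils::write.csv(tidy, compPath, row.names = FALSE)

  m <- stockMeta(stock)
  metaPath <- file.path(dir, paste0(id, "_meta.yaml"))
  yaml::write_yaml(list(
    stock_id = m@stockId, region = m@region, habitat = m@habitat,
    sampling_interval_years = m@samplingInterval, M = m@M, K = m@K,
    L_inf = m@Linf, A_50 = m@A50, L_50 = m@L50,
    terminal_edge = e[length(e)]), metaPath)

  fs <- forcing(stock)
  forcingPath <- file.path(dir, paste0(id, "_forcing.csv"))
  utils::write.csv(data.frame(year = fs@years, F = fs@F, mu = fs@mu,
                              T = fs@temperature),
                   forcingPath, row.names = FALSE)
  invisible(list(composition = compPath, meta = metaPath,
                 forcing = forcingPath))
}

#' @describeIn toProportions Divide each year's counts by its total; errors
#'   on a zero-total year.
#' @export
setMethod("toProportions", "LengthComposition", function(x, ...) {
  tot <- rowSums(x@counts)
  if (any(tot <= 0))
    stop("zero-total year(s): ", paste(x@years[tot <= 0], collapse = ", "))
  LengthComposition(x@years, x@binEdges, x@counts / tot)
})

#' Hellinger transform of a length composition
#'
#' Square root of the per-year proportions, a standard composition transform
#' that makes Euclidean-based ordination appropriate for relative data.
#'
#' @param comp A \linkS4class{LengthComposition}.
#' @return A \linkS4class{LengthComposition} holding
#'   \eqn{\sqrt{p_{ti}}} values.
#' @export
hellingerTransform <- function(comp) {
  p <- toProportions(comp)
  LengthComposition(p@years, p@binEdges, sqrt(p@counts))
}

#' Align composition and forcing years at a temperature lag
#'
#' Builds the response matrix and forcing vectors for variation
#' partitioning: for each retained year \eqn{t}, the response row is the
#' length-composition proportions (optionally Hellinger-transformed) at
#' \eqn{t}, fishing is \eqn{F_t} (fishing is never lagged), and temperature
#' is \eqn{T_{t - lag}}.  Years lacking any of the three values are
#' dropped, order is preserved, and length bins whose total over the
#' retained years is zero are removed (they carry no variance).
#'
#' @param stock A \linkS4class{StockSeries} whose forcing has \code{F} in
#'   every analysis year (convert \code{mu} first with
#'   [exploitationToF()]; [runStockAnalysis()] does this automatically).
#' @param tempLag Temperature lag in years (>= 0).
#' @param minYears Minimum aligned rows required (default 8).
#' @param transform \code{"proportions"} (default) or \code{"hellinger"}.
#' @return A list with \code{Y} (years by bins matrix), \code{xFish},
#'   \code{xTemp}, \code{years}, \code{binEdges}.
#' @examples
#' st <- simulateStock(SimConfig(nYears = 15L, seed = 1L))
#' a <- alignYears(st, tempLag = 1L)
#' dim(a$Y); range(rowSums(a$Y))
#' @export
alignYears <- function(stock, tempLag, minYears = 8L,
                       transform = c("proportions", "hellinger")) {
  transform <- match.arg(transform)
  stopifnot(tempLag >= 0)
  lc <- composition(stock)
  fs <- forcing(stock)
  keep <- logical(length(lc@years))
  xFish <- xTemp <- numeric(length(lc@years))
  for (i in seq_along(lc@years)) {
    t <- lc@years[i]
    iF <- match(t, fs@years)
    iT <- match(t - tempLag, fs@years)
    ok <- !is.na(iF) && !is.na(fs@F[iF]) && !is.na(iT) &&
      !is.na(fs@temperature[iT])
    keep[i] <- ok
    if (ok) {
      xFish[i] <- fs@F[iF]
      xTemp[i] <- fs@temperature[iT]
    }
  }
  if (sum(keep) < minYears)
    stop(sprintf("only %d aligned year(s) at lag %d; need >= %d",
                 sum(keep), tempLag, minYears))
  p <- if (transform == "hellinger") hellingerTransform(lc)
       else toProportions(lc)
  Y <- p@counts[keep, , drop = FALSE]
  occupied <- colSums(counts(lc)[keep, , drop = FALSE]) > 0
  list(Y = Y[, occupied, drop = FALSE], xFish = xFish[keep],
       xTemp = xTemp[keep], years = lc@years[keep],
       binEdges = binEdges(lc))
}
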