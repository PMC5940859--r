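#' Two-set variation partition of a length composition
#'
#' Decomposes the year-to-year variation of the response matrix into the
#' pure fishing fraction \eqn{a}, the shared fraction \eqn{b}, the pure
#' temperature fraction \eqn{c} and the residual, using differences of
#' Ezekiel-adjusted R-squared values: with \eqn{A_f}, \eqn{A_t},
#' \eqn{A_{ft}} the adjusted R-squared of the fishing-only, temperature-only
#' and joint RDA models,
#' \deqn{a = A_{ft} - A_t, \quad c = A_{ft} - A_f, \quad
#'       b = A_f + A_t - A_{ft}.}
#' Fractions are stored unclamped (the shared fraction in particular can be
#' negative); [reportedFractions()] applies the clamped three-decimal report
#' convention.  The identity \eqn{a + b + c = A_{ft}} holds to rounding.
#'
#' With \code{nPerm > 0}, permutation p-values are attached for the two
#' pure fractions (the shared fraction is not testable): the observed
#' statistic is the pseudo-F of the partial RDA of one forcing given the
#' other, and the null distribution permutes the residual rows of the
#' reduced model (see [permutationTestFraction()]).
#'
#' @param Y Response matrix (years by bins), typically from [alignYears()].
#' @param xFish,xTemp Aligned forcing vectors.
#' @param nPerm Number of permutations for the significance tests (0 skips
#'   them; 1000 is the conventional choice).
#' @param seed Integer seed for the permutation tests.
#' @param lag Temperature lag to record in the result (bookkeeping only).
#' @return A \linkS4class{PartitionResult}.
#' @examples
#' st <- simulateStock(SimConfig(nYears = 20L, seed = 3L))
#' a <- alignYears(st, tempLag = 0L)
#' partitionFishingTemperature(a$Y, a$xFish, a$xTemp, nPerm = 99, seed = 1)
#' @export
partitionFishingTemperature <- function(Y, xFish, xTemp, nPerm = 0L,
                                        seed = 1L, lag = 0L) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Af <- rdaR2(Y, xFish)@adjR2
  At <- rdaR2(Y, xTemp)@adjR2
  Aft <- rdaR2(Y, cbind(fish = xFish, temp = xTemp))@adjR2
  a <- Aft - At
  c_ <- Aft - Af
  b <- Af + At - Aft
  pF <- pT <- NA_real_
  if (nPerm > 0) {
    pF <- permutationTestFraction(Y, xFish, xTemp, nPerm = nPerm,
                                  seed = seed)
    pT <- permutationTestFraction(Y, xTemp, xFish, nPerm = nPerm,
                                  seed = seed + 1L)
  }
  new("PartitionResult", fracFishing = a, fracShared = b,
      fracTemperature = c_, fracResidual = 1 - Aft, totalAdjR2 = Aft,
      pFishing = pF, pTemperature = pT, lag = as.integer(lag),
      nYears = as.integer(n))
}

#' Permutation test of a pure fraction (partial RDA pseudo-F)
#'
#' Tests the pure contribution of \code{xFocal} to \code{Y} given
#' \code{xCond}.  The observed statistic is the pseudo-F of the partial RDA
#' \code{Y ~ xFocal | xCond}.  Null replicates permute the rows of the
#' residuals of the reduced model \code{Y ~ xCond} (residuals-under-reduced-
#' model scheme), refit, and recompute pseudo-F; the p-value is
#' \eqn{(\#\{F^* \ge F_{obs}\} + 1) / (nPerm + 1)}.  Deterministic given
#' \code{seed}.
#'
#' @param Y Response matrix.
#' @param xFocal Focal predictor (vector or matrix).
#' @param xCond Conditioning predictor(s), or \code{NULL} to test a plain
#'   RDA against row permutations of centred \code{Y}.
#' @param nPerm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return Permutation p-value in \eqn{(0, 1]}.
#' @export
permutationTestFraction <- function(Y, xFocal, xCond = NULL, nPerm = 1000L,
                                    seed = 1L) {
  if (nPerm < 99) stop("nPerm must be >= 99 for usable p-value resolution")
  Y <- centerCols(as.matrix(Y))
  n <- nrow(Y)
  if (n < 10)
    warning("permutation test on fewer than 10 rows has coarse resolution")
  X <- centerCols(as.matrix(xFocal))
  p <- ncol(X)
  qrW <- NULL
  q <- 0L
  R <- Y
  Xr <- X
  if (!is.null(xCond)) {
    W <- centerCols(as.matrix(xCond))
    qrW0 <- qr(W)
    if (qrW0$rank > 0L) {   # a constant conditioning set conditions on nothing
      qrW <- qrW0
      q <- qrW0$rank
      R <- Y - qr.fitted(qrW, Y)
      Xr <- qr.resid(qrW, X)
    }
  }
  df2 <- n - p - q - 1L
  if (df2 < 1) stop("insufficient degrees of freedom for the pseudo-F test")
  qrX <- qr(Xr)
  if (qrX$rank == 0L) {
    warning("focal predictor is degenerate (constant or aliased by the conditioning set); p = 1")
    return(1)
  }
  p <- qrX$rank
  # orthonormal basis of the focal space for fast projections
  Qx <- qr.Q(qrX)[, seq_len(p), drop = FALSE]

  statOf <- function(Rmat) {
    # Rmat: reduced-model residuals (already orthogonal to W for observed;
    # permuted copies are re-residualised below before calling this)
    ssExp <- sum(crossprod(Qx, Rmat)^2)
    ssRes <- sum(Rmat^2) - ssExp
    (ssExp / p) / (ssRes / df2)
  }
  fObs <- statOf(R)
  withSeed(seed, {
    count <- 0L
    for (i in seq_len(nPerm)) {
      Rp <- R[sample.int(n), , drop = FALSE]
      if (!is.null(qrW)) Rp <- qr.resid(qrW, Rp)
      else Rp <- centerCols(Rp)
      if (statOf(Rp) >= fObs) count <- count + 1L
    }
    (count + 1) / (nPerm + 1)
  })
}

#' Default temperature-lag candidates
#'
#' Annually sampled stocks consider lags \{0, 1, 3\}; stocks surveyed every
#' 2--3 years consider \{0, 2, 3\} (a 1-year lag is not resolvable between
#' surveys).  \code{restrictMultiYear = TRUE} drops lag 0 for multi-year
#' stocks, leaving \{2, 3\}.
#'
#' @param samplingInterval Survey interval in years.
#' @param restrictMultiYear Drop lag 0 for multi-year sampled stocks.
#' @return Integer vector of candidate lags.
#' @export
defaultLagCandidates <- function(samplingInterval,
                                 restrictMultiYear = FALSE) {
  if (samplingInterval > 1L) {
    if (restrictMultiYear) c(2L, 3L) else c(0L, 2L, 3L)
  } else c(0L, 1L, 3L)
}

#' Lag model selection for one stock
#'
#' Runs [alignYears()] and [partitionFishingTemperature()] at each candidate
#' temperature lag and keeps the model with the largest total adjusted
#' R-squared (effect size); ties break toward the smaller lag (parsimony).
#' Permutation p-values are computed for the selected model only.
#'
#' @param stock A \linkS4class{StockSeries} with \code{F} available (see
#'   [alignYears()]).
#' @param lagCandidates Integer vector of lags; default from
#'   [defaultLagCandidates()] based on the stock's sampling interval.
#' @param nPerm Permutations for the selected model's significance tests.
#' @param seed Integer seed.
#' @param minYears Minimum aligned years per candidate.
#' @param transform Passed to [alignYears()].
#' @return A \linkS4class{PartitionResult} with the chosen lag recorded.
#' @export
selectLagModel <- function(stock, lagCandidates = NULL, nPerm = 1000L,
                           seed = 1L, minYears = 8L,
                           transform = c("proportions", "hellinger")) {
  transform <- match.arg(transform)
  if (is.null(lagCandidates))
    lagCandidates <- defaultLagCandidates(stockMeta(stock)@samplingInterval)
  if (!length(lagCandidates)) stop("no lag candidates supplied")
  lagCandidates <- sort(as.integer(lagCandidates))
  fits <- list()
  for (lag in lagCandidates) {
    al <- tryCatch(alignYears(stock, lag, minYears = minYears,
                              transform = transform),
                   error = function(e) NULL)
    if (is.null(al)) next
    fits[[as.character(lag)]] <- al
  }
  if (!length(fits))
    stop("no lag candidate yields enough aligned years for '",
         stockId(stock), "'")
  totals <- vapply(fits, function(al) {
    rdaR2(al$Y, cbind(al$xFish, al$xTemp))@adjR2
  }, numeric(1))
  # candidates are sorted ascending, so which.max takes the smallest lag
  # among ties
  best <- names(fits)[which.max(totals)]
  al <- fits[[best]]
  partitionFishingTemperature(al$Y, al$xFish, al$xTemp, nPerm = nPerm,
                              seed = seed, lag = as.integer(best))
}
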