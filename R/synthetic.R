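#' Simulate an AR(1) temperature series
#'
#' \eqn{T_t = \bar T + \rho (T_{t-1} - \bar T) + \epsilon_t},
#' \eqn{\epsilon_t \sim N(0, sd^2)}, started at the stationary distribution
#' (or at the mean when \eqn{sd = 0}).  Seeded and reproducible.
#'
#' @param cfg A \linkS4class{SimConfig}.
#' @param n Number of years (default \code{cfg@nYears}).
#' @param seed Seed (default \code{cfg@seed}).
#' @return Numeric vector of temperatures (degrees C).
#' @export
simulateTemperature <- function(cfg, n = cfg@nYears, seed = cfg@seed) {
  withSeed(seed, {
    out <- numeric(n)
    statSd <- cfg@tempSd / sqrt(1 - cfg@tempRho^2)
    out[1] <- cfg@tempMean + stats::rnorm(1, 0, statSd)
    for (t in seq_len(n - 1))
      out[t + 1] <- cfg@tempMean + cfg@tempRho * (out[t] - cfg@tempMean) +
        stats::rnorm(1, 0, cfg@tempSd)
    out
  })
}

#' Simulate a fishing-mortality trajectory
#'
#' Linear ramp from \code{fStart} to \code{fEnd} plus a Gaussian random
#' walk of step sd \code{fWalkSd}, reflected at zero so \eqn{F_t \ge 0}.
#'
#' The default seed is offset from the configuration seed so the fishing
#' and temperature innovations are independent streams.
#'
#' @inheritParams simulateTemperature
#' @return Numeric vector of fishing mortalities (1/yr).
#' @export
simulateFishing <- function(cfg, n = cfg@nYears,
                            seed = cfg@seed + 1000003L) {
  withSeed(seed, {
    ramp <- seq(cfg@fStart, cfg@fEnd, length.out = n)
    walk <- cumsum(stats::rnorm(n, 0, cfg@fWalkSd))
    abs(ramp + walk)
  })
}

# Logistic selectivity-at-length.
.logisticSel <- function(len, l50, slope) 1 / (1 + exp(-slope * (len - l50)))

#' Simulate a size-structured stock
#'
#' Seeded age-structured simulator producing a \linkS4class{StockSeries}
#' with the mechanisms the partitioning analysis assumes:
#' \itemize{
#'   \item cohort dynamics
#'     \eqn{N_{a+1,t+1} = N_{a,t} \exp(-(M + s(\bar L_a) F_t))} with
#'     logistic size selectivity \eqn{s} evaluated at the von Bertalanffy
#'     mean length at age \eqn{\bar L_a = L_\infty (1 - e^{-K (a - a_0)})},
#'     so rising \eqn{F} truncates the size structure;
#'   \item temperature-forced lognormal recruitment
#'     \eqn{N_{0,t} = R_0 \exp(\beta_T (T_{t-\ell} - \bar T) - \sigma_R^2/2
#'     + \eta_t)}, \eqn{\eta_t \sim N(0, \sigma_R^2)}, with the
#'     \eqn{-\sigma_R^2/2} correction keeping mean recruitment stationary
#'     when \eqn{\beta_T = 0};
#'   \item a survey observation model: each year's length distribution is
#'     the normal mixture over ages (\code{sd = cvLength * meanLength})
#'     weighted by survey-vulnerable abundance, discretised into bins of
#'     \code{binWidth} cm and sampled multinomially with \code{nSample}
#'     individuals (rows of the composition sum to \code{nSample} exactly).
#' }
#' The survey selectivity defaults to the fishery's
#' (\code{surveyL50 = NA}); set it separately to make young fish visible to
#' the survey, e.g. for lag-recovery experiments.
#' The population starts at the deterministic equilibrium age structure
#' under \eqn{F_1}.  The forcing series carries the true \eqn{F_t} and
#' \eqn{T_t}; the metadata carries the true traits
#' (\eqn{L_{50} = \bar L(A_{50})}, \eqn{A_{50}} set to the age at which
#' fishery selection reaches 50\%).
#'
#' @param cfg A \linkS4class{SimConfig}.
#' @param stockId Identifier for the simulated stock.
#' @return A validated \linkS4class{StockSeries}.
#' @examples
#' st <- simulateStock(SimConfig(nYears = 12L, seed = 42L))
#' st
#' @export
simulateStock <- function(cfg, stockId = sprintf("sim%04d", cfg@seed)) {
  validObject(cfg)
  nY <- cfg@nYears
  ages <- 0:cfg@Amax
  lenAtAge <- cfg@Linf * (1 - exp(-cfg@K * (ages - cfg@a0)))
  lenAtAge <- pmax(lenAtAge, 0.1)
  selF <- .logisticSel(lenAtAge, cfg@selL50, cfg@selSlope)
  selSurv <- if (is.na(cfg@surveyL50)) selF
             else .logisticSel(lenAtAge, cfg@surveyL50,
                               if (is.na(cfg@surveySlope)) cfg@selSlope
                               else cfg@surveySlope)

  nburn <- cfg@recLag
  Tall <- simulateTemperature(cfg, n = nY + nburn, seed = cfg@seed)
  Fser <- simulateFishing(cfg, n = nY)

  withSeed(cfg@seed + 2000003L, {
    eta <- stats::rnorm(nY, 0, cfg@sigmaR)
    # recruits in year t respond to the temperature anomaly recLag years
    # earlier; the burn-in years of Tall supply the pre-series anomalies
    recDev <- cfg@betaT * (Tall[seq_len(nY) + nburn - cfg@recLag] -
                             cfg@tempMean) - cfg@sigmaR^2 / 2 + eta
    R <- cfg@R0 * exp(recDev)

    N <- matrix(0, length(ages), nY)
    Z1 <- cfg@M + selF * Fser[1]
    N[, 1] <- cfg@R0 * exp(-cumsum(c(0, Z1[-length(Z1)])))
    N[1, 1] <- R[1]
    for (t in seq_len(nY - 1)) {
      Zt <- cfg@M + selF * Fser[t]
      N[-1, t + 1] <- N[-length(ages), t] * exp(-Zt[-length(ages)])
      N[1, t + 1] <- R[t + 1]
    }
    if (any(colSums(N) < 1e-06 * cfg@R0))
      stop("population collapse: total abundance fell below the floor")

    maxLen <- ceiling(cfg@Linf * (1 + 4 * cfg@cvLength) / cfg@binWidth) *
      cfg@binWidth
    edges <- seq(0, maxLen, by = cfg@binWidth)
    nb <- length(edges) - 1L
    # per-age bin probabilities of the length distribution
    binP <- matrix(0, length(ages), nb)
    for (a in seq_along(ages)) {
      cdf <- stats::pnorm(edges, lenAtAge[a], cfg@cvLength * lenAtAge[a])
      binP[a, ] <- diff(cdf) / (cdf[length(cdf)] - cdf[1])
    }
    cts <- matrix(0, nY, nb)
    for (t in seq_len(nY)) {
      w <- N[, t] * selSurv
      probs <- colSums(binP * w) / sum(w)
      cts[t, ] <- stats::rmultinom(1, cfg@nSample, probs)
    }
  })

  yrs <- seq_len(nY) + 2000L - 1L
  keep <- colSums(cts) > 0  # trim never-occupied tail bins
  firstKeep <- which(keep)[1]
  lastKeep <- max(which(keep))
  sel <- firstKeep:lastKeep
  lc <- LengthComposition(yrs, edges[c(sel, lastKeep + 1L)],
                          cts[, sel, drop = FALSE])
  fs <- ForcingSeries(yrs, F = Fser,
                      temperature = Tall[nburn + seq_len(nY)])
  # age at which mean length reaches L50 (inverse von Bertalanffy)
  A50 <- max(1, round(cfg@a0 - log(1 - min(cfg@selL50, 0.95 * cfg@Linf) /
                                     cfg@Linf) / cfg@K))
  meta <- StockMeta(stockId = stockId, region = "other",
                    habitat = "demersal", samplingInterval = 1L,
                    M = cfg@M, K = cfg@K, Linf = cfg@Linf, A50 = A50,
                    L50 = min(cfg@selL50, 0.95 * cfg@Linf))
  StockSeries(meta, lc, fs)
}

#' Simulate a batch of stocks and write them to disk
#'
#' Generates \code{n} stocks with seeds \code{cfg@seed + 0:(n-1)}, writes
#' each in the package's CSV/YAML exchange format via [writeStockSeries()],
#' plus a \code{manifest.csv} listing the stock ids and file paths.
#'
#' @param cfg Base \linkS4class{SimConfig}; only the seed varies across
#'   stocks.
#' @param n Number of stocks.
#' @param dir Output directory.
#' @return Invisibly, the manifest data frame.
#' @export
simulateStockBatch <- function(cfg, n, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cfg@seed <- cfg@seed + (i > 1)  # consecutive seeds
    st <- simulateStock(cfg)
    paths <- writeStockSeries(st, dir)
    rows[[i]] <- data.frame(stock = stockId(st),
                            composition = paths$composition,
                            meta = paths$meta, forcing = paths$forcing)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
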