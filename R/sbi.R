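#' Univariate size-based indicators per year
#'
#' Computes, for every year of a length composition, the five classical
#' size-based indicators from the per-year bin proportions \eqn{p_i} and
#' bin midpoints \eqn{m_i}:
#' \itemize{
#'   \item \code{L95}: weighted 95th percentile of length, linearly
#'     interpolated within the bin where the cumulative proportion crosses
#'     0.95 (\eqn{L_{95} = lower + (0.95 - cum_{below}) / p_{bin} \times
#'     width});
#'   \item \code{meanLength}: \eqn{\sum p_i m_i};
#'   \item \code{shannonH}: \eqn{-\sum_{p_i > 0} p_i \ln p_i} (nats);
#'   \item \code{pielouJ}: \eqn{H / \ln S} with \eqn{S} the number of bins
#'     occupied at the stock level (constant across years, so evenness is
#'     comparable between years); \code{NA} when \eqn{S = 1};
#'   \item \code{skewness}: population-moment form
#'     \eqn{\sum p_i (m_i - \bar m)^3 / (\sum p_i (m_i - \bar m)^2)^{3/2}};
#'     \code{NA} (with a warning) for a zero-spread year.
#' }
#'
#' @param comp A \linkS4class{LengthComposition}.
#' @return A data frame with columns \code{year}, \code{L95},
#'   \code{meanLength}, \code{shannonH}, \code{pielouJ}, \code{skewness}.
#' @examples
#' lc <- LengthComposition(2001, c(10, 20, 30, 40),
#'                         matrix(c(50, 30, 20), 1))
#' computeSBITable(lc)  # meanLength 22, L95 37.5
#' @export
computeSBITable <- function(comp) {
  P <- toProportions(comp)@counts
  e <- binEdges(comp)
  mids <- (e[-1] + e[-length(e)]) / 2
  lowers <- e[-length(e)]
  widths <- diff(e)
  S <- sum(colSums(counts(comp)) > 0)

  out <- data.frame(year = years(comp), L95 = NA_real_,
                    meanLength = NA_real_, shannonH = NA_real_,
                    pielouJ = NA_real_, skewness = NA_real_)
  degenerate <- FALSE
  for (i in seq_len(nrow(P))) {
    p <- P[i, ]
    mu <- sum(p * mids)
    v <- sum(p * (mids - mu)^2)
    out$meanLength[i] <- mu
    pp <- p[p > 0]
    H <- -sum(pp * log(pp))
    out$shannonH[i] <- H
    out$pielouJ[i] <- if (S > 1) H / log(S) else NA_real_
    if (v > 0) {
      out$skewness[i] <- sum(p * (mids - mu)^3) / v^1.5
    } else degenerate <- TRUE
    cum <- cumsum(p)
    j <- which(cum >= 0.95)[1]
    below <- if (j > 1) cum[j - 1] else 0
    out$L95[i] <- lowers[j] + (0.95 - below) / p[j] * widths[j]
  }
  if (degenerate)
    warning("skewness undefined for year(s) with all mass in one bin; NA returned")
  out
}

#' Regress one size-based indicator on fishing and temperature
#'
#' Ordinary least squares of an annual indicator on temperature, fishing
#' and their product.  Both predictors are z-scored before the product term
#' is formed, so the interaction is not dominated by measurement scale
#' (marginal p-values are unaffected by this choice; the product-term fit
#' is not scale-free, and the standardised form is the documented
#' convention).  Years with a missing indicator (e.g. undefined skewness)
#' are dropped.
#'
#' A constant indicator carries no information: the slopes are reported as
#' 0 with p = 1 (documented degenerate-response rule).
#'
#' @param sbi Numeric vector of annual indicator values.
#' @param xFish,xTemp Aligned forcing vectors.
#' @param sbiName Label carried into the result.
#' @return A data frame with columns \code{sbi}, \code{term},
#'   \code{estimate}, \code{p}; terms are \code{(Intercept)},
#'   \code{temperature}, \code{fishing}, \code{temperature:fishing}.
#' @export
sbiRegression <- function(sbi, xFish, xTemp, sbiName = "sbi") {
  n0 <- length(sbi)
  stopifnot(length(xFish) == n0, length(xTemp) == n0)
  ok <- !is.na(sbi)
  sbi <- sbi[ok]
  n <- length(sbi)
  if (n < 8) stop("need at least 8 non-missing years")
  zF <- as.numeric(scale(xFish[ok]))
  zT <- as.numeric(scale(xTemp[ok]))
  if (anyNA(zF) || anyNA(zT))
    stop("collinear or constant predictor in SBI regression")
  terms <- c("(Intercept)", "temperature", "fishing",
             "temperature:fishing")
  if (stats::sd(sbi) == 0) {
    return(data.frame(sbi = sbiName, term = terms,
                      estimate = c(mean(sbi), 0, 0, 0),
                      p = c(NA_real_, 1, 1, 1)))
  }
  fit <- stats::lm(sbi ~ zT + zF + zT:zF)
  cf <- summary(fit)$coefficients
  data.frame(sbi = sbiName, term = terms, estimate = unname(cf[, 1]),
             p = unname(cf[, 4]))
}

#' All five SBI regressions for one aligned stock
#'
#' Convenience wrapper running [sbiRegression()] for each indicator column
#' of a [computeSBITable()] result restricted to the aligned years.
#'
#' @param sbiTable Data frame from [computeSBITable()].
#' @param years Aligned years (subset of \code{sbiTable$year}).
#' @param xFish,xTemp Forcing vectors aligned to \code{years}.
#' @return Row-bound regression results for \code{L95}, \code{meanLength},
#'   \code{shannonH}, \code{pielouJ}, \code{skewness}.
#' @export
sbiRegressionTable <- function(sbiTable, years, xFish, xTemp) {
  idx <- match(years, sbiTable$year)
  if (anyNA(idx)) stop("aligned years missing from the SBI table")
  cols <- c("L95", "meanLength", "shannonH", "pielouJ", "skewness")
  do.call(rbind, lapply(cols, function(cl)
    sbiRegression(sbiTable[[cl]][idx], xFish, xTemp, sbiName = cl)))
}
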