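#' Redundancy analysis R-squared (optionally partial)
#'
#' Fits a (partial) redundancy analysis by linear projection: the response
#' matrix \code{Y} and predictors \code{X} are column-centred; with a
#' conditioning set \code{W}, both are first residualised on \code{W}
#' (partial RDA).  The explained fraction is the Frobenius sum of squares of
#' the projection of (residualised) \code{Y} onto the column space of
#' (residualised) \code{X}, divided by the \emph{total} centred sum of
#' squares of \code{Y} — so partial fractions are on the same scale as the
#' total variance.  The pseudo-F statistic is
#' \deqn{F = (SS_{exp} / p) / (SS_{res} / (n - p - q - 1)),}
#' where \eqn{SS_{res}} is what remains of \code{Y} after removing both
#' \code{W} and \code{X}.
#'
#' Aliased predictors (zero variance, or linearly dependent on other
#' predictors or on \code{W}) are handled as constrained ordination software
#' conventionally does: the effective predictor count \code{p} is the rank
#' of the centred, residualised \code{X}, so a duplicated forcing vector
#' collapses to a single constraint instead of failing.  A fully degenerate
#' \code{X} (rank 0, e.g. a constant forcing) explains nothing: \code{r2 =
#' 0} with \code{pseudoF = NA}.
#'
#' @param Y Numeric response matrix (rows = years, columns = length bins).
#' @param X Numeric predictor matrix or vector.
#' @param W Optional conditioning matrix or vector (\code{NULL} for plain
#'   RDA).
#' @return An \linkS4class{RDAFit}.
#' @examples
#' x <- 1:10
#' Y <- cbind(2 * x, -x) + 0   # exactly linear in x
#' rdaR2(Y, x)                 # R2 = 1
#' @export
rdaR2 <- function(Y, X, W = NULL) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  n <- nrow(Y)
  q <- if (is.null(W)) 0L else qr(centerCols(as.matrix(W)))$rank
  if (nrow(X) != n) stop("Y and X must have the same number of rows")

  Yc <- centerCols(Y)
  ssTot <- sum(Yc^2)
  if (ssTot <= 0) stop("Y has zero variance after centering")
  Xc <- centerCols(X)

  if (!is.null(W)) {
    W <- as.matrix(W)
    if (nrow(W) != n) stop("W must have the same number of rows as Y")
    qrW <- qr(centerCols(W))
    Yc <- qr.resid(qrW, Yc)
    Xc <- qr.resid(qrW, Xc)
  }
  qrX <- qr(Xc)
  p <- qrX$rank
  if (n <= p + q + 1) stop("need n > p + q + 1 rows")
  if (p == 0L)
    return(new("RDAFit", r2 = 0, adjR2 = adjustR2(0, n, q), n = as.integer(n),
               p = 0L, q = as.integer(q), pseudoF = NA_real_))
  ssExp <- sum(qr.fitted(qrX, Yc)^2)
  ssRes <- sum(Yc^2) - ssExp
  df2 <- n - p - q - 1L
  new("RDAFit", r2 = ssExp / ssTot,
      adjR2 = adjustR2(ssExp / ssTot, n, p + q),
      n = as.integer(n), p = as.integer(p), q = as.integer(q),
      pseudoF = (ssExp / p) / (ssRes / df2))
}

#' Ezekiel-adjusted R-squared
#'
#' \deqn{R^2_{adj} = 1 - (1 - R^2) (n - 1) / (n - p - 1).}
#' Unbiased under random predictors; can be negative.
#'
#' @param r2 Unadjusted fraction of variance explained.
#' @param n Number of rows.
#' @param p Number of predictors.
#' @return Adjusted R-squared.
#' @examples
#' adjustR2(0, 10, 1)    # -0.125
#' adjustR2(5/9, 4, 1)   # 1/3
#' @export
adjustR2 <- function(r2, n, p) {
  if (n - p - 1 < 1) stop("insufficient degrees of freedom: need n - p - 1 >= 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}
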