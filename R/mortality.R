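#' Exploitation rate from instantaneous mortalities (type II fishery)
#'
#' In a type II fishery, fishing and natural mortality operate concurrently
#' through the year.  With total mortality \eqn{Z = F + M} and actual
#' (annual) total mortality \eqn{A = 1 - e^{-Z}}, the exploitation rate is
#' \deqn{\mu = F \cdot A / Z = F (1 - e^{-(F+M)}) / (F + M),}
#' the fraction of the population removed by fishing in one year.  It is
#' strictly increasing in \eqn{F}, 0 at \eqn{F = 0} and approaches 1 as
#' \eqn{F \to \infty}.
#'
#' @param F Instantaneous fishing mortality (1/yr), vectorised, \eqn{\ge 0}.
#' @param M Instantaneous natural mortality (1/yr), \eqn{> 0}.
#' @return Exploitation rate(s) in \eqn{[0, 1)}.
#' @examples
#' muFromF(0.4, 0.2)  # 0.4 * (1 - exp(-0.6)) / 0.6
#' @seealso [exploitationToF()] for the numerical inverse.
#' @export
muFromF <- function(F, M) {
  if (any(F < 0)) stop("F must be >= 0")
  if (any(M <= 0)) stop("M must be > 0")
  Z <- F + M
  F * (1 - exp(-Z)) / Z
}

#' Fishing mortality from exploitation rate (numerical inversion)
#'
#' Solves \eqn{\mu = F (1 - e^{-(F+M)}) / (F + M)} for \eqn{F \ge 0} given
#' the annual exploitation rate and natural mortality, by bracketing (upper
#' bound doubled until it brackets the root) and Brent's method
#' ([stats::uniroot()]).
#'
#' @param mu Exploitation rate(s) in \eqn{[0, 1)}, vectorised.
#' @param M Natural mortality (1/yr), \eqn{> 0}.
#' @param tol Tolerance on \eqn{\mu} (default \code{1e-10}).
#' @return Fishing mortality (1/yr).
#' @examples
#' exploitationToF(muFromF(0.4, 0.2), 0.2)  # recovers 0.4
#' @export
exploitationToF <- function(mu, M, tol = 1e-10) {
  if (any(mu < 0)) stop("mu must be >= 0")
  if (any(mu >= 1)) stop("mu must be < 1: exploitation cannot remove the whole population")
  if (any(M <= 0)) stop("M must be > 0")
  vapply(mu, function(m) {
    if (m == 0) return(0)
    hi <- 1
    while (muFromF(hi, M) < m) hi <- hi * 2
    stats::uniroot(function(f) muFromF(f, M) - m, c(0, hi),
                   tol = tol)$root
  }, numeric(1))
}

#' Mortality-ratio series F/M
#'
#' Fishing mortality normalised by natural mortality, the cross-stock
#' comparable measure of fishing pressure.
#'
#' @param F Vector of annual fishing mortalities (1/yr).
#' @param M Natural mortality (1/yr), \eqn{> 0}.
#' @return Elementwise \code{F / M}.
#' @export
mortalityRatioSeries <- function(F, M) {
  if (any(M <= 0)) stop("M must be > 0")
  F / M
}

#' Long-term mean and variability of a forcing series
#'
#' @param series Numeric vector, length \eqn{\ge 2}.
#' @return Named list with \code{mean} (arithmetic) and \code{cv} (sample
#'   standard deviation, \eqn{n - 1} denominator, over the mean).  Errors
#'   when the mean is zero (CV undefined).
#' @examples
#' longTermIndices(c(1, 3))  # mean 2, cv sqrt(2)/2
#' @export
longTermIndices <- function(series) {
  if (length(series) < 2L) stop("need at least 2 values")
  list(mean = mean(series), cv = sampleCV(series))
}
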