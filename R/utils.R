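# Internal helpers.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so seeded operations do not perturb the
# session RNG stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Column-centre a matrix.
centerCols <- function(x) sweep(x, 2L, colMeans(x))

# Sample CV (n-1 sd over mean); errors on zero mean per the module contract.
sampleCV <- function(x) {
  m <- mean(x)
  if (m == 0) stop("CV undefined: series mean is zero")
  stats::sd(x) / m
}
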