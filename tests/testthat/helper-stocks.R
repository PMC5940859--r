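# Shared fixture builders (all generated in code; nothing on disk).

# Tiny composition: counts matrix with given years and unit-width bins
# starting at `origin`.
makeComp <- function(counts, years = seq_len(nrow(counts)) + 1999L,
                     origin = 10, width = 10) {
  counts <- as.matrix(counts)
  edges <- origin + width * (0:ncol(counts))
  LengthComposition(years, edges, counts)
}

# A StockSeries with fully controlled composition and forcing vectors.
makeStock <- function(counts, F, temperature,
                      years = seq_len(nrow(counts)) + 1999L,
                      forcingYears = years, M = 0.2) {
  comp <- makeComp(counts, years = years)
  fs <- ForcingSeries(forcingYears, F = F, temperature = temperature)
  meta <- StockMeta("test", M = M, K = 0.2, Linf = 80, A50 = 4, L50 = 40)
  StockSeries(meta, comp, fs)
}

# Brute-force RDA oracle for a single predictor: per-response-column simple
# regression explained SS over total centred SS.
olsR2Oracle <- function(Y, x) {
  Y <- as.matrix(Y)
  ssExp <- 0; ssTot <- 0
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    fit <- lm(y ~ x)
    ssExp <- ssExp + sum((fitted(fit) - mean(y))^2)
    ssTot <- ssTot + sum((y - mean(y))^2)
  }
  ssExp / ssTot
}
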