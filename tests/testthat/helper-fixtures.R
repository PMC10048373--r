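## Shared fixtures and independent oracles, built in code at test time.

## constant-depth track: depths is a named list chrom -> single value,
## lengths the matching chromosome lengths in bp
constantDepth <- function(depths, lengths) {
  out <- lapply(names(depths), function(chrom)
    S4Vectors::Rle(depths[[chrom]], lengths[[chrom]]))
  names(out) <- names(depths)
  IRanges::RleList(out, compress = FALSE)
}

## brute-force window counter: SNP positions falling in [starts, ends]
bruteWindowCounts <- function(pos, starts, ends) {
  vapply(seq_along(starts),
         function(i) sum(pos >= starts[i] & pos <= ends[i]), 0L)
}

## record-by-record filter oracle: the quality expression with strict
## comparisons followed by the inclusive depth band, one if() per record
filterOracle <- function(qual, dp, gq, sp, meanCov,
                         minQual = 20, maxSp = 60, minDp = 5, minGq = 20,
                         band = c(0.30, 2.50)) {
  keep <- logical(length(qual))
  for (i in seq_along(qual)) {
    removed <- qual[i] < minQual ||
      (sp[i] > maxSp || dp[i] < minDp || gq[i] < minGq)
    inBand <- dp[i] >= band[1] * meanCov && dp[i] <= band[2] * meanCov
    keep[i] <- !removed && inBand
  }
  keep
}

## definitional N50/L50: sort descending, cumulative sum, first crossing
bruteN50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(s)
  i <- which(cum >= sum(s) / 2)[1]
  list(n50 = s[i], l50 = i)
}

## a male test genome small enough for per-base simulation in tests
maleGenome <- function(parLength = 6e5, xLength = 2e6)
  makeGenome(2, c(3e6, 2e6), xLength = xLength, parLength = parLength,
             sex = "male")

femaleGenome <- function(xLength = 2e6)
  makeGenome(2, c(3e6, 2e6), xLength = xLength, parLength = 0,
             sex = "female")
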