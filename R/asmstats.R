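#' Assembly contiguity statistics (N50/L50)
#'
#' N50 follows the usual "cumulative at least half the total" convention:
#' sort lengths in decreasing order, take the first length at which the
#' cumulative sum reaches half the total assembly length.  L50 is the
#' number of scaffolds needed to get there.
#'
#' @param lengths numeric, scaffold lengths in bp (positive, non-empty).
#' @return A \code{\link{ScaffoldStats}}.
#' @examples
#' scaffoldStats(c(10, 5, 5))  # N50 = 10, L50 = 1
#' @export
scaffoldStats <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length list")
  if (any(lengths <= 0)) stop("scaffold lengths must be positive")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(s)
  l50 <- which(cum >= sum(s) / 2)[1L]
  new("ScaffoldStats", nScaffolds = length(s), totalLength = sum(s),
      n50 = s[l50], l50 = as.integer(l50), lengths = s)
}

#' Detect the chromosome-scale scaffold cutoff
#'
#' Chromosome-length assemblies typically show a dramatic drop in
#' scaffold length between the last chromosome-scale scaffold and the
#' first debris scaffold.  Among ranks 1..min(searchTop, n-1) of the
#' descending-sorted lengths, the cutoff is the rank k maximizing
#' L[k] / L[k+1]; ties break to the smallest k.  The fold gap is also
#' rounded to the nearest integer for display, and the cutoff is flagged
#' chromosome-scale when the gap reaches \code{flagThreshold}.
#'
#' @param lengths numeric, scaffold lengths in bp (at least 2).
#' @param searchTop integer(1), deepest rank searched (default 64).
#' @param flagThreshold numeric(1), fold gap regarded as chromosome-scale
#'   evidence (default 10).
#' @return A \code{\link{CScaffoldCutoff}}.
#' @examples
#' cScaffoldCutoff(c(100e6, 90e6, 57.63e6, 1.99e6, 1e6))  # k = 3, ~29x
#' @export
cScaffoldCutoff <- function(lengths, searchTop = 64L, flagThreshold = 10) {
  if (length(lengths) < 2L) stop("need at least 2 scaffolds")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  kmax <- min(as.integer(searchTop), length(s) - 1L)
  ratio <- s[seq_len(kmax)] / s[seq_len(kmax) + 1L]
  k <- which.max(ratio)                       # first maximum on ties
  new("CScaffoldCutoff", k = as.integer(k), foldGap = ratio[k],
      foldGapRounded = round(ratio[k]),
      isChromosomeScale = ratio[k] >= flagThreshold,
      flagThreshold = flagThreshold)
}

## half-up rounding to one decimal (round() is banker's rounding)
.halfUp1 <- function(x) floor(x * 10 + 0.5) / 10

#' Convert BUSCO category counts to percentages
#'
#' Converts (complete single-copy, complete duplicated, fragmented,
#' missing) ortholog counts into percentages of the database total,
#' rounded half-up to one decimal.  When the published percentages are
#' supplied for comparison, disagreements are flagged rather than
#' silently matched -- published tables occasionally round differently.
#'
#' @param counts numeric(4): single, duplicated, fragmented, missing.
#'   The four categories must sum to \code{total}.
#' @param total integer(1), orthologs in the database (e.g. 9226 for
#'   mammalia_odb10).
#' @param printed optional numeric(4) of published percentages to check
#'   against.
#' @return Named numeric(4) of percentages (\code{single},
#'   \code{duplicated}, \code{fragmented}, \code{missing}); when
#'   \code{printed} is given, an attribute \code{mismatch} (logical(4))
#'   marks entries whose computed value differs from the printed one.
#' @examples
#' buscoPercent(c(7981, 140, 444, 661), 9226)
#' @export
buscoPercent <- function(counts, total, printed = NULL) {
  if (length(counts) != 4L) stop("counts must have 4 entries")
  if (any(counts < 0)) stop("counts must be >= 0")
  if (sum(counts) != total)
    stop("the four category counts must sum to the database total")
  pct <- setNames(.halfUp1(100 * counts / total),
                  c("single", "duplicated", "fragmented", "missing"))
  if (!is.null(printed)) {
    mism <- abs(pct - printed) > 1e-9
    attr(pct, "mismatch") <- setNames(mism, names(pct))
    if (any(mism))
      message("computed percentage differs from printed value for: ",
              paste(names(pct)[mism], collapse = ", "))
  }
  pct
}

#' Estimate genome size from a k-mer multiplicity histogram
#'
#' Standard spectral estimator: let t be the trough (the first strict
#' local minimum of the spectrum after multiplicity 1, separating the
#' error component from the coverage component) or \code{minMult} when
#' given; let m be the multiplicity with the highest count at or beyond
#' t (the coverage peak).  The genome size estimate is
#' \deqn{G = \sum_{i \ge t} i \, c_i / m,}
#' the k-mer mass above the trough divided by the per-copy coverage.
#' Error mass below the trough does not enter the estimate.
#'
#' @param hist data.frame with columns \code{multiplicity} and
#'   \code{count} (as from \code{\link{simulateKmerHistogram}} or
#'   \code{\link{readKmerHistogram}}).
#' @param minMult optional integer(1): skip trough detection and start
#'   the coverage component here.  Required for spectra with no strict
#'   local minimum (e.g. error-free simulations).
#' @return numeric(1), the genome size estimate in bp, with attributes
#'   \code{peak} (m), \code{trough} (t) and \code{mass}
#'   (\eqn{\sum_{i\ge t} i c_i}).
#' @examples
#' h <- simulateKmerHistogram(1e6, simulationConfig(meanDepth = 20,
#'                                                  seed = 9))
#' genomeSizeFromKmers(h, minMult = 3)
#' @export
genomeSizeFromKmers <- function(hist, minMult = NULL) {
  stopifnot(all(c("multiplicity", "count") %in% names(hist)))
  if (any(hist$multiplicity < 1) || any(hist$multiplicity %% 1 != 0))
    stop("multiplicities must be positive integers")
  if (any(hist$count < 0)) stop("counts must be >= 0")
  ## dense count vector indexed by multiplicity
  cnt <- numeric(max(hist$multiplicity))
  cnt[hist$multiplicity] <- hist$count
  if (is.null(minMult)) {
    t <- NA_integer_
    for (i in 2:(length(cnt) - 1L)) {
      if (cnt[i] < cnt[i - 1L] && cnt[i] < cnt[i + 1L]) { t <- i; break }
    }
    if (is.na(t))
      stop("no strict local minimum found between the error and ",
           "coverage components; supply minMult explicitly")
  } else t <- as.integer(minMult)
  if (t > length(cnt)) stop("minMult beyond the histogram range")
  idx <- t:length(cnt)
  m <- idx[which.max(cnt[idx])]
  mass <- sum(idx * cnt[idx])
  G <- mass / m
  attr(G, "peak") <- m
  attr(G, "trough") <- t
  attr(G, "mass") <- mass
  G
}
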