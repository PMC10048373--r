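#' Simulate a synteny block set with planted inversions
#'
#' Tiles every reference chromosome with alignment blocks of jittered
#' length (uniform in 0.5-1.5 times \code{meanBlockLen}), producing a
#' query assembly whose scaffolds are renamed (optionally permuted) copies
#' of the reference chromosomes.  Blocks falling inside a planted
#' inversion carry the opposite orientation, and their query coordinates
#' are reflected within the inverted interval (kept ascending, with
#' orientation carrying the strand sense, as in PSL).  An inversion
#' spanning a whole chromosome yields a fully reverse-oriented scaffold.
#'
#' @param ref a \code{\link{GenomeModel}} describing the reference.
#' @param plantedInversions \code{GRanges} on reference chromosomes (may
#'   be empty); intervals must be disjoint and within bounds.
#' @param scaffoldPermutation named character: reference chromosome ->
#'   query scaffold name.  Defaults to the identity (same names).
#' @param meanBlockLen numeric(1), mean block length in bp.
#' @param seed integer(1).
#' @param orientationNoise numeric(1) in [0, 1): probability that a
#'   block's orientation is flipped at random (alignment noise); default
#'   0.
#' @return A \code{\link{SyntenyBlockSet}}.
#' @examples
#' g <- makeGenome(2, c(2e6, 1e6), sex = "female")
#' inv <- GenomicRanges::GRanges("aut1", IRanges::IRanges(5e5, 9e5))
#' sb <- simulateSynteny(g, inv, meanBlockLen = 1e5, seed = 3)
#' table(blocks(sb)$orientation)
#' @export
simulateSynteny <- function(ref, plantedInversions = GRanges(),
                            scaffoldPermutation = NULL,
                            meanBlockLen = 100000, seed = 1L,
                            orientationNoise = 0) {
  stopifnot(is(ref, "GenomeModel"), is(plantedInversions, "GRanges"))
  validObject(ref)
  if (orientationNoise < 0 || orientationNoise >= 1)
    stop("orientationNoise must be in [0, 1)")
  refLen <- setNames(ref@chromLengths, ref@chromNames)
  if (length(plantedInversions)) {
    if (!IRanges::isDisjoint(plantedInversions))
      stop("planted inversions must not overlap")
    pin <- as.character(seqnames(plantedInversions))
    if (!all(pin %in% names(refLen)))
      stop("planted inversion on unknown chromosome")
    if (any(end(plantedInversions) > refLen[pin]) ||
        any(start(plantedInversions) < 1))
      stop("planted inversion outside chromosome bounds")
  }
  if (is.null(scaffoldPermutation))
    scaffoldPermutation <- setNames(names(refLen), names(refLen))
  if (!all(names(refLen) %in% names(scaffoldPermutation)))
    stop("scaffoldPermutation must cover every reference chromosome")
  queryLen <- setNames(refLen, scaffoldPermutation[names(refLen)])

  .withSeed(seed, {
    rows <- lapply(names(refLen), function(chrom) {
      len <- refLen[[chrom]]
      starts <- integer(); ends <- integer()
      pos <- 1
      while (pos <= len) {
        bl <- max(1, round(runif(1, 0.5, 1.5) * meanBlockLen))
        e <- min(pos + bl - 1, len)
        starts <- c(starts, pos); ends <- c(ends, e)
        pos <- e + 1
      }
      n <- length(starts)
      orient <- rep("+", n)
      qs <- starts; qe <- ends
      if (length(plantedInversions)) {
        pin <- plantedInversions[seqnames(plantedInversions) == chrom]
        for (j in seq_along(pin)) {
          s <- start(pin)[j]; e <- end(pin)[j]
          mid <- (starts + ends) / 2
          inside <- mid >= s & mid <= e
          orient[inside] <- "-"
          ## reflect query coordinates within the inverted interval
          qs[inside] <- s + e - pmin(ends[inside], e)
          qe[inside] <- s + e - pmax(starts[inside], s)
        }
      }
      if (orientationNoise > 0) {
        flip <- runif(n) < orientationNoise
        orient[flip] <- ifelse(orient[flip] == "+", "-", "+")
      }
      data.frame(refChrom = chrom, refStart = starts, refEnd = ends,
                 queryChrom = unname(scaffoldPermutation[chrom]),
                 queryStart = qs, queryEnd = qe, orientation = orient,
                 stringsAsFactors = FALSE)
    })
    b <- do.call(rbind, rows)
    b <- b[order(b$refChrom, b$refStart), , drop = FALSE]
    rownames(b) <- NULL
    new("SyntenyBlockSet", blocks = b, refLengths = refLen,
        queryLengths = queryLen)
  })
}
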