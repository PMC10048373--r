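#' Simulate a k-mer multiplicity histogram
#'
#' Generates the spectrum a k-mer counter would report for shotgun reads
#' of a genome of \code{genomeSize} distinct k-mers sequenced at
#' \code{meanDepth}: a coverage component (one multiplicity per genomic
#' k-mer, a discretised normal centred at \code{meanDepth} with Poisson-
#' scale width \code{sqrt(meanDepth * depthDispersion)}, floored at 1) and
#' an error component concentrated at multiplicities 1-2.  The error mass
#' is set so that \code{errorRate} of all k-mer observations are
#' erroneous; the non-error mass \code{sum(i * count[i])} over the
#' coverage component is approximately \code{genomeSize * meanDepth}.
#'
#' @param genomeSize numeric(1), number of distinct genomic k-mers
#'   (approximately the genome size in bp for large k).
#' @param config a \code{\link{SimulationConfig}}; uses \code{meanDepth},
#'   \code{depthDispersion}, \code{errorRate}, \code{seed}.
#' @return A data.frame with columns \code{multiplicity} (1, 2, ...) and
#'   \code{count}, jellyfish-histo compatible; write with
#'   \code{\link{writeKmerHistogram}}.
#' @examples
#' h <- simulateKmerHistogram(1e6, simulationConfig(meanDepth = 20,
#'                                                  seed = 4))
#' sum(h$multiplicity * h$count) / 1e6  # ~ 20
#' @export
simulateKmerHistogram <- function(genomeSize, config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (genomeSize <= 0) stop("genomeSize must be positive")
  mu <- config@meanDepth
  sdv <- sqrt(mu * config@depthDispersion)
  .withSeed(config@seed, {
    mult <- pmax(1L, as.integer(round(rnorm(genomeSize, mu, sdv))))
    counts <- tabulate(mult)
    if (config@errorRate > 0) {
      genomicMass <- sum(mult)
      errMass <- config@errorRate / (1 - config@errorRate) * genomicMass
      ## error k-mers: multiplicity 1 (80%) or 2 (20%), mean mass 1.2
      nErr <- round(errMass / 1.2)
      em <- sample(c(1L, 2L), nErr, replace = TRUE, prob = c(0.8, 0.2))
      counts[1L] <- counts[1L] + sum(em == 1L)
      counts[2L] <- counts[2L] + sum(em == 2L)
    }
    data.frame(multiplicity = seq_along(counts), count = counts)
  })
}
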