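#' Simulate heterozygous SNP calls with quality annotations
#'
#' Plants heterozygous SNPs uniformly along each chromosome at the
#' configured per-region density (SNPs/kbp).  On a male X, only the PAR
#' emits heterozygous calls: the hemizygous remainder produces none, by
#' construction.  Each record carries the annotation fields consumed by
#' \code{\link{filterVariants}}: site quality \code{qual} (gamma, mean
#' 120), sample depth \code{dp} (drawn from the configured depth model),
#' genotype quality \code{gq} (gamma, capped at 99), and strand-bias
#' Phred score \code{sp} (half-normal, sd 15 -- only its > 60 tail matters
#' to the filter).
#'
#' @param genome a \code{\link{GenomeModel}}.
#' @param config a \code{\link{SimulationConfig}}; \code{hetDensity} gives
#'   the per-chromosome planted densities.
#' @return A sorted \code{GRanges} of width-1 SNPs with metadata columns
#'   \code{ref}, \code{alt}, \code{qual}, \code{dp}, \code{gq}, \code{sp},
#'   \code{gt} (one of \code{"hom-ref"}, \code{"het"}, \code{"hom-alt"},
#'   \code{"missing"}) and \code{isSnp}.  Serializable with
#'   \code{\link{writeVariantsVcf}}.
#' @examples
#' g <- makeGenome(1, 1e6, sex = "female")
#' v <- simulateVariants(g, simulationConfig(hetDensity = 0.5, seed = 2))
#' length(v)  # ~ Poisson(500)
#' @export
simulateVariants <- function(genome, config) {
  stopifnot(is(genome, "GenomeModel"), is(config, "SimulationConfig"))
  validObject(genome); validObject(config)
  bases <- c("A", "C", "G", "T")
  si <- Seqinfo(genome@chromNames, genome@chromLengths)
  .withSeed(config@seed, {
    parts <- lapply(seq_along(genome@chromNames), function(i) {
      chrom <- genome@chromNames[i]
      len <- genome@chromLengths[i]
      dens <- .densityFor(config, chrom)
      hemizygous <- genome@sex == "male" && !is.na(genome@xName) &&
        chrom == genome@xName
      if (hemizygous) {
        ## hets only inside the PAR (none at all without one)
        if (!length(genome@par)) return(GRanges(seqinfo = si))
        lo <- start(genome@par); hi <- end(genome@par)
      } else {
        lo <- 1L; hi <- as.integer(len)
      }
      span <- hi - lo + 1
      n <- rpois(1L, dens * span / 1000)
      n <- min(n, span)
      if (n == 0L) return(GRanges(seqinfo = si))
      pos <- sort(lo - 1L + sample.int(span, n))
      ref <- sample(bases, n, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
      gr <- GRanges(chrom, IRanges(pos, width = 1L), seqinfo = si)
      mcols(gr) <- DataFrame(
        ref = ref, alt = unname(alt),
        qual = round(rgamma(n, shape = 4, scale = 30), 1),
        dp = .rdepth(n, config@meanDepth, config@depthDispersion),
        gq = pmin(99, round(rgamma(n, shape = 6, scale = 8))),
        sp = round(abs(rnorm(n, sd = 15)), 1),
        gt = rep("het", n), isSnp = rep(TRUE, n))
      gr
    })
    out <- do.call(c, parts)
    sort(out)
  })
}
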