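#' Construct a genome model for simulation
#'
#' Builds the chromosome complement of a simulated diploid individual:
#' \code{nAutosomes} autosomes named \code{"aut1"..."autN"}, optionally an
#' X chromosome named \code{"chrX"} carrying a terminal pseudoautosomal
#' region (PAR).  The PAR is placed at the X start by default; pass
#' \code{parAt = "end"} to abut the other terminus.  Construction is fully
#' deterministic; the \code{seed} argument is accepted for interface
#' symmetry with the generators and ignored.
#'
#' @param nAutosomes integer, number of autosomes.
#' @param autosomeLengths numeric of length \code{nAutosomes}, lengths in
#'   bp.
#' @param xLength numeric(1), X length in bp, or 0 for no X.
#' @param parLength numeric(1), PAR length in bp (0 = no PAR); must be
#'   smaller than \code{xLength}.
#' @param sex \code{"male"} or \code{"female"}.
#' @param parAt \code{"start"} (default) or \code{"end"}: which X terminus
#'   the PAR abuts.
#' @param seed ignored (construction is deterministic).
#' @return A \code{\link{GenomeModel}}.
#' @examples
#' g <- makeGenome(2, c(10e6, 8e6), xLength = 6e6, parLength = 1e6,
#'                 sex = "male")
#' parRegion(g)
#' @export
makeGenome <- function(nAutosomes, autosomeLengths, xLength = 0,
                       parLength = 0, sex = c("male", "female"),
                       parAt = c("start", "end"), seed = NULL) {
  sex <- match.arg(sex)
  parAt <- match.arg(parAt)
  if (length(autosomeLengths) != nAutosomes)
    stop("autosomeLengths must have length nAutosomes")
  if (any(autosomeLengths <= 0)) stop("autosome lengths must be positive")
  if (parLength > 0 && xLength <= 0)
    stop("a PAR requires an X chromosome")
  if (parLength >= xLength && parLength > 0)
    stop("parLength must be smaller than xLength")
  nm <- if (nAutosomes > 0) paste0("aut", seq_len(nAutosomes)) else character()
  len <- as.numeric(autosomeLengths)
  xnm <- NA_character_
  if (xLength > 0) {
    xnm <- "chrX"
    nm <- c(nm, xnm)
    len <- c(len, as.numeric(xLength))
  }
  par <- GRanges(seqinfo = Seqinfo(nm, len))
  if (parLength > 0) {
    rng <- if (parAt == "start") IRanges(1L, as.integer(parLength))
           else IRanges(as.integer(xLength - parLength + 1L),
                        as.integer(xLength))
    par <- GRanges(xnm, rng, seqinfo = Seqinfo(nm, len))
  }
  new("GenomeModel", chromNames = nm, chromLengths = len, xName = xnm,
      par = par, sex = sex)
}

#' Construct a simulation configuration
#'
#' @param meanDepth numeric(1), mean reads-per-base on diploid sequence
#'   (autosomes, PAR, female X).  Male non-PAR X is simulated at half this
#'   depth.
#' @param depthDispersion numeric(1) >= 1, per-base depth variance
#'   inflation: 1 gives Poisson depth, larger values a negative binomial
#'   with variance \code{meanDepth * depthDispersion}.
#' @param hetDensity named numeric, heterozygous SNPs per kbp per
#'   chromosome; the \code{".default"} entry covers chromosomes without a
#'   dedicated one.  A bare unnamed scalar is taken as the default for all
#'   chromosomes.
#' @param errorRate numeric(1) in [0, 1), fraction of k-mer observations
#'   that are errors.
#' @param k integer(1), k-mer length.
#' @param seed integer(1), seed used by every generator.
#' @return A \code{\link{SimulationConfig}}.
#' @examples
#' simulationConfig(meanDepth = 30, hetDensity = 0.6, seed = 7)
#' @export
simulationConfig <- function(meanDepth = 30, depthDispersion = 1,
                             hetDensity = c(.default = 0.6),
                             errorRate = 0, k = 23L, seed = 1L) {
  if (length(hetDensity) == 1L && is.null(names(hetDensity)))
    names(hetDensity) <- ".default"
  new("SimulationConfig", meanDepth = as.numeric(meanDepth),
      depthDispersion = as.numeric(depthDispersion),
      hetDensity = hetDensity, errorRate = as.numeric(errorRate),
      k = as.integer(k), seed = as.integer(seed))
}

## density for one chromosome, falling back to the ".default" entry
.densityFor <- function(config, chrom) {
  d <- config@hetDensity
  if (chrom %in% names(d)) return(unname(d[chrom]))
  if (".default" %in% names(d)) return(unname(d[".default"]))
  stop("no heterozygosity density configured for chromosome ", chrom,
       " and no '.default' entry")
}

## non-PAR X interval(s) of a model, as GRanges (empty if no X)
.nonParX <- function(genome) {
  if (is.na(genome@xName)) return(GRanges())
  xlen <- genome@chromLengths[match(genome@xName, genome@chromNames)]
  x <- GRanges(genome@xName, IRanges(1L, as.integer(xlen)))
  if (!length(genome@par)) return(x)
  GenomicRanges::setdiff(x, genome@par, ignore.strand = TRUE)
}
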