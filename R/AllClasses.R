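## S4 containers for the pipeline's central objects.  Coordinates are
## 1-based closed IRanges/GRanges throughout; 0-based half-open conversion
## happens only at the file boundary (BED/bedGraph, block TSV).

#' GenomeModel: chromosome complement of a simulated individual
#'
#' Describes the chromosomes of a diploid individual: autosome names and
#' lengths, an optional X chromosome, an optional pseudoautosomal region
#' (PAR) abutting one X terminus, and the individual's sex.  Males carry a
#' single X, so outside the PAR the X is hemizygous: it is simulated at
#' half the autosomal read depth and emits no heterozygous genotypes.
#'
#' @slot chromNames character, chromosome names in karyotype order.
#' @slot chromLengths numeric, chromosome lengths in bp (all positive).
#' @slot xName character(1), name of the X chromosome or \code{NA} if the
#'   model has no X.
#' @slot par \code{GRanges} with zero or one range on the X: the PAR.
#'   Must abut an X terminus and be shorter than the X.
#' @slot sex character(1), \code{"male"} or \code{"female"}.
#'
#' @seealso \code{\link{makeGenome}}
#' @export
setClass("GenomeModel",
  representation(
    chromNames = "character",
    chromLengths = "numeric",
    xName = "character",
    par = "GRanges",
    sex = "character"
  )
)

setValidity("GenomeModel", function(object) {
  msg <- NULL
  if (length(object@chromNames) != length(object@chromLengths))
    msg <- c(msg, "chromNames and chromLengths differ in length")
  if (anyDuplicated(object@chromNames))
    msg <- c(msg, "duplicated chromosome names")
  if (any(object@chromLengths <= 0))
    msg <- c(msg, "chromosome lengths must be positive")
  if (length(object@xName) != 1L)
    msg <- c(msg, "xName must be a single name or NA")
  if (!is.na(object@xName) && !(object@xName %in% object@chromNames))
    msg <- c(msg, "xName is not a chromosome of the model")
  if (!object@sex %in% c("male", "female"))
    msg <- c(msg, "sex must be 'male' or 'female'")
  if (length(object@par) > 1L)
    msg <- c(msg, "at most one PAR interval is allowed")
  if (length(object@par) == 1L) {
    if (is.na(object@xName))
      msg <- c(msg, "PAR given but model has no X")
    else {
      xlen <- object@chromLengths[match(object@xName, object@chromNames)]
      if (as.character(seqnames(object@par)) != object@xName)
        msg <- c(msg, "PAR must lie on the X")
      if (width(object@par) >= xlen)
        msg <- c(msg, "PAR must be shorter than the X")
      if (start(object@par) != 1L && end(object@par) != xlen)
        msg <- c(msg, "PAR must abut an X terminus")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' SimulationConfig: knobs of the synthetic-data generator
#'
#' @slot meanDepth numeric(1), mean reads-per-base on diploid sequence.
#' @slot depthDispersion numeric(1), variance inflation of the per-base
#'   depth distribution; 1 = Poisson, > 1 = negative binomial with
#'   variance \code{meanDepth * depthDispersion}.
#' @slot hetDensity named numeric, heterozygous SNPs per kbp by
#'   chromosome; the entry named \code{".default"} applies to any
#'   chromosome without its own entry.
#' @slot errorRate numeric(1) in [0, 1): fraction of k-mer observations
#'   that are sequencing errors (low-multiplicity spectrum component).
#' @slot k integer(1), k-mer length (default 23).
#' @slot seed integer(1), seed consumed by every generator for
#'   byte-identical reproducibility.
#'
#' @seealso \code{\link{simulationConfig}}
#' @export
setClass("SimulationConfig",
  representation(
    meanDepth = "numeric",
    depthDispersion = "numeric",
    hetDensity = "numeric",
    errorRate = "numeric",
    k = "integer",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- NULL
  if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be > 0")
  if (object@depthDispersion < 1)
    msg <- c(msg, "depthDispersion must be >= 1")
  if (any(object@hetDensity < 0))
    msg <- c(msg, "heterozygosity densities must be >= 0")
  if (is.null(names(object@hetDensity)) || any(names(object@hetDensity) == ""))
    msg <- c(msg, "hetDensity must be fully named")
  if (object@errorRate < 0 || object@errorRate >= 1)
    msg <- c(msg, "errorRate must be in [0, 1)")
  if (object@k < 1L) msg <- c(msg, "k must be a positive integer")
  if (is.null(msg)) TRUE else msg
})

#' CoverageWindowTrack: windowed median read depth
#'
#' Fixed-width stacking (non-overlapping, tiling) windows per chromosome
#' with the median per-base depth of each.  The last window of a
#' chromosome may be shorter than the nominal width and is flagged
#' \code{partial}; it participates in downstream segment merging with its
#' actual median.  Normalized levels (fraction of the genome-wide level)
#' are available once \code{genomeLevel} has been computed.
#'
#' @slot windows \code{GRanges} sorted and tiling each chromosome, with
#'   metadata columns \code{median} (numeric) and \code{partial} (logical).
#' @slot windowSize integer(1), nominal window width in bp.
#' @slot xName character(1), name of the X chromosome or \code{NA}.
#' @slot genomeLevel numeric(1), the normalization denominator, or
#'   \code{NA} before \code{\link{genomeLevel}} has been applied.
#'
#' @seealso \code{\link{windowMedians}}, \code{\link{normalizedLevels}}
#' @export
setClass("CoverageWindowTrack",
  representation(
    windows = "GRanges",
    windowSize = "integer",
    xName = "character",
    genomeLevel = "numeric"
  )
)

setValidity("CoverageWindowTrack", function(object) {
  msg <- NULL
  w <- object@windows
  if (!all(c("median", "partial") %in% names(mcols(w))))
    msg <- c(msg, "windows need 'median' and 'partial' metadata columns")
  else {
    if (any(mcols(w)$median < 0, na.rm = TRUE))
      msg <- c(msg, "window medians must be >= 0")
    bychr <- split(w, seqnames(w))
    for (chr in names(bychr)) {
      g <- bychr[[chr]]
      if (length(g) == 0L) next
      if (is.unsorted(start(g)))
        msg <- c(msg, sprintf("windows on %s are unsorted", chr))
      if (length(g) > 1L && any(start(g)[-1L] != end(g)[-length(g)] + 1L))
        msg <- c(msg, sprintf("windows on %s do not tile", chr))
    }
  }
  if (object@windowSize < 1L) msg <- c(msg, "windowSize must be positive")
  if (!is.na(object@genomeLevel) && object@genomeLevel < 0)
    msg <- c(msg, "genomeLevel must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' ParCall: diploid-coverage segments on the X and the designated PAR
#'
#' @slot segments \code{GRanges}, disjoint sorted X intervals whose
#'   (merged) windows reached the diploid coverage threshold.
#' @slot par \code{GRanges} with zero or one range: the terminal segment
#'   designated as the pseudoautosomal region, or empty if none.
#' @slot threshold numeric(1), the fraction of the genome level used.
#' @slot diploidX logical(1), \code{TRUE} when the whole X was at diploid
#'   level (a female-like X) so a terminal PAR is not resolvable.
#'
#' @seealso \code{\link{detectPar}}, \code{\link{parLength}}
#' @export
setClass("ParCall",
  representation(
    segments = "GRanges",
    par = "GRanges",
    threshold = "numeric",
    diploidX = "logical"
  )
)

setValidity("ParCall", function(object) {
  msg <- NULL
  s <- object@segments
  if (length(s) > 1L) {
    if (is.unsorted(start(s))) msg <- c(msg, "segments must be sorted")
    if (any(start(s)[-1L] <= end(s)[-length(s)]))
      msg <- c(msg, "segments must be disjoint")
  }
  if (length(object@par) > 1L) msg <- c(msg, "at most one PAR")
  if (is.null(msg)) TRUE else msg
})

#' SexInference: coverage-based sex call
#'
#' @slot xRatio numeric(1), median normalized X window level divided by
#'   the autosomal level (which is 1 after normalization).
#' @slot label character(1), \code{"male"} or \code{"female"};
#'   male iff \code{xRatio < threshold}.
#' @slot threshold numeric(1), decision threshold on the ratio.
#'
#' @seealso \code{\link{inferSex}}
#' @export
setClass("SexInference",
  representation(xRatio = "numeric", label = "character",
                 threshold = "numeric")
)

setValidity("SexInference", function(object) {
  msg <- NULL
  if (object@xRatio < 0) msg <- c(msg, "xRatio must be >= 0")
  if (!object@label %in% c("male", "female"))
    msg <- c(msg, "label must be 'male' or 'female'")
  if ((object@xRatio < object@threshold) != (object@label == "male"))
    msg <- c(msg, "label inconsistent with xRatio and threshold")
  if (is.null(msg)) TRUE else msg
})

#' FilterConfig: variant quality filter thresholds
#'
#' Holds the removal rule \code{QUAL < minQual || (SP > maxSp | DP < minDp
#' | GQ < minGq)} (all comparisons strict) and the inclusive depth band
#' \code{[covBand[1], covBand[2]]} expressed as fractions of the mean
#' genome coverage.
#'
#' @slot minQual numeric(1), default 20.
#' @slot maxSp numeric(1), strand-bias Phred score ceiling, default 60.
#' @slot minDp numeric(1), default 5.
#' @slot minGq numeric(1), default 20.
#' @slot covBand numeric(2), depth band as fractions of mean coverage,
#'   default \code{c(0.30, 2.50)}.
#'
#' @seealso \code{\link{filterConfig}}, \code{\link{filterVariants}}
#' @export
setClass("FilterConfig",
  representation(minQual = "numeric", maxSp = "numeric", minDp = "numeric",
                 minGq = "numeric", covBand = "numeric")
)

setValidity("FilterConfig", function(object) {
  msg <- NULL
  if (length(object@covBand) != 2L || object@covBand[1] >= object@covBand[2])
    msg <- c(msg, "covBand must be two increasing fractions")
  if (any(c(object@minQual, object@maxSp, object@minDp, object@minGq,
            object@covBand) < 0))
    msg <- c(msg, "all thresholds must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' HetTrack: sliding-window heterozygosity densities
#'
#' Overlapping windows (default 1 Mbp, advanced by a 100 kbp step) per
#' chromosome, each carrying the count of heterozygous SNPs whose position
#' falls in the window and the count scaled to SNPs per kbp of the actual
#' window span (end-of-chromosome windows are truncated, not dropped).
#'
#' @slot windows \code{GRanges} with metadata columns \code{count}
#'   (integer) and \code{density} (numeric, SNPs/kbp), sorted by start
#'   within chromosome; consecutive starts differ by \code{step}.
#' @slot window integer(1), nominal window span in bp.
#' @slot step integer(1), step between window starts in bp.
#' @slot xName character(1), name of the X chromosome or \code{NA}.
#'
#' @seealso \code{\link{hetWindows}}, \code{\link{hetSummary}}
#' @export
setClass("HetTrack",
  representation(windows = "GRanges", window = "integer", step = "integer",
                 xName = "character")
)

setValidity("HetTrack", function(object) {
  msg <- NULL
  w <- object@windows
  if (!all(c("count", "density") %in% names(mcols(w))))
    msg <- c(msg, "windows need 'count' and 'density' metadata columns")
  else if (any(mcols(w)$density < 0))
    msg <- c(msg, "densities must be >= 0")
  if (object@window %% object@step != 0L)
    msg <- c(msg, "window must be a multiple of step")
  st <- split(start(w), seqnames(w))
  for (chr in names(st)) {
    s <- st[[chr]]
    if (length(s) > 1L && any(diff(s) != object@step))
      msg <- c(msg, sprintf("window starts on %s not spaced by step", chr))
  }
  if (is.null(msg)) TRUE else msg
})

#' HetSummary: summary statistics of a heterozygosity track
#'
#' @slot min,median,mean,max numeric(1), over window densities (SNPs/kbp).
#' @slot modes numeric, center(s) of the most populated histogram bin(s);
#'   ties yield multiple modes.  Bins are centered on multiples of
#'   \code{binWidth}.
#' @slot zeroMode logical(1), \code{TRUE} when the zero bin is a local
#'   maximum of the histogram (the signature of a hemizygous male X), even
#'   if it is not the global mode.
#' @slot binWidth numeric(1), histogram bin width in SNPs/kbp.
#' @slot xExcluded logical(1), whether X windows were excluded.
#'
#' @seealso \code{\link{hetSummary}}
#' @export
setClass("HetSummary",
  representation(min = "numeric", median = "numeric", mean = "numeric",
                 max = "numeric", modes = "numeric", zeroMode = "logical",
                 binWidth = "numeric", xExcluded = "logical")
)

setValidity("HetSummary", function(object) {
  msg <- NULL
  if (!(object@min <= object@median && object@median <= object@max))
    msg <- c(msg, "min <= median <= max violated")
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' SyntenyBlockSet: oriented reference-query alignment blocks
#'
#' A table of synteny blocks between a reference genome and a query
#' assembly, with the scaffold length tables of both sides.  Block
#' coordinates are 1-based closed on both reference and query; query
#' coordinates always ascend, with the \code{orientation} column
#' (\code{"+"} or \code{"-"}) carrying the strand sense (PSL-like
#' convention).
#'
#' @slot blocks data.frame with columns \code{refChrom}, \code{refStart},
#'   \code{refEnd}, \code{queryChrom}, \code{queryStart}, \code{queryEnd},
#'   \code{orientation}; sorted by (refChrom, refStart).
#' @slot refLengths named numeric, reference chromosome lengths (bp).
#' @slot queryLengths named numeric, query scaffold lengths (bp).
#'
#' @seealso \code{\link{simulateSynteny}}, \code{\link{filterBlocks}},
#'   \code{\link{readSyntenyBlocks}}
#' @export
setClass("SyntenyBlockSet",
  representation(blocks = "data.frame", refLengths = "numeric",
                 queryLengths = "numeric")
)

setValidity("SyntenyBlockSet", function(object) {
  msg <- NULL
  b <- object@blocks
  need <- c("refChrom", "refStart", "refEnd", "queryChrom", "queryStart",
            "queryEnd", "orientation")
  if (!all(need %in% names(b)))
    return(paste("blocks must have columns:", paste(need, collapse = ", ")))
  if (nrow(b)) {
    if (!all(b$orientation %in% c("+", "-")))
      msg <- c(msg, "orientation must be '+' or '-'")
    if (any(b$refStart < 1 | b$refStart > b$refEnd))
      msg <- c(msg, "need 1 <= refStart <= refEnd")
    if (any(b$queryStart < 1 | b$queryStart > b$queryEnd))
      msg <- c(msg, "need 1 <= queryStart <= queryEnd")
    if (!all(b$refChrom %in% names(object@refLengths)))
      msg <- c(msg, "refChrom missing from refLengths")
    else if (any(b$refEnd > object@refLengths[b$refChrom]))
      msg <- c(msg, "block exceeds reference chromosome length")
    if (!all(b$queryChrom %in% names(object@queryLengths)))
      msg <- c(msg, "queryChrom missing from queryLengths")
    else if (any(b$queryEnd > object@queryLengths[b$queryChrom]))
      msg <- c(msg, "block exceeds query scaffold length")
    o <- order(b$refChrom, b$refStart)
    if (!identical(o, seq_len(nrow(b))))
      msg <- c(msg, "blocks must be sorted by (refChrom, refStart)")
  }
  if (is.null(msg)) TRUE else msg
})

#' ChromosomeCorrespondence: query scaffold to reference chromosome map
#'
#' Each query scaffold is assigned to the reference chromosome that
#' receives the most aligned bp, named either from a chromosome-painting
#' (Zoo-FISH) map (\code{"chr<n>"}) or, without one, \code{"chrX"} for the
#' scaffold matching the reference X and \code{"aut1"..."autN"} for the
#' rest in order of decreasing scaffold length.
#'
#' @slot table data.frame with one row per query scaffold: \code{query},
#'   \code{ref} (assigned chromosome or NA), \code{alignedBp},
#'   \code{coverageFraction} (alignedBp / scaffold length),
#'   \code{assignedName}, \code{dominantOrientation} (\code{"+"}/\code{"-"}),
#'   \code{minusFraction} (fraction of aligned bp in "-" blocks).
#' @slot refXName character(1), name of the reference X or \code{NA}.
#'
#' @seealso \code{\link{assignChromosomes}}
#' @export
setClass("ChromosomeCorrespondence",
  representation(table = "data.frame", refXName = "character")
)

setValidity("ChromosomeCorrespondence", function(object) {
  tb <- object@table
  need <- c("query", "ref", "alignedBp", "coverageFraction", "assignedName",
            "dominantOrientation", "minusFraction")
  if (!all(need %in% names(tb)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  nm <- tb$assignedName[!is.na(tb$assignedName)]
  if (anyDuplicated(nm)) return("assigned names must be unique")
  TRUE
})

#' ScaffoldStats: assembly contiguity summary
#'
#' @slot nScaffolds integer(1).
#' @slot totalLength numeric(1), summed scaffold length in bp.
#' @slot n50 numeric(1), the length N such that scaffolds of length >= N
#'   hold at least half the total (N50 is always a member of the list).
#' @slot l50 integer(1), number of scaffolds needed to reach half the
#'   total.
#' @slot lengths numeric, scaffold lengths sorted in decreasing order.
#'
#' @seealso \code{\link{scaffoldStats}}
#' @export
setClass("ScaffoldStats",
  representation(nScaffolds = "integer", totalLength = "numeric",
                 n50 = "numeric", l50 = "integer", lengths = "numeric")
)

setValidity("ScaffoldStats", function(object) {
  msg <- NULL
  if (!object@n50 %in% object@lengths)
    msg <- c(msg, "n50 must be a member of the length list")
  cum <- cumsum(object@lengths)
  if (cum[object@l50] < object@totalLength / 2)
    msg <- c(msg, "cumulative length at l50 below half the total")
  if (object@l50 > 1L && cum[object@l50 - 1L] >= object@totalLength / 2)
    msg <- c(msg, "l50 is not the first crossing")
  if (is.null(msg)) TRUE else msg
})

#' CScaffoldCutoff: chromosome-scale scaffold cutoff
#'
#' The rank \code{k} (1-based, on the descending-sorted length list) at
#' which the ratio of consecutive scaffold lengths is maximal: scaffolds
#' 1..k are the chromosome-scale candidates when the fold gap is large.
#'
#' @slot k integer(1), rank maximizing \code{L[k] / L[k+1]}.
#' @slot foldGap numeric(1), the maximal ratio (>= 1).
#' @slot foldGapRounded numeric(1), \code{foldGap} rounded to the nearest
#'   integer for display ("a 29-fold difference").
#' @slot isChromosomeScale logical(1), \code{foldGap >= flagThreshold}.
#' @slot flagThreshold numeric(1), the flagging threshold used.
#'
#' @seealso \code{\link{cScaffoldCutoff}}
#' @export
setClass("CScaffoldCutoff",
  representation(k = "integer", foldGap = "numeric",
                 foldGapRounded = "numeric", isChromosomeScale = "logical",
                 flagThreshold = "numeric")
)

setValidity("CScaffoldCutoff", function(object) {
  if (object@foldGap < 1) return("foldGap must be >= 1")
  TRUE
})
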