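#' Construct a variant filter configuration
#'
#' Defaults encode the removal expression
#' \code{QUAL < 20.0 || (SP > 60.0 | DP < 5.0 | GQ < 20.0)} (strict
#' comparisons) followed by the inclusive 30-250\% depth band relative to
#' the mean genome coverage.
#'
#' @param minQual,maxSp,minDp,minGq numeric thresholds; see
#'   \code{\link{FilterConfig}}.
#' @param covBand numeric(2), depth band as fractions of mean coverage.
#' @return A \code{\link{FilterConfig}}.
#' @export
filterConfig <- function(minQual = 20.0, maxSp = 60.0, minDp = 5.0,
                         minGq = 20.0, covBand = c(0.30, 2.50)) {
  new("FilterConfig", minQual = minQual, maxSp = maxSp, minDp = minDp,
      minGq = minGq, covBand = covBand)
}

#' Filter variant records by quality and depth band
#'
#' Applies the two-stage filter: a record is removed iff
#' \code{qual < minQual} OR \code{sp > maxSp} OR \code{dp < minDp} OR
#' \code{gq < minGq} (all strict); survivors are then kept iff
#' \code{covBand[1] * meanCov <= dp <= covBand[2] * meanCov} (inclusive).
#' Records missing a required annotation are counted and skipped rather
#' than aborting the run.  The removal tally attributes each removed
#' record to the first failing rule, in the order the expression is
#' written (\code{qual}, \code{sp}, \code{dp}, \code{gq}, then
#' \code{covBand}) -- a stable, explainable accounting.
#'
#' @param records \code{GRanges} with metadata columns \code{qual},
#'   \code{dp}, \code{gq}, \code{sp} (as from
#'   \code{\link{simulateVariants}} or \code{\link{readVariantsVcf}}).
#' @param config a \code{\link{FilterConfig}}.
#' @param meanCov numeric(1) > 0, mean whole-genome coverage anchoring
#'   the depth band.
#' @return A list with \code{kept} (the surviving \code{GRanges}) and
#'   \code{tally} (named integer: removals per rule, \code{missing} for
#'   records lacking a field, and \code{kept}).
#' @examples
#' g <- makeGenome(1, 1e6, sex = "female")
#' v <- simulateVariants(g, simulationConfig(seed = 6))
#' filterVariants(v, filterConfig(), meanCov = 30)$tally
#' @export
filterVariants <- function(records, config = filterConfig(), meanCov) {
  stopifnot(is(records, "GRanges"), is(config, "FilterConfig"))
  validObject(config)
  if (missing(meanCov) || meanCov <= 0)
    stop("meanCov must be supplied and > 0")
  mc <- mcols(records)
  need <- c("qual", "dp", "gq", "sp")
  if (!all(need %in% names(mc)))
    stop("records must carry metadata columns: ",
         paste(setdiff(need, names(mc)), collapse = ", "))
  qual <- mc$qual; dp <- mc$dp; gq <- mc$gq; sp <- mc$sp
  missing <- is.na(qual) | is.na(dp) | is.na(gq) | is.na(sp)
  ## first-match rule attribution, in written order
  failQual <- !missing & qual < config@minQual
  failSp   <- !missing & !failQual & sp > config@maxSp
  failDp   <- !missing & !failQual & !failSp & dp < config@minDp
  failGq   <- !missing & !failQual & !failSp & !failDp & gq < config@minGq
  pass1 <- !missing & !(failQual | failSp | failDp | failGq)
  lo <- config@covBand[1] * meanCov
  hi <- config@covBand[2] * meanCov
  failBand <- pass1 & !(dp >= lo & dp <= hi)
  keep <- pass1 & !failBand
  tally <- c(qual = sum(failQual), sp = sum(failSp), dp = sum(failDp),
             gq = sum(failGq), covBand = sum(failBand),
             missing = sum(missing), kept = sum(keep))
  list(kept = records[keep], tally = tally)
}

.HET_GT <- c("het", "0/1", "1/0", "0|1", "1|0")

## TRUE for records whose genotype is heterozygous
.isHet <- function(records) {
  gt <- mcols(records)$gt
  if (is.null(gt)) stop("records must carry a 'gt' metadata column")
  !is.na(gt) & gt %in% .HET_GT
}

#' Mask heterozygous calls in the hemizygous region of a male X
#'
#' A male carries a single copy of the X outside the pseudoautosomal
#' region, so heterozygous genotypes there are artifacts; they are set to
#' \code{"missing"} and thereby excluded from all downstream counts.
#' Females, autosomes and the PAR are untouched.  A male without a
#' resolved PAR is handled conservatively: the whole X is masked, with a
#' warning.
#'
#' @param records \code{GRanges} with a \code{gt} metadata column.
#' @param sex \code{"male"} or \code{"female"}.
#' @param par a \code{\link{ParCall}}, a \code{GRanges} holding the PAR,
#'   or \code{NULL} if unresolved.
#' @param xName character(1), name of the X chromosome.
#' @return The records with masked genotypes set to \code{"missing"}.
#' @export
applyPloidyMask <- function(records, sex = c("male", "female"), par,
                            xName = "chrX") {
  sex <- match.arg(sex)
  stopifnot(is(records, "GRanges"))
  if (sex == "female") return(records)
  parGr <- if (is(par, "ParCall")) par@par
           else if (is(par, "GRanges")) par
           else GRanges()
  onX <- as.character(seqnames(records)) == xName
  if (length(parGr) == 0L) {
    warning("male sample without a resolved PAR: masking the whole X")
    mask <- onX & .isHet(records)
  } else {
    inPar <- overlapsAny(records, parGr, ignore.strand = TRUE)
    mask <- onX & !inPar & .isHet(records)
  }
  mcols(records)$gt[mask] <- "missing"
  records
}
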