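#' Filter synteny blocks by reference span
#'
#' Retains blocks whose reference span (refEnd - refStart + 1) is at
#' least \code{minLen} bp; the 50 kbp default matches the usual minimum
#' block size of whole-genome-alignment synteny extraction.
#'
#' @param set a \code{\link{SyntenyBlockSet}}.
#' @param minLen numeric(1), inclusive minimum span in bp.
#' @return The filtered \code{\link{SyntenyBlockSet}}; the number of
#'   removed blocks is available as \code{metadata} attribute
#'   \code{nRemoved} on the returned object's block table.
#' @export
filterBlocks <- function(set, minLen = 50000) {
  stopifnot(is(set, "SyntenyBlockSet"))
  b <- set@blocks
  span <- b$refEnd - b$refStart + 1
  keep <- span >= minLen
  out <- b[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nRemoved") <- sum(!keep)
  new("SyntenyBlockSet", blocks = out, refLengths = set@refLengths,
      queryLengths = set@queryLengths)
}

## aligned bp per (query, ref) pair and per orientation
.pairTable <- function(b) {
  bp <- b$refEnd - b$refStart + 1
  key <- paste(b$queryChrom, b$refChrom, sep = "\r")
  tot <- tapply(bp, key, sum)
  minus <- tapply(bp * (b$orientation == "-"), key, sum)
  parts <- do.call(rbind, strsplit(names(tot), "\r", fixed = TRUE))
  data.frame(query = parts[, 1], ref = parts[, 2],
             alignedBp = as.numeric(tot),
             minusBp = as.numeric(minus), stringsAsFactors = FALSE)
}

#' Assign query scaffolds to reference chromosomes
#'
#' Each query scaffold is assigned to the reference chromosome receiving
#' the most aligned bp.  Naming follows karyotype practice: with a
#' chromosome-painting map (\code{fishMap}: query scaffold -> chromosome
#' number) scaffolds are named \code{"chr<n>"}; without one, the scaffold
#' assigned to the reference X is named \code{"chrX"} (the X is highly
#' conserved across carnivores, so this assignment is safe) and the rest
#' are numbered \code{"aut1"..."autN"} from longest to shortest query
#' scaffold.  The dominant orientation of each assignment is the strand
#' carrying the majority of aligned bp -- robust to many tiny blocks.
#'
#' @param set a (filtered) \code{\link{SyntenyBlockSet}}.
#' @param fishMap optional named vector: query scaffold -> chromosome
#'   number.
#' @param refXName character(1), name of the reference X chromosome, or
#'   \code{NA} if unknown.
#' @return A \code{\link{ChromosomeCorrespondence}}.  Query scaffolds
#'   with zero aligned bp are reported with \code{ref = NA}.
#' @export
assignChromosomes <- function(set, fishMap = NULL, refXName = "chrX") {
  stopifnot(is(set, "SyntenyBlockSet"))
  refXName <- if (is.null(refXName) || is.na(refXName)) NA_character_
              else as.character(refXName)
  b <- set@blocks
  pt <- if (nrow(b)) .pairTable(b) else
    data.frame(query = character(), ref = character(),
               alignedBp = numeric(), minusBp = numeric())
  queries <- names(set@queryLengths)
  rows <- lapply(queries, function(q) {
    sub <- pt[pt$query == q, , drop = FALSE]
    if (nrow(sub) == 0L)
      return(data.frame(query = q, ref = NA_character_, alignedBp = 0,
                        coverageFraction = 0,
                        dominantOrientation = NA_character_,
                        minusFraction = NA_real_,
                        stringsAsFactors = FALSE))
    best <- sub[which.max(sub$alignedBp), ]
    minusFrac <- best$minusBp / best$alignedBp
    data.frame(query = q, ref = best$ref, alignedBp = best$alignedBp,
               coverageFraction = best$alignedBp / set@queryLengths[[q]],
               dominantOrientation = if (minusFrac > 0.5) "-" else "+",
               minusFraction = minusFrac, stringsAsFactors = FALSE)
  })
  tb <- do.call(rbind, rows)
  ## naming: fishMap beats conservation-based X + length-ranked "aut"
  tb$assignedName <- NA_character_
  if (!is.null(fishMap)) {
    hit <- tb$query %in% names(fishMap) & !is.na(tb$ref)
    tb$assignedName[hit] <- paste0("chr", fishMap[tb$query[hit]])
  } else {
    isX <- !is.na(tb$ref) & !is.na(refXName) & tb$ref == refXName
    tb$assignedName[isX] <- "chrX"
    rest <- which(!is.na(tb$ref) & !isX)
    if (length(rest)) {
      ord <- rest[order(-set@queryLengths[tb$query[rest]])]
      tb$assignedName[ord] <- paste0("aut", seq_along(ord))
    }
  }
  rownames(tb) <- NULL
  new("ChromosomeCorrespondence", table = tb, refXName = refXName)
}

#' Flag whole-scaffold inversions
#'
#' A query scaffold is flagged whole-scaffold-inverted when at least
#' \code{minFraction} of its aligned bp lies in reverse-orientation
#' blocks -- i.e. the scaffold was assembled reverse-complemented with
#' respect to the reference.  Scaffolds where neither orientation
#' reaches \code{minFraction} are reported ambiguous and not flagged.
#'
#' @param corr a \code{\link{ChromosomeCorrespondence}}.
#' @param minFraction numeric(1) in (0.5, 1], default 0.8.
#' @return data.frame with columns \code{query}, \code{ref},
#'   \code{minusFraction}, \code{inverted}, \code{ambiguous}.
#' @export
scaffoldOrientation <- function(corr, minFraction = 0.8) {
  stopifnot(is(corr, "ChromosomeCorrespondence"))
  tb <- corr@table
  mf <- tb$minusFraction
  inverted <- !is.na(mf) & mf >= minFraction
  ambiguous <- !is.na(mf) & pmax(mf, 1 - mf) < minFraction
  data.frame(query = tb$query, ref = tb$ref, minusFraction = mf,
             inverted = inverted, ambiguous = ambiguous,
             stringsAsFactors = FALSE)
}

## group indices of opposite-orientation blocks into runs, tolerating up
## to maxIntervening dominant blocks inside a run
.oppositeRuns <- function(opp, maxIntervening) {
  idx <- which(opp)
  if (length(idx) == 0L) return(list())
  breaks <- which(diff(idx) > maxIntervening + 1L)
  startAt <- c(1L, breaks + 1L)
  endAt <- c(breaks, length(idx))
  lapply(seq_along(startAt),
         function(i) idx[startAt[i]]:idx[endAt[i]])
}

#' Call inversions from opposite-orientation block runs
#'
#' Within each assigned (query scaffold, reference chromosome) pair,
#' maximal runs of consecutive blocks whose orientation opposes the
#' pair's dominant orientation become inversion calls.  A call spans the
#' first to the last opposing block on the reference; its scale class is
#' \code{"megabase"} when the span reaches \code{megabaseThreshold},
#' \code{"short"} otherwise.  \code{maxIntervening} dominant-orientation
#' blocks are tolerated inside a run (0 = strict runs) to absorb
#' orientation-flip noise in the alignment.
#'
#' @param set a filtered \code{\link{SyntenyBlockSet}}.
#' @param corr the matching \code{\link{ChromosomeCorrespondence}}.
#' @param megabaseThreshold numeric(1), span separating megabase-scale
#'   calls from short ones (default 1 Mbp).
#' @param maxIntervening integer(1), dominant blocks tolerated inside a
#'   run (default 0).
#' @return data.frame with one row per call: \code{refChrom},
#'   \code{refStart}, \code{refEnd}, \code{query}, \code{nBlocks},
#'   \code{span}, \code{scaleClass}.
#' @export
callInversions <- function(set, corr, megabaseThreshold = 1000000,
                           maxIntervening = 0L) {
  stopifnot(is(set, "SyntenyBlockSet"),
            is(corr, "ChromosomeCorrespondence"))
  b <- set@blocks
  tb <- corr@table
  calls <- list()
  for (i in seq_len(nrow(tb))) {
    if (is.na(tb$ref[i])) next
    q <- tb$query[i]; r <- tb$ref[i]; dom <- tb$dominantOrientation[i]
    sub <- b[b$queryChrom == q & b$refChrom == r, , drop = FALSE]
    if (nrow(sub) == 0L) next
    sub <- sub[order(sub$refStart), , drop = FALSE]
    runs <- .oppositeRuns(sub$orientation != dom, as.integer(maxIntervening))
    for (run in runs) {
      opp <- run[sub$orientation[run] != dom]
      s <- sub$refStart[min(run)]; e <- sub$refEnd[max(run)]
      calls[[length(calls) + 1L]] <- data.frame(
        refChrom = r, refStart = s, refEnd = e, query = q,
        nBlocks = length(opp), span = e - s + 1,
        scaleClass = if (e - s + 1 >= megabaseThreshold) "megabase"
                     else "short",
        stringsAsFactors = FALSE)
    }
  }
  if (length(calls) == 0L)
    return(data.frame(refChrom = character(), refStart = numeric(),
                      refEnd = numeric(), query = character(),
                      nBlocks = integer(), span = numeric(),
                      scaleClass = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  out <- out[order(out$refChrom, out$refStart), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## reciprocal overlap of [s1,e1] and [s2,e2] (1-based closed)
.reciprocalOverlap <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2) + 1
  if (ov <= 0) return(0)
  min(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1))
}

#' Group inversion calls shared across query species
#'
#' Calls from different query species on the same reference chromosome
#' overlapping reciprocally by at least \code{minReciprocal} are grouped
#' as shared: each call gains a \code{sharedWith} column listing the
#' other species carrying an overlapping call (comma-separated, empty
#' when unique).
#'
#' @param callsList named list of call tables (one per query species) as
#'   returned by \code{\link{callInversions}}.
#' @param minReciprocal numeric(1) in (0, 1], default 0.5.
#' @return One combined data.frame with added columns \code{species} and
#'   \code{sharedWith}.
#' @export
sharedInversions <- function(callsList, minReciprocal = 0.5) {
  stopifnot(is.list(callsList), !is.null(names(callsList)))
  all <- do.call(rbind, lapply(names(callsList), function(sp) {
    x <- callsList[[sp]]
    if (nrow(x) == 0L) return(NULL)
    x$species <- sp
    x
  }))
  if (is.null(all))
    return(data.frame(refChrom = character(), refStart = numeric(),
                      refEnd = numeric(), query = character(),
                      nBlocks = integer(), span = numeric(),
                      scaleClass = character(), species = character(),
                      sharedWith = character(), stringsAsFactors = FALSE))
  shared <- character(nrow(all))
  for (i in seq_len(nrow(all))) {
    hits <- character()
    for (j in seq_len(nrow(all))) {
      if (i == j || all$species[i] == all$species[j]) next
      if (all$refChrom[i] != all$refChrom[j]) next
      ro <- .reciprocalOverlap(all$refStart[i], all$refEnd[i],
                               all$refStart[j], all$refEnd[j])
      if (ro >= minReciprocal) hits <- c(hits, all$species[j])
    }
    shared[i] <- paste(unique(hits), collapse = ",")
  }
  all$sharedWith <- shared
  rownames(all) <- NULL
  all
}
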