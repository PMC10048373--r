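## coerce per-base depth input (RleList, named list of vectors, or a
## single Rle/vector for a one-chromosome track) to a named list of Rle
.asDepthList <- function(depth, chromName = NULL) {
  if (is(depth, "RleList")) {
    out <- as.list(depth)
  } else if (is(depth, "Rle") || is.atomic(depth)) {
    out <- list(Rle(depth))
    names(out) <- if (!is.null(chromName)) chromName else "chr"
  } else if (is.list(depth)) {
    out <- lapply(depth, Rle)
  } else stop("unsupported depth track representation")
  if (length(out) && (is.null(names(out)) || any(names(out) == "")))
    stop("depth track chromosomes must be named")
  out
}

## median of each stacking window of width w over a depth vector; the
## trailing partial window (if any) is computed on its actual span
.windowMedianVec <- function(v, w) {
  len <- length(v)
  nfull <- len %/% w
  med <- numeric(0)
  if (nfull > 0) {
    ## one radix sort of (window, value) beats per-window sorting
    vv <- v[seq_len(nfull * w)]
    grp <- rep.int(seq_len(nfull), rep.int(w, nfull))
    s <- vv[order(grp, vv, method = "radix")]
    base <- (seq_len(nfull) - 1L) * w
    med <- if (w %% 2L == 1L) s[base + (w + 1L) %/% 2L]
           else (s[base + w %/% 2L] + s[base + w %/% 2L + 1L]) / 2
  }
  if (len > nfull * w) med <- c(med, median(v[(nfull * w + 1L):len]))
  med
}

#' Median read depth in stacking windows
#'
#' Tiles every chromosome with non-overlapping windows of \code{window}
#' bp (default 10 kbp) and records the median per-base depth of each.
#' The trailing window of a chromosome may be shorter than nominal; it is
#' kept, computed over its actual span, and flagged \code{partial} --
#' dropping terminal windows would bias the boundaries of terminal
#' features such as the PAR.
#'
#' @param depth per-base depth track: an \code{RleList} (as from
#'   \code{\link{simulateCoverage}} or \code{\link{readDepthBedgraph}}),
#'   a named list of per-base vectors, or a single vector/Rle for a
#'   one-chromosome track.
#' @param window integer(1), window width in bp (default 10000).
#' @param xName character(1), name of the X chromosome if present
#'   (carried along for \code{\link{genomeLevel}}, \code{\link{inferSex}}
#'   and \code{\link{detectPar}}).
#' @param chromName chromosome name to use when \code{depth} is a bare
#'   vector.
#' @return A \code{\link{CoverageWindowTrack}}.
#' @examples
#' wt <- windowMedians(list(a = rep(30, 25000)), window = 10000)
#' trackWindows(wt)
#' @export
windowMedians <- function(depth, window = 10000L, xName = NA_character_,
                          chromName = NULL) {
  if (window <= 0) stop("window must be positive")
  dl <- .asDepthList(depth, chromName)
  if (length(dl) == 0L || all(lengths(dl) == 0L))
    stop("empty depth track")
  window <- as.integer(window)
  si <- Seqinfo(names(dl), vapply(dl, length, 0))
  parts <- lapply(names(dl), function(chrom) {
    v <- as.numeric(dl[[chrom]])
    len <- length(v)
    if (len == 0L) return(NULL)
    med <- .windowMedianVec(v, window)
    n <- length(med)
    starts <- (seq_len(n) - 1L) * window + 1L
    ends <- pmin(starts + window - 1L, len)
    gr <- GRanges(chrom, IRanges(starts, ends), seqinfo = si)
    mcols(gr) <- DataFrame(median = med,
                           partial = width(gr) < window)
    gr
  })
  w <- do.call(c, parts[!vapply(parts, is.null, TRUE)])
  new("CoverageWindowTrack", windows = w, windowSize = window,
      xName = xName, genomeLevel = NA_real_)
}

#' @describeIn genomeLevel median of per-window medians over the selected
#'   chromosomes: the "whole genome level" used to normalize window
#'   coverage.  With \code{autosomesOnly = TRUE} (default) windows on the
#'   X are excluded, which keeps the level robust to the depth depression
#'   of a male X.
#' @param autosomesOnly logical(1), exclude X windows (default TRUE; the
#'   X is identified by the track's \code{xName}).
#' @export
setMethod("genomeLevel", "CoverageWindowTrack",
          function(x, autosomesOnly = TRUE) {
  w <- x@windows
  if (autosomesOnly && !is.na(x@xName))
    w <- w[seqnames(w) != x@xName]
  if (length(w) == 0L) stop("no qualifying windows for the genome level")
  median(mcols(w)$median)
})

#' Infer sample sex from the X to autosome coverage ratio
#'
#' A male carries one X against two of each autosome, so its X windows
#' sit near half the genome-wide coverage level (the small PAR excepted),
#' while a female X matches the autosomes.  The ratio of the median
#' normalized X window level to the autosomal level (1.0 by definition)
#' therefore clusters near 0.5 or 1.0; the decision threshold defaults to
#' the midpoint 0.75.
#'
#' @param track a \code{\link{CoverageWindowTrack}} whose \code{xName}
#'   identifies the X.
#' @param level numeric(1), the genome level; computed from the autosomal
#'   windows when omitted.
#' @param decisionThreshold numeric(1); label is \code{"male"} iff the
#'   ratio is strictly below it.
#' @return A \code{\link{SexInference}}.
#' @export
inferSex <- function(track, level = NULL, decisionThreshold = 0.75) {
  stopifnot(is(track, "CoverageWindowTrack"))
  if (is.na(track@xName))
    stop("track has no X chromosome identified (xName)")
  w <- track@windows
  xw <- w[seqnames(w) == track@xName]
  if (length(xw) == 0L) stop("no windows on the X chromosome")
  if (is.null(level)) level <- genomeLevel(track)
  ratio <- median(mcols(xw)$median) / level
  new("SexInference", xRatio = ratio,
      label = if (ratio < decisionThreshold) "male" else "female",
      threshold = decisionThreshold)
}

## merge runs of consecutive marked windows into segments (GRanges)
.mergeMarked <- function(xw, marked) {
  if (!any(marked)) return(granges(xw)[0])
  r <- rle(marked)
  endIdx <- cumsum(r$lengths)
  startIdx <- endIdx - r$lengths + 1L
  keep <- r$values
  GRanges(seqnames(xw)[1],
          IRanges(start(xw)[startIdx[keep]], end(xw)[endIdx[keep]]))
}

#' Detect the pseudoautosomal region from X coverage
#'
#' Two-pass segment construction on the X chromosome.  Pass 1: windows
#' whose median depth reaches \code{threshold} times the genome level are
#' marked, and adjacent marked windows are merged into diploid-coverage
#' segments.  Pass 2: for each pair of consecutive segments the pooled
#' per-base median depth over the intervening gap is computed; if it also
#' reaches the threshold the pair is merged, and the pass repeats until a
#' fixed point (all qualifying gaps are closed simultaneously, so the
#' result does not depend on scan order).  The PAR is the resulting
#' segment that abuts an X terminus with length at least \code{minPar}
#' (the longer one if both termini qualify).  A segment spanning the
#' whole X (a female-like, fully diploid X) yields \code{par} absent with
#' \code{diploidX = TRUE}.
#'
#' @param track a \code{\link{CoverageWindowTrack}} containing X windows
#'   (other chromosomes are ignored).
#' @param depth the per-base depth of the X: an \code{RleList} containing
#'   the X, or a single vector/Rle; used for pass-2 gap medians.
#' @param level numeric(1), genome level; computed from the track's
#'   autosomes when omitted.
#' @param threshold numeric(1) in (0, 1], fraction of the genome level
#'   (default 0.70).
#' @param minPar numeric(1), minimum PAR length in bp (default 1e5),
#'   suppressing single-window noise segments.
#' @return A \code{\link{ParCall}}.
#' @examples
#' g <- makeGenome(1, 3e5, xLength = 2e5, parLength = 6e4, sex = "male")
#' cov <- simulateCoverage(g, simulationConfig(meanDepth = 30, seed = 5))
#' wt <- windowMedians(cov, window = 10000, xName = "chrX")
#' detectPar(wt, cov, minPar = 2e4)
#' @export
detectPar <- function(track, depth, level = NULL, threshold = 0.70,
                      minPar = 100000) {
  stopifnot(is(track, "CoverageWindowTrack"))
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  if (is.na(track@xName))
    stop("track has no X chromosome identified (xName)")
  xw <- track@windows[seqnames(track@windows) == track@xName]
  if (length(xw) == 0L) stop("no windows on the X chromosome")
  if (is.null(level)) level <- genomeLevel(track)
  dl <- .asDepthList(depth, chromName = track@xName)
  if (!track@xName %in% names(dl))
    stop("per-base depth for the X ('", track@xName, "') not supplied")
  xdepth <- dl[[track@xName]]
  xlen <- max(end(xw))
  cut <- threshold * level

  ## pass 1: threshold window medians, merge adjacent marked windows
  segs <- .mergeMarked(xw, mcols(xw)$median >= cut)

  ## pass 2: close gaps whose pooled per-base median reaches the cut;
  ## all qualifying gaps merge simultaneously, iterate to fixed point
  while (length(segs) > 1L) {
    gs <- end(segs)[-length(segs)] + 1L
    ge <- start(segs)[-1L] - 1L
    gapMed <- vapply(seq_along(gs), function(i)
      median(as.numeric(S4Vectors::window(xdepth, gs[i], ge[i]))), 0)
    closing <- gapMed >= cut
    if (!any(closing)) break
    keepStart <- c(TRUE, !closing)      # segment i+1 absorbed when closing[i]
    keepEnd <- c(!closing, TRUE)
    segs <- GRanges(track@xName,
                    IRanges(start(segs)[keepStart], end(segs)[keepEnd]))
  }

  diploidX <- length(segs) == 1L && start(segs) == 1L && end(segs) >= xlen
  par <- segs[0]
  if (!diploidX && length(segs)) {
    terminal <- (start(segs) == 1L | end(segs) >= xlen) &
      width(segs) >= minPar
    if (any(terminal)) {
      cand <- segs[terminal]
      par <- cand[which.max(width(cand))]
    }
  }
  new("ParCall", segments = segs, par = par, threshold = threshold,
      diploidX = diploidX)
}
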