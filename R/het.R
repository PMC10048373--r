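#' Count heterozygous SNPs in sliding windows
#'
#' Overlapping windows of \code{window} bp advanced by \code{step} bp
#' (defaults 1 Mbp / 100 kbp, i.e. each interior SNP contributes to ten
#' windows).  A window holds the number of heterozygous SNPs whose
#' position falls within it, scaled to SNPs per kbp of the window's
#' actual span: windows truncated at a chromosome end are scaled by their
#' real width rather than dropped, so chromosome-end densities (which
#' tend to run high) are not biased.  Only SNPs count; indels may pass
#' the quality filter but are excluded here.
#'
#' @param records \code{GRanges} of kept variant records with metadata
#'   columns \code{gt} and (optionally) \code{isSnp}.
#' @param chromLengths named numeric, chromosome lengths in bp (e.g.
#'   \code{chromLengths(genome)} or \code{\link{readFai}}).
#' @param window integer(1), window span in bp; must be a multiple of
#'   \code{step}.
#' @param step integer(1), step between window starts in bp.
#' @param xName character(1), X chromosome name carried into the track.
#' @return A \code{\link{HetTrack}}.
#' @examples
#' g <- makeGenome(1, 2e6, sex = "female")
#' v <- simulateVariants(g, simulationConfig(hetDensity = 0.6, seed = 8))
#' ht <- hetWindows(v, chromLengths(g))
#' head(trackWindows(ht))
#' @export
hetWindows <- function(records, chromLengths, window = 1000000L,
                       step = 100000L, xName = NA_character_) {
  stopifnot(is(records, "GRanges"))
  window <- as.integer(window); step <- as.integer(step)
  if (window %% step != 0L)
    stop("window must be a multiple of step")
  if (is.null(names(chromLengths)))
    stop("chromLengths must be named")
  het <- records[.isHet(records)]
  if (!is.null(mcols(het)$isSnp)) het <- het[mcols(het)$isSnp]
  si <- Seqinfo(names(chromLengths), unname(chromLengths))
  parts <- lapply(names(chromLengths), function(chrom) {
    len <- as.integer(chromLengths[[chrom]])
    ## one window per step while the start is inside the chromosome;
    ## a chromosome shorter than the step gets a single covering window
    starts <- seq.int(1L, max(1L, len), by = step)
    starts <- starts[starts <= len]
    ends <- pmin(starts + window - 1L, len)
    gr <- GRanges(chrom, IRanges(starts, ends), seqinfo = si)
    pos <- start(het[seqnames(het) == chrom])
    cnt <- vapply(seq_along(starts), function(i)
      sum(pos >= starts[i] & pos <= ends[i]), 0L)
    mcols(gr) <- DataFrame(count = cnt,
                           density = cnt / (width(gr) / 1000))
    gr
  })
  w <- do.call(c, parts)
  new("HetTrack", windows = w, window = window, step = step,
      xName = xName)
}

#' Summarize a heterozygosity track
#'
#' Minimum, median, mean and maximum of the window densities, plus the
#' histogram mode: densities are binned into bins of width
#' \code{modeBin} centered on multiples of \code{modeBin} (so a mode of
#' 0 is representable), and the mode is the center of the most populated
#' bin -- ties yield multiple modes.  When the zero bin is a local
#' maximum without being the global mode it is reported via
#' \code{zeroMode}: in males the hemizygous non-PAR X contributes a
#' secondary density mode at 0.
#'
#' @param track a \code{\link{HetTrack}}.
#' @param excludeX logical(1), drop X windows before summarizing.
#' @param modeBin numeric(1), histogram bin width in SNPs/kbp (default
#'   0.02, i.e. two-decimal modes).
#' @return A \code{\link{HetSummary}}.
#' @export
hetSummary <- function(track, excludeX = FALSE, modeBin = 0.02) {
  stopifnot(is(track, "HetTrack"))
  if (modeBin <= 0) stop("modeBin must be > 0")
  w <- track@windows
  if (excludeX) {
    if (is.na(track@xName))
      stop("excludeX = TRUE but the track has no xName")
    w <- w[seqnames(w) != track@xName]
  }
  if (length(w) == 0L) stop("empty heterozygosity track")
  d <- mcols(w)$density
  bin <- round(d / modeBin)
  counts <- table(bin)
  centers <- as.numeric(names(counts)) * modeBin
  modes <- centers[counts == max(counts)]
  zeroCount <- if ("0" %in% names(counts)) counts[["0"]] else 0L
  oneCount <- if ("1" %in% names(counts)) counts[["1"]] else 0L
  zeroMode <- zeroCount > 0L && zeroCount > oneCount && !(0 %in% modes)
  new("HetSummary", min = min(d), median = median(d), mean = mean(d),
      max = max(d), modes = modes, zeroMode = zeroMode,
      binWidth = modeBin, xExcluded = excludeX)
}
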