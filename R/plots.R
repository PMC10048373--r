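#' Heatmap of normalized window coverage per chromosome
#'
#' One horizontal band per chromosome, colored by the window median as a
#' fraction of the genome level (capped at \code{zmax}).  A male X shows
#' up as a half-level band with a full-level terminal PAR block.
#'
#' @param track a \code{\link{CoverageWindowTrack}}.
#' @param zmax numeric(1), color-scale cap (default 1.5).
#' @param ... passed to \code{graphics::image}.
#' @return invisibly, the matrix-free list of per-chromosome normalized
#'   levels that was drawn.
#' @export
plotCoverageHeatmap <- function(track, zmax = 1.5, ...) {
  stopifnot(is(track, "CoverageWindowTrack"))
  w <- track@windows
  lev <- if (is.na(track@genomeLevel)) genomeLevel(track)
         else track@genomeLevel
  norm <- mcols(w)$median / lev
  chroms <- unique(as.character(seqnames(w)))
  byc <- split(pmin(norm, zmax), as.character(seqnames(w)))[chroms]
  nmax <- max(lengths(byc))
  m <- matrix(NA_real_, nrow = nmax, ncol = length(chroms))
  for (i in seq_along(chroms)) m[seq_along(byc[[i]]), i] <- byc[[i]]
  graphics::image(x = seq_len(nmax) * track@windowSize / 1e6,
                  y = seq_along(chroms), z = m,
                  col = grDevices::hcl.colors(64, "viridis"),
                  zlim = c(0, zmax), xlab = "position (Mbp)", ylab = "",
                  yaxt = "n", ...)
  graphics::axis(2, at = seq_along(chroms), labels = chroms, las = 2)
  invisible(byc)
}

#' k-mer spectrum plot
#'
#' Distinct k-mer counts against multiplicity, with the detected trough
#' and coverage peak marked when a genome-size estimate is supplied.
#'
#' @param hist data.frame with \code{multiplicity} and \code{count}.
#' @param estimate optional result of \code{\link{genomeSizeFromKmers}}.
#' @param xmax x-axis limit (default 3x the peak or 60).
#' @param ... passed to \code{graphics::plot}.
#' @return invisibly \code{NULL}.
#' @export
plotKmerSpectrum <- function(hist, estimate = NULL, xmax = NULL, ...) {
  peak <- if (!is.null(estimate)) attr(estimate, "peak") else NULL
  if (is.null(xmax)) xmax <- if (!is.null(peak)) 3 * peak else 60
  sub <- hist[hist$multiplicity <= xmax, ]
  graphics::plot(sub$multiplicity, sub$count, type = "h", lwd = 2,
                 xlab = "multiplicity", ylab = "distinct k-mers", ...)
  if (!is.null(estimate)) {
    graphics::abline(v = attr(estimate, "trough"), lty = 2, col = "grey40")
    graphics::abline(v = peak, lty = 3, col = "red3")
    graphics::mtext(sprintf("G ~ %.2f Mbp", estimate / 1e6), side = 3,
                    adj = 1, cex = 0.8)
  }
  invisible(NULL)
}

#' Synteny dot plot with orientation bands
#'
#' For each reference chromosome, blocks are drawn in a top band when
#' their orientation matches the pair's dominant orientation and in a
#' bottom band when it is opposite, so inversions stand out as bottom-
#' band runs.
#'
#' @param set a \code{\link{SyntenyBlockSet}}.
#' @param corr a \code{\link{ChromosomeCorrespondence}} (for dominant
#'   orientations); computed on the fly when omitted.
#' @param refChrom optional single reference chromosome to draw.
#' @return invisibly \code{NULL}.
#' @export
plotSyntenyDotplot <- function(set, corr = NULL, refChrom = NULL) {
  stopifnot(is(set, "SyntenyBlockSet"))
  if (is.null(corr)) corr <- assignChromosomes(set, refXName = NA)
  b <- set@blocks
  if (!is.null(refChrom)) b <- b[b$refChrom == refChrom, , drop = FALSE]
  chroms <- unique(b$refChrom)
  graphics::plot(NULL, xlim = c(0, max(b$refEnd) / 1e6),
                 ylim = c(0.5, length(chroms) + 0.5),
                 xlab = "reference position (Mbp)", ylab = "", yaxt = "n")
  graphics::axis(2, at = seq_along(chroms), labels = chroms, las = 2)
  tb <- corr@table
  for (i in seq_along(chroms)) {
    sub <- b[b$refChrom == chroms[i], , drop = FALSE]
    dom <- tb$dominantOrientation[match(sub$queryChrom, tb$query)]
    same <- sub$orientation == dom
    y <- ifelse(same, i + 0.15, i - 0.15)
    graphics::segments(sub$refStart / 1e6, y, sub$refEnd / 1e6, y,
                       lwd = 3, col = ifelse(same, "steelblue", "red3"))
  }
  invisible(NULL)
}

#' Violin-style summary of heterozygosity densities
#'
#' Kernel-density "violin" of window densities per sample, mirroring the
#' usual per-individual heterozygosity comparison figure.
#'
#' @param tracks named list of \code{\link{HetTrack}} objects.
#' @param ... passed to \code{graphics::plot}.
#' @return invisibly \code{NULL}.
#' @export
plotHetViolin <- function(tracks, ...) {
  stopifnot(is.list(tracks), length(tracks) > 0)
  dens <- lapply(tracks, function(t) mcols(t@windows)$density)
  graphics::plot(NULL, xlim = c(0.5, length(dens) + 0.5),
                 ylim = range(unlist(dens)), xaxt = "n",
                 xlab = "", ylab = "SNPs/kbp", ...)
  graphics::axis(1, at = seq_along(dens), labels = names(dens), las = 2)
  for (i in seq_along(dens)) {
    d <- dens[[i]]
    if (length(unique(d)) > 1) {
      k <- stats::density(d, from = max(0, min(d)), to = max(d))
      w <- 0.4 * k$y / max(k$y)
      graphics::polygon(c(i - w, rev(i + w)), c(k$x, rev(k$x)),
                        col = "grey80", border = "grey40")
    }
    graphics::segments(i - 0.2, median(d), i + 0.2, median(d), lwd = 2)
  }
  invisible(NULL)
}
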