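#' Accessors for selkie S4 objects
#'
#' Small read-only accessors: chromosome names/lengths and the X name of a
#' \code{\link{GenomeModel}} or track; the PAR interval, its length and
#' the diploid segments of a \code{\link{ParCall}}; the ratio and label of
#' a \code{\link{SexInference}}; the window ranges of coverage and
#' heterozygosity tracks; the block table of a
#' \code{\link{SyntenyBlockSet}}; the assignment table of a
#' \code{\link{ChromosomeCorrespondence}}.
#'
#' @param x the object.
#' @return The slot value; see the class documentation for types.
#' @name accessors
#' @aliases NULL
NULL

#' @rdname accessors
#' @export
setMethod("chromNames", "GenomeModel", function(x) x@chromNames)

#' @rdname accessors
#' @export
setMethod("chromLengths", "GenomeModel",
          function(x) setNames(x@chromLengths, x@chromNames))

#' @rdname accessors
#' @export
setMethod("xName", "GenomeModel", function(x) x@xName)

#' @rdname accessors
#' @export
setMethod("xName", "CoverageWindowTrack", function(x) x@xName)

#' @rdname accessors
#' @export
setMethod("xName", "HetTrack", function(x) x@xName)

#' @rdname accessors
#' @export
setMethod("parRegion", "GenomeModel", function(x) x@par)

#' @rdname accessors
#' @export
setMethod("parRegion", "ParCall", function(x) x@par)

#' @rdname accessors
#' @export
setMethod("parLength", "ParCall",
          function(x) if (length(x@par)) sum(width(x@par)) else 0L)

#' @rdname accessors
#' @export
setMethod("parLength", "GenomeModel",
          function(x) if (length(x@par)) sum(width(x@par)) else 0L)

#' @rdname accessors
#' @export
setMethod("parSegments", "ParCall", function(x) x@segments)

#' @rdname accessors
#' @export
setMethod("sexLabel", "SexInference", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("sexLabel", "GenomeModel", function(x) x@sex)

#' @rdname accessors
#' @export
setMethod("xRatio", "SexInference", function(x) x@xRatio)

#' @rdname accessors
#' @export
setMethod("trackWindows", "CoverageWindowTrack", function(x) x@windows)

#' @rdname accessors
#' @export
setMethod("trackWindows", "HetTrack", function(x) x@windows)

#' @rdname accessors
#' @export
setMethod("blocks", "SyntenyBlockSet", function(x) x@blocks)

#' @rdname accessors
#' @export
setMethod("correspondenceTable", "ChromosomeCorrespondence",
          function(x) x@table)

#' @describeIn normalizedLevels window medians divided by the genome
#'   level (computed on the fly from autosomes when not yet recorded).
#' @export
setMethod("normalizedLevels", "CoverageWindowTrack", function(x) {
  lev <- if (is.na(x@genomeLevel)) genomeLevel(x) else x@genomeLevel
  mcols(x@windows)$median / lev
})

setMethod("show", "GenomeModel", function(object) {
  cat(sprintf("GenomeModel: %d chromosome(s), %s\n",
              length(object@chromNames), object@sex))
  cat(sprintf("  total length: %.3f Mbp\n", sum(object@chromLengths) / 1e6))
  if (!is.na(object@xName)) {
    cat(sprintf("  X: %s (%.3f Mbp)", object@xName,
                object@chromLengths[match(object@xName, object@chromNames)] / 1e6))
    if (length(object@par))
      cat(sprintf(", PAR %d-%d (%.3f Mbp)", start(object@par),
                  end(object@par), width(object@par) / 1e6))
    cat("\n")
  }
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: depth %.1fx (dispersion %.2f), ",
                     "error rate %.3f, k = %d, seed %d\n"),
              object@meanDepth, object@depthDispersion, object@errorRate,
              object@k, object@seed))
  dens <- paste(sprintf("%s=%.3g", names(object@hetDensity),
                        object@hetDensity), collapse = ", ")
  cat("  het density (SNPs/kbp):", dens, "\n")
})

setMethod("show", "CoverageWindowTrack", function(object) {
  cat(sprintf("CoverageWindowTrack: %d windows of %d bp on %d chromosome(s)\n",
              length(object@windows), object@windowSize,
              length(unique(seqnames(object@windows)))))
  if (!is.na(object@genomeLevel))
    cat(sprintf("  genome level: %.2f\n", object@genomeLevel))
})

setMethod("show", "ParCall", function(object) {
  cat(sprintf("ParCall: %d diploid segment(s), threshold %.2f\n",
              length(object@segments), object@threshold))
  if (object@diploidX)
    cat("  diploid X, PAR not resolvable\n")
  else if (length(object@par))
    cat(sprintf("  PAR: %s:%d-%d (%.3f Mbp)\n",
                as.character(seqnames(object@par)), start(object@par),
                end(object@par), width(object@par) / 1e6))
  else cat("  PAR: absent\n")
})

setMethod("show", "SexInference", function(object) {
  cat(sprintf("SexInference: %s (X:autosome ratio %.3f, threshold %.2f)\n",
              object@label, object@xRatio, object@threshold))
})

setMethod("show", "FilterConfig", function(object) {
  cat(sprintf(paste0("FilterConfig: QUAL < %.1f || (SP > %.1f | DP < %.1f",
                     " | GQ < %.1f); depth band %.0f%%-%.0f%% of mean\n"),
              object@minQual, object@maxSp, object@minDp, object@minGq,
              100 * object@covBand[1], 100 * object@covBand[2]))
})

setMethod("show", "HetTrack", function(object) {
  cat(sprintf(paste0("HetTrack: %d sliding windows (%.1f kbp span, ",
                     "%.0f kbp step) on %d chromosome(s)\n"),
              length(object@windows), object@window / 1e3,
              object@step / 1e3, length(unique(seqnames(object@windows)))))
})

setMethod("show", "HetSummary", function(object) {
  cat(sprintf(paste0("HetSummary (SNPs/kbp%s): min %.2f, median %.2f, ",
                     "mean %.2f, mode %s, max %.2f\n"),
              if (object@xExcluded) ", X excluded" else "",
              object@min, object@median, object@mean,
              paste(sprintf("%.2f", object@modes), collapse = "/"),
              object@max))
  if (object@zeroMode)
    cat("  additional mode at 0 (hemizygous-region signature)\n")
})

setMethod("show", "SyntenyBlockSet", function(object) {
  cat(sprintf(paste0("SyntenyBlockSet: %d blocks, %d reference ",
                     "chromosome(s), %d query scaffold(s)\n"),
              nrow(object@blocks), length(object@refLengths),
              length(object@queryLengths)))
})

setMethod("show", "ChromosomeCorrespondence", function(object) {
  cat(sprintf("ChromosomeCorrespondence: %d query scaffold(s)\n",
              nrow(object@table)))
  print(utils::head(object@table, 8))
  if (nrow(object@table) > 8) cat("  ...\n")
})

setMethod("show", "ScaffoldStats", function(object) {
  cat(sprintf(paste0("ScaffoldStats: %d scaffolds, total %.3f Mbp, ",
                     "N50 %.3f Mbp, L50 %d\n"),
              object@nScaffolds, object@totalLength / 1e6,
              object@n50 / 1e6, object@l50))
})

setMethod("show", "CScaffoldCutoff", function(object) {
  cat(sprintf(paste0("CScaffoldCutoff: rank %d, %.1f-fold gap ",
                     "(~%.0f-fold); chromosome-scale: %s\n"),
              object@k, object@foldGap, object@foldGapRounded,
              object@isChromosomeScale))
})
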