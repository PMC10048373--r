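#' Standardize reads to a fixed length and target coverage
#'
#' Harmonizes sequencing libraries across samples by cutting every read
#' down to \code{targetLen} bp (reads already shorter are dropped, never
#' padded) and then downsampling, uniformly at random without
#' replacement, to \code{targetCov} fold coverage of \code{genomeSize}.
#' Cutting keeps the 5' end of each read; qualities are cut alongside.
#'
#' @param reads a FASTQ file path, or a \code{DNAStringSet} whose
#'   \code{mcols()$qualities} holds per-read qualities (as returned by
#'   \code{Biostrings::readDNAStringSet(..., format = "fastq",
#'   with.qualities = TRUE)}).
#' @param targetLen integer(1), output read length in bp (default 100).
#' @param targetCov numeric(1), output coverage in fold (default 20).
#' @param genomeSize numeric(1), genome size in bp used to translate
#'   coverage into a base budget.
#' @param seed integer(1), seed for the subsampling.
#' @param out optional FASTQ path; when given, the result is also written
#'   there.
#' @return A \code{DNAStringSet} of reads of length \code{targetLen}
#'   totalling approximately \code{targetCov * genomeSize} bases, in input
#'   order.  Errors if the post-cut library cannot reach \code{targetCov},
#'   naming the achievable coverage.
#' @export
standardizeReads <- function(reads, targetLen = 100L, targetCov = 20,
                             genomeSize, seed = 1L, out = NULL) {
  if (is.character(reads))
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq",
                                          with.qualities = TRUE)
  stopifnot(is(reads, "DNAStringSet"))
  if (genomeSize <= 0) stop("genomeSize must be positive")
  quals <- mcols(reads)$qualities
  keep <- width(reads) >= targetLen
  reads <- reads[keep]
  if (!is.null(quals)) quals <- quals[keep]
  reads <- Biostrings::subseq(reads, 1L, targetLen)
  if (!is.null(quals)) quals <- Biostrings::subseq(quals, 1L, targetLen)
  needed <- round(targetCov * genomeSize / targetLen)
  if (length(reads) < needed) {
    achievable <- length(reads) * targetLen / genomeSize
    stop(sprintf(paste0("cannot reach %.3gx coverage: only %.3gx ",
                        "available after cutting to %d bp"),
                 targetCov, achievable, targetLen))
  }
  idx <- .withSeed(seed, sort(sample.int(length(reads), needed)))
  reads <- reads[idx]
  if (!is.null(quals)) {
    quals <- quals[idx]
    mcols(reads)$qualities <- quals
  }
  if (!is.null(out))
    Biostrings::writeXStringSet(reads, out, format = "fastq",
                                qualities = mcols(reads)$qualities)
  reads
}
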