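## File-format boundary.  Everything on disk is plain text: bedGraph and
## BED through rtracklayer (0-based half-open handled there), VCF 4.x
## through VariantAnnotation, TSV through read/write.table.

#' Read and write per-base depth tracks as bedGraph
#'
#' \code{writeDepthBedgraph} run-length-collapses the per-base track;
#' \code{readDepthBedgraph} expands a bedGraph into per-base depth,
#' filling positions absent from the file with depth 0 (as required for
#' windowed medians over sparse tracks).
#'
#' @param depth named \code{RleList} (or list of per-base vectors).
#' @param file path to a bedGraph file.
#' @param chromLengths named numeric; chromosome lengths for the read
#'   track (e.g. from \code{\link{readFai}}).  Defaults to the last
#'   covered position per chromosome.
#' @return \code{readDepthBedgraph}: a named \code{RleList};
#'   \code{writeDepthBedgraph}: the file path, invisibly.
#' @export
writeDepthBedgraph <- function(depth, file) {
  dl <- .asDepthList(depth)
  si <- Seqinfo(names(dl), vapply(dl, length, 0))
  gr <- do.call(c, lapply(names(dl), function(chrom) {
    r <- dl[[chrom]]
    ends <- cumsum(runLength(r))
    starts <- ends - runLength(r) + 1L
    g <- GRanges(chrom, IRanges(starts, ends), seqinfo = si)
    mcols(g)$score <- as.numeric(runValue(r))
    g
  }))
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}

#' @rdname writeDepthBedgraph
#' @export
readDepthBedgraph <- function(file, chromLengths = NULL) {
  gr <- rtracklayer::import(file, format = "bedGraph")
  if (is.null(chromLengths)) {
    chromLengths <- vapply(split(end(gr), as.character(seqnames(gr))),
                           max, 0)
  }
  out <- lapply(names(chromLengths), function(chrom) {
    sub <- gr[seqnames(gr) == chrom]
    IRanges::coverage(ranges(sub), weight = mcols(sub)$score,
                      width = chromLengths[[chrom]])
  })
  names(out) <- names(chromLengths)
  RleList(out, compress = FALSE)
}

#' Read a FASTA index (fai) or two-column length table
#'
#' @param file path to a samtools \code{.fai} file (name and length in
#'   the first two columns) or any two-column name/length TSV.
#' @return named numeric of sequence lengths.
#' @export
readFai <- function(file) {
  tb <- read.table(file, sep = "\t", stringsAsFactors = FALSE)
  setNames(as.numeric(tb[[2]]), tb[[1]])
}

#' Read and write k-mer multiplicity histograms
#'
#' Two-column (multiplicity, count) whitespace-separated text, compatible
#' with \code{jellyfish histo} output.
#'
#' @param hist data.frame with columns \code{multiplicity}, \code{count}.
#' @param file path.
#' @return \code{readKmerHistogram}: the data.frame;
#'   \code{writeKmerHistogram}: the path, invisibly.
#' @export
writeKmerHistogram <- function(hist, file) {
  stopifnot(all(c("multiplicity", "count") %in% names(hist)))
  write.table(hist[, c("multiplicity", "count")], file, sep = " ",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writeKmerHistogram
#' @export
readKmerHistogram <- function(file) {
  tb <- read.table(file, stringsAsFactors = FALSE)
  data.frame(multiplicity = as.integer(tb[[1]]), count = as.numeric(tb[[2]]))
}

#' Read and write synteny block tables
#'
#' Tab-separated block tables with header columns \code{ref_chrom},
#' \code{ref_start}, \code{ref_end}, \code{query_chrom},
#' \code{query_start}, \code{query_end}, \code{orientation}.  On disk the
#' coordinates are 0-based half-open (PSL/BED-like); in memory they are
#' 1-based closed.
#'
#' @param set a \code{\link{SyntenyBlockSet}}.
#' @param file path.
#' @param refLengths,queryLengths named numeric scaffold length tables
#'   (e.g. from \code{\link{readFai}}).
#' @return \code{readSyntenyBlocks}: a \code{\link{SyntenyBlockSet}};
#'   \code{writeSyntenyBlocks}: the path, invisibly.
#' @export
writeSyntenyBlocks <- function(set, file) {
  stopifnot(is(set, "SyntenyBlockSet"))
  b <- set@blocks
  out <- data.frame(ref_chrom = b$refChrom, ref_start = b$refStart - 1L,
                    ref_end = b$refEnd, query_chrom = b$queryChrom,
                    query_start = b$queryStart - 1L,
                    query_end = b$queryEnd, orientation = b$orientation)
  write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writeSyntenyBlocks
#' @export
readSyntenyBlocks <- function(file, refLengths, queryLengths) {
  tb <- read.table(file, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  b <- data.frame(refChrom = tb$ref_chrom,
                  refStart = as.numeric(tb$ref_start) + 1,
                  refEnd = as.numeric(tb$ref_end),
                  queryChrom = tb$query_chrom,
                  queryStart = as.numeric(tb$query_start) + 1,
                  queryEnd = as.numeric(tb$query_end),
                  orientation = tb$orientation,
                  stringsAsFactors = FALSE)
  b <- b[order(b$refChrom, b$refStart), , drop = FALSE]
  rownames(b) <- NULL
  new("SyntenyBlockSet", blocks = b, refLengths = refLengths,
      queryLengths = queryLengths)
}

.GT_CODE <- c("hom-ref" = "0/0", "het" = "0/1", "hom-alt" = "1/1",
              "missing" = "./.")

#' Write variant records as VCF 4.2
#'
#' Serializes a record set (as produced by \code{\link{simulateVariants}}
#' or filtered downstream) as a single-sample VCF with FORMAT fields GT,
#' DP, GQ and SP.
#'
#' @param records \code{GRanges} with metadata columns \code{ref},
#'   \code{alt}, \code{qual}, \code{dp}, \code{gq}, \code{sp}, \code{gt}.
#' @param file output path (plain or .gz/.bgz).
#' @param sampleName sample column name.
#' @return The path written by \code{VariantAnnotation::writeVcf},
#'   invisibly.
#' @export
writeVariantsVcf <- function(records, file, sampleName = "sample") {
  stopifnot(is(records, "GRanges"))
  n <- length(records)
  mc <- mcols(records)
  rr <- granges(records)
  names(rr) <- paste0("v", seq_len(n))
  fixed <- DataFrame(
    REF = Biostrings::DNAStringSet(if (n) mc$ref else character()),
    ALT = Biostrings::DNAStringSetList(as.list(if (n) mc$alt
                                               else character())),
    QUAL = as.numeric(mc$qual),
    FILTER = rep("PASS", n))
  gtStr <- ifelse(mc$gt %in% names(.GT_CODE), .GT_CODE[mc$gt], mc$gt)
  geno <- S4Vectors::SimpleList(
    GT = matrix(gtStr, ncol = 1, dimnames = list(names(rr), sampleName)),
    DP = matrix(as.integer(mc$dp), ncol = 1,
                dimnames = list(names(rr), sampleName)),
    GQ = matrix(as.integer(round(mc$gq)), ncol = 1,
                dimnames = list(names(rr), sampleName)),
    SP = matrix(as.integer(round(mc$sp)), ncol = 1,
                dimnames = list(names(rr), sampleName)))
  hdr <- VariantAnnotation::VCFHeader(
    samples = sampleName,
    header = IRanges::DataFrameList(
      fileformat = DataFrame(Value = "VCFv4.2",
                             row.names = "fileformat"),
      FORMAT = DataFrame(
        Number = c("1", "1", "1", "1"),
        Type = c("String", "Integer", "Integer", "Integer"),
        Description = c("Genotype", "Read depth",
                        "Genotype quality",
                        "Phred-scaled strand bias P-value"),
        row.names = c("GT", "DP", "GQ", "SP"))))
  vcf <- VariantAnnotation::VCF(rowRanges = rr, fixed = fixed,
                                colData = DataFrame(Samples = 1L,
                                  row.names = sampleName),
                                exptData = list(header = hdr),
                                geno = geno, collapsed = TRUE)
  invisible(VariantAnnotation::writeVcf(vcf, file))
}

#' Read a VCF into the package's record representation
#'
#' Loads a (single-sample) VCF and extracts, for the first sample, the
#' fields the filter chain consumes: QUAL and FORMAT/DP, GQ, SP, plus the
#' genotype classified into hom-ref / het / hom-alt / missing and a SNP
#' flag (1 bp REF and ALT).
#'
#' @param file VCF path (plain or bgzipped).
#' @param genome genome identifier passed to
#'   \code{VariantAnnotation::readVcf}.
#' @return \code{GRanges} with metadata columns \code{ref}, \code{alt},
#'   \code{qual}, \code{dp}, \code{gq}, \code{sp}, \code{gt},
#'   \code{isSnp}.
#' @export
readVariantsVcf <- function(file, genome = "unknown") {
  vcf <- VariantAnnotation::readVcf(file, genome = genome)
  gr <- granges(SummarizedExperiment::rowRanges(vcf))
  mcols(gr) <- NULL
  ref <- as.character(VariantAnnotation::ref(vcf))
  altList <- VariantAnnotation::alt(vcf)
  alt <- vapply(seq_along(altList), function(i) {
    a <- as.character(altList[[i]])
    if (length(a)) a[1L] else NA_character_
  }, "")
  gn <- VariantAnnotation::geno(vcf)
  pick <- function(field, default = NA_real_) {
    if (field %in% names(gn)) as.numeric(gn[[field]][, 1L])
    else rep(default, length(gr))
  }
  gtRaw <- if ("GT" %in% names(gn)) as.character(gn$GT[, 1L])
           else rep(".", length(gr))
  alleles <- strsplit(gsub("\\|", "/", gtRaw), "/", fixed = FALSE)
  gt <- vapply(alleles, function(a) {
    if (any(a == ".") || length(a) < 2L) "missing"
    else if (a[1L] != a[2L]) "het"
    else if (all(a == "0")) "hom-ref"
    else "hom-alt"
  }, "")
  mcols(gr) <- DataFrame(
    ref = ref, alt = alt,
    qual = as.numeric(VariantAnnotation::qual(vcf)),
    dp = pick("DP"), gq = pick("GQ"), sp = pick("SP"),
    gt = gt, isSnp = nchar(ref) == 1L & !is.na(alt) & nchar(alt) == 1L)
  names(gr) <- NULL
  gr
}

#' Write a PAR call as BED
#'
#' Writes the diploid-coverage segments, with the designated PAR (if
#' any) named \code{"PAR"} and the remaining segments \code{"segment"}.
#'
#' @param x a \code{\link{ParCall}}.
#' @param file BED path.
#' @return the path, invisibly.
#' @export
writeParBed <- function(x, file) {
  stopifnot(is(x, "ParCall"))
  segs <- x@segments
  nm <- rep("segment", length(segs))
  if (length(x@par))
    nm[start(segs) == start(x@par) & end(segs) == end(x@par)] <- "PAR"
  mcols(segs)$name <- nm
  rtracklayer::export(segs, file, format = "BED")
  invisible(file)
}

#' Write a coverage-based sex and PAR summary as JSON
#'
#' @param sex a \code{\link{SexInference}}.
#' @param par a \code{\link{ParCall}} (optional).
#' @param level numeric(1), the genome level used.
#' @param file JSON path.
#' @return the path, invisibly.
#' @export
writeSexJson <- function(sex, par = NULL, level = NA_real_, file) {
  stopifnot(is(sex, "SexInference"))
  out <- list(x_ratio = sex@xRatio, label = sex@label,
              decision_threshold = sex@threshold, genome_level = level)
  if (!is.null(par)) {
    out$par_length <- parLength(par)
    out$par_threshold <- par@threshold
    out$diploid_x <- par@diploidX
  }
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write a heterozygosity track as BED-like TSV
#'
#' Columns: chrom, start (0-based), end, count, density (SNPs/kbp).
#'
#' @param track a \code{\link{HetTrack}}.
#' @param file path.
#' @return the path, invisibly.
#' @export
writeHetTrack <- function(track, file) {
  stopifnot(is(track, "HetTrack"))
  w <- track@windows
  out <- data.frame(chrom = as.character(seqnames(w)),
                    start = start(w) - 1L, end = end(w),
                    count = mcols(w)$count, density = mcols(w)$density)
  write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a chromosome correspondence table or inversion calls as TSV
#'
#' @param x a \code{\link{ChromosomeCorrespondence}} or an inversion call
#'   table from \code{\link{callInversions}} /
#'   \code{\link{sharedInversions}}.
#' @param file path.
#' @return the path, invisibly.
#' @export
writeSyntenyTsv <- function(x, file) {
  tb <- if (is(x, "ChromosomeCorrespondence")) x@table else x
  write.table(tb, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
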