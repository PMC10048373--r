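test_that("genome model construction places the PAR and validates input", {
  g <- makeGenome(2, c(10e6, 8e6), xLength = 6e6, parLength = 1e6,
                  sex = "male")
  expect_identical(chromNames(g), c("aut1", "aut2", "chrX"))
  expect_equal(unname(chromLengths(g)), c(10e6, 8e6, 6e6))
  par <- parRegion(g)
  expect_equal(start(par), 1)
  expect_equal(end(par), 1e6)
  expect_identical(as.character(seqnames(par)), "chrX")

  ## degenerate: no PAR at all
  g0 <- makeGenome(1, 1e6, xLength = 5e5, parLength = 0, sex = "male")
  expect_length(parRegion(g0), 0)

  ## PAR can abut the other terminus
  ge <- makeGenome(1, 1e6, xLength = 5e5, parLength = 1e5, sex = "male",
                   parAt = "end")
  expect_equal(start(parRegion(ge)), 4e5 + 1)
  expect_equal(end(parRegion(ge)), 5e5)

  ## identical inputs give identical models
  expect_identical(makeGenome(2, c(1e6, 2e6), 5e5, 1e5, "female"),
                   makeGenome(2, c(1e6, 2e6), 5e5, 1e5, "female"))

  expect_error(makeGenome(1, 1e6, xLength = 5e5, parLength = 5e5,
                          sex = "male"), "smaller")
  expect_error(makeGenome(1, 1e6, xLength = 0, parLength = 1e5,
                          sex = "male"), "requires an X")
})

test_that("simulated coverage has diploid autosomes and a hemizygous male X", {
  g <- maleGenome(parLength = 4e5, xLength = 2e6)
  cfg <- simulationConfig(meanDepth = 30, depthDispersion = 1, seed = 101)
  cov <- simulateCoverage(g, cfg)
  expect_named(cov, c("aut1", "aut2", "chrX"))
  expect_equal(lengths(cov), setNames(c(3e6, 2e6, 2e6),
                                      c("aut1", "aut2", "chrX")))

  ## Poisson mean check: window means within 3 standard errors
  npx <- as.numeric(cov[["chrX"]])[(4e5 + 1):2e6]   # non-PAR X
  se <- sqrt(15 / length(npx))
  expect_lt(abs(mean(npx) - 15), 3 * se)
  aut <- as.numeric(cov[["aut1"]])
  expect_lt(abs(mean(aut) - 30), 3 * sqrt(30 / length(aut)))
  par <- as.numeric(cov[["chrX"]])[1:4e5]
  expect_lt(abs(mean(par) - 30), 3 * sqrt(30 / length(par)))

  ## Poisson variance: var ~ mean at dispersion 1
  expect_lt(abs(var(aut) - 30), 0.5)

  ## over-dispersed model inflates the variance
  covNb <- simulateCoverage(g, simulationConfig(meanDepth = 30,
                                                depthDispersion = 3,
                                                seed = 101))
  expect_gt(var(as.numeric(covNb[["aut1"]])), 60)

  ## female X is indistinguishable from autosomes
  gf <- femaleGenome()
  covF <- simulateCoverage(gf, cfg)
  expect_lt(abs(mean(as.numeric(covF[["chrX"]])) - 30),
            3 * sqrt(30 / 2e6))

  ## byte-identical reproducibility
  expect_identical(cov, simulateCoverage(g, cfg))
})

test_that("simulated variants match planted densities and male X hemizygosity", {
  g <- makeGenome(1, 10e6, sex = "female")
  cfg <- simulationConfig(hetDensity = 0.6, seed = 7)
  v <- simulateVariants(g, cfg)
  ## Poisson count check: 6000 expected, 3 sd slack
  expect_lt(abs(length(v) - 6000), 3 * sqrt(6000))
  expect_true(all(c("qual", "dp", "gq", "sp", "gt", "isSnp") %in%
                  names(mcols(v))))
  expect_true(all(mcols(v)$gt == "het"))
  expect_true(all(mcols(v)$ref != mcols(v)$alt))

  ## zero density -> empty record set
  v0 <- simulateVariants(g, simulationConfig(hetDensity = 0, seed = 7))
  expect_length(v0, 0)

  ## male: X emits hets only inside the PAR
  gm <- maleGenome(parLength = 4e5, xLength = 2e6)
  vm <- simulateVariants(gm, simulationConfig(hetDensity = 0.6, seed = 8))
  xv <- vm[seqnames(vm) == "chrX"]
  expect_gt(length(xv), 0)
  expect_true(all(end(xv) <= 4e5))

  ## determinism
  expect_identical(vm, simulateVariants(gm, simulationConfig(
    hetDensity = 0.6, seed = 8)))
})

test_that("variant counts are Poisson-consistent with the planted density", {
  ## goodness of fit of per-seed counts against Poisson(density * span)
  g <- makeGenome(1, 2e6, sex = "female")
  lambda <- 0.6 * 2e6 / 1000
  counts <- vapply(1:20, function(s)
    length(simulateVariants(g, simulationConfig(hetDensity = 0.6,
                                                seed = s))), 0L)
  stat <- sum((counts - lambda)^2 / lambda)   # ~ chi-square, 20 df
  expect_gt(pchisq(stat, df = 20, lower.tail = FALSE), 0.01)
})

test_that("synteny simulation plants inversions and follows permutations", {
  g <- makeGenome(2, c(5e6, 4e6), sex = "female")
  inv <- GRanges("aut1", IRanges(1e6, 3e6))
  sb <- simulateSynteny(g, inv, meanBlockLen = 2e5, seed = 5)
  b <- blocks(sb)
  mid <- (b$refStart + b$refEnd) / 2
  inside <- b$refChrom == "aut1" & mid >= 1e6 & mid <= 3e6
  expect_true(all(b$orientation[inside] == "-"))
  expect_true(all(b$orientation[!inside] == "+"))
  expect_true(all(b$queryStart <= b$queryEnd))

  ## identity: same names, all plus
  sbI <- simulateSynteny(g, meanBlockLen = 2e5, seed = 5)
  expect_true(all(blocks(sbI)$orientation == "+"))
  expect_identical(blocks(sbI)$refChrom, blocks(sbI)$queryChrom)

  ## permutation relabels query scaffolds
  perm <- c(aut1 = "s2", aut2 = "s1")
  sbP <- simulateSynteny(g, scaffoldPermutation = perm,
                         meanBlockLen = 2e5, seed = 5)
  bp <- blocks(sbP)
  expect_true(all(bp$queryChrom[bp$refChrom == "aut1"] == "s2"))
  expect_true(all(bp$queryChrom[bp$refChrom == "aut2"] == "s1"))

  ## overlapping planted inversions are rejected
  bad <- GRanges("aut1", IRanges(c(1e6, 2e6), c(2.5e6, 3e6)))
  expect_error(simulateSynteny(g, bad), "overlap")
})

test_that("k-mer histograms conserve mass and show an error peak", {
  cfg <- simulationConfig(meanDepth = 20, errorRate = 0, seed = 3)
  h <- simulateKmerHistogram(1e6, cfg)
  mass <- sum(h$multiplicity * h$count)
  expect_lt(abs(mass - 2e7) / 2e7, 0.01)   # ~ genomeSize * depth

  ## heavy error rate: multiplicity-1 bin becomes a visible second peak
  hE <- simulateKmerHistogram(1e6, simulationConfig(meanDepth = 20,
                                                    errorRate = 0.5,
                                                    seed = 3))
  expect_gt(hE$count[1], hE$count[2])
  expect_gt(hE$count[1], max(hE$count[5:10]))

  ## determinism
  expect_identical(h, simulateKmerHistogram(1e6, cfg))
  expect_error(simulationConfig(errorRate = 1), "errorRate")
})

test_that("read standardization cuts to length and downsamples to coverage", {
  genomeSize <- 1e5
  mkReads <- function(n, len) {
    s <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), "")
    r <- Biostrings::DNAStringSet(s)
    names(r) <- paste0("r", seq_len(n))
    S4Vectors::mcols(r)$qualities <-
      Biostrings::BStringSet(rep(strrep("I", len), n))
    r
  }
  ## 150 bp at 40x over 0.1 Mb -> 20,000 output reads of 100 bp (2 Mb)
  set.seed(42)
  reads <- mkReads(ceiling(40 * genomeSize / 150), 150)
  out <- standardizeReads(reads, targetLen = 100, targetCov = 20,
                          genomeSize = genomeSize, seed = 1)
  expect_true(all(width(out) == 100))
  expect_equal(length(out), 20 * genomeSize / 100)

  ## fixed point: already 100 bp at exactly 20x
  reads100 <- mkReads(20 * genomeSize / 100, 100)
  out2 <- standardizeReads(reads100, targetLen = 100, targetCov = 20,
                           genomeSize = genomeSize, seed = 1)
  expect_setequal(names(out2), names(reads100))

  ## short reads are dropped, never padded
  mixed <- c(mkReads(50, 80), mkReads(50, 120))
  outM <- standardizeReads(mixed, targetLen = 100, targetCov = 0.01,
                           genomeSize = genomeSize, seed = 1)
  expect_true(all(width(outM) == 100))
  expect_true(all(grepl("^r", names(outM))))

  ## infeasible target coverage errors with the achievable value
  few <- mkReads(100, 150)   # 10,000 usable bases -> 0.1x
  expect_error(standardizeReads(few, targetLen = 100, targetCov = 20,
                                genomeSize = genomeSize, seed = 1),
               "0.1x")

  ## FASTQ round trip preserves sequences
  fq <- tempfile(fileext = ".fastq")
  standardizeReads(reads, targetLen = 100, targetCov = 20,
                   genomeSize = genomeSize, seed = 1, out = fq)
  back <- Biostrings::readDNAStringSet(fq, format = "fastq")
  expect_equal(length(back), length(out))
  expect_identical(as.character(back[[1]]), as.character(out[[1]]))
})
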