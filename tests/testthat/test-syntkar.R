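## hand-build a block set without the simulator
mkBlockSet <- function(df, refLengths, queryLengths) {
  df <- df[order(df$refChrom, df$refStart), , drop = FALSE]
  rownames(df) <- NULL
  new("SyntenyBlockSet", blocks = df, refLengths = refLengths,
      queryLengths = queryLengths)
}

test_that("block filtering keeps spans at or above the inclusive minimum", {
  df <- data.frame(refChrom = "c1",
                   refStart = c(1, 100001, 300001),
                   refEnd = c(1 + 49999 - 1, 100001 + 50000 - 1,
                              300001 + 50001 - 1),
                   queryChrom = "c1", queryStart = c(1, 100001, 300001),
                   queryEnd = c(49999, 150000, 350001),
                   orientation = "+", stringsAsFactors = FALSE)
  sb <- mkBlockSet(df, c(c1 = 1e6), c(c1 = 1e6))
  fb <- filterBlocks(sb, 50000)
  spans <- blocks(fb)$refEnd - blocks(fb)$refStart + 1
  expect_equal(spans, c(50000, 50001))
  expect_equal(attr(blocks(fb), "nRemoved"), 1)

  ## empty set in, empty set out
  empty <- mkBlockSet(df[0, ], c(c1 = 1e6), c(c1 = 1e6))
  expect_equal(nrow(blocks(filterBlocks(empty))), 0)

  ## random set: survivors equal a per-block scan
  g <- makeGenome(2, c(3e6, 2e6), sex = "female")
  sb2 <- simulateSynteny(g, meanBlockLen = 8e4, seed = 17)
  fb2 <- filterBlocks(sb2, 50000)
  keep <- with(blocks(sb2), refEnd - refStart + 1 >= 50000)
  expect_equal(nrow(blocks(fb2)), sum(keep))
})

test_that("chromosome assignment recovers identity and planted permutations", {
  g <- makeGenome(3, c(5e6, 4e6, 3e6), xLength = 2e6, parLength = 0,
                  sex = "female")
  sbI <- simulateSynteny(g, meanBlockLen = 2e5, seed = 19)
  corrI <- assignChromosomes(filterBlocks(sbI))
  tbI <- correspondenceTable(corrI)
  expect_identical(tbI$ref, tbI$query)            # identity mapping
  expect_true(all(tbI$coverageFraction > 0.95))
  expect_true(all(tbI$dominantOrientation == "+"))
  ## conservation naming: X by name, autosomes ranked by query length
  expect_identical(tbI$assignedName[match("chrX", tbI$query)], "chrX")
  expect_identical(tbI$assignedName[match("aut1", tbI$query)], "aut1")

  ## two swapped scaffolds: mapping recovers the permutation and the
  ## aut numbering follows query scaffold lengths
  perm <- c(aut1 = "s_b", aut2 = "s_a", aut3 = "s_c", chrX = "s_x")
  sbP <- simulateSynteny(g, scaffoldPermutation = perm,
                         meanBlockLen = 2e5, seed = 19)
  corrP <- assignChromosomes(filterBlocks(sbP))
  tbP <- correspondenceTable(corrP)
  expect_identical(tbP$ref[match("s_b", tbP$query)], "aut1")
  expect_identical(tbP$ref[match("s_a", tbP$query)], "aut2")
  expect_identical(tbP$assignedName[match("s_x", tbP$query)], "chrX")
  ## s_b carries aut1 (5 Mb) so it is the longest query scaffold
  expect_identical(tbP$assignedName[match("s_b", tbP$query)], "aut1")
  expect_identical(tbP$assignedName[match("s_a", tbP$query)], "aut2")

  ## an explicit painting map overrides the length-ranked naming
  fish <- c(s_b = 2, s_a = 1, s_c = 3, s_x = "X")
  corrF <- assignChromosomes(filterBlocks(sbP), fishMap = fish)
  tbF <- correspondenceTable(corrF)
  expect_identical(tbF$assignedName[match("s_b", tbF$query)], "chr2")
  expect_identical(tbF$assignedName[match("s_x", tbF$query)], "chrX")

  ## a scaffold with no aligned bp is reported unassigned
  sbU <- sbP
  sbU@queryLengths <- c(sbP@queryLengths, orphan = 1e6)
  corrU <- assignChromosomes(filterBlocks(sbU))
  tbU <- correspondenceTable(corrU)
  expect_true(is.na(tbU$ref[match("orphan", tbU$query)]))
  expect_equal(tbU$alignedBp[match("orphan", tbU$query)], 0)
})

test_that("whole-scaffold inversions are flagged by aligned-bp majority", {
  g <- makeGenome(2, c(5e6, 4e6), sex = "female")
  ## aut1 fully reverse-complemented, aut2 untouched
  inv <- GRanges("aut1", IRanges(1, 5e6))
  sb <- simulateSynteny(g, inv, meanBlockLen = 2e5, seed = 23)
  corr <- assignChromosomes(filterBlocks(sb))
  so <- scaffoldOrientation(corr)
  expect_true(so$inverted[so$query == "aut1"])
  expect_false(so$inverted[so$query == "aut2"])

  ## a single internal 4 Mb inversion on a 100 Mb chromosome: dominant
  ## orientation stays +, scaffold is not flagged
  g2 <- makeGenome(1, 100e6, sex = "female")
  sb2 <- simulateSynteny(g2, GRanges("aut1", IRanges(40e6, 44e6)),
                         meanBlockLen = 1e6, seed = 23)
  so2 <- scaffoldOrientation(assignChromosomes(filterBlocks(sb2)))
  expect_false(so2$inverted)
  expect_false(so2$ambiguous)

  ## 50/50 orientation: ambiguous, not flagged
  df <- data.frame(refChrom = "c1", refStart = c(1, 500001),
                   refEnd = c(500000, 1000000), queryChrom = "q1",
                   queryStart = c(1, 500001), queryEnd = c(500000, 1000000),
                   orientation = c("+", "-"), stringsAsFactors = FALSE)
  sb3 <- mkBlockSet(df, c(c1 = 1e6), c(q1 = 1e6))
  so3 <- scaffoldOrientation(assignChromosomes(sb3))
  expect_false(so3$inverted)
  expect_true(so3$ambiguous)
})

test_that("inversion calls segment opposite-orientation runs", {
  g <- makeGenome(2, c(30e6, 20e6), sex = "female")
  inv <- GRanges("aut1", IRanges(10e6, 14e6))    # 4 Mb planted
  sb <- filterBlocks(simulateSynteny(g, inv, meanBlockLen = 3e5,
                                     seed = 29))
  corr <- assignChromosomes(sb)
  calls <- callInversions(sb, corr)
  expect_equal(nrow(calls), 1)
  expect_identical(calls$scaleClass, "megabase")
  ro <- selkie:::.reciprocalOverlap(calls$refStart, calls$refEnd,
                                    10e6, 14e6)
  expect_gte(ro, 0.9)

  ## uniform orientation: no calls at all
  sbU <- filterBlocks(simulateSynteny(g, meanBlockLen = 3e5, seed = 29))
  expect_equal(nrow(callInversions(sbU, assignChromosomes(sbU))), 0)

  ## two disjoint planted inversions separated by dominant blocks
  inv2 <- GRanges("aut1", IRanges(c(5e6, 20e6), c(7e6, 23e6)))
  sb2 <- filterBlocks(simulateSynteny(g, inv2, meanBlockLen = 3e5,
                                      seed = 31))
  calls2 <- callInversions(sb2, assignChromosomes(sb2))
  expect_equal(nrow(calls2), 2)
  expect_true(all(calls2$scaleClass == "megabase"))

  ## calls never overlap within a pair
  if (nrow(calls2) > 1) {
    o <- order(calls2$refStart)
    expect_true(all(calls2$refStart[o][-1] > calls2$refEnd[o][-nrow(calls2)]))
  }
})

test_that("reversing every block yields the complementary call structure", {
  g <- makeGenome(1, 20e6, sex = "female")
  inv <- GRanges("aut1", IRanges(8e6, 11e6))
  sb <- filterBlocks(simulateSynteny(g, inv, meanBlockLen = 4e5, seed = 37))
  corr <- assignChromosomes(sb)
  calls <- callInversions(sb, corr)

  flipped <- sb
  b <- blocks(flipped)
  b$orientation <- ifelse(b$orientation == "+", "-", "+")
  flipped@blocks <- b
  corrF <- assignChromosomes(flipped)
  tbF <- correspondenceTable(corrF)
  expect_identical(tbF$dominantOrientation, "-")
  callsF <- callInversions(flipped, corrF)
  ## the same blocks oppose the (now flipped) dominant orientation,
  ## so the call set is unchanged
  expect_equal(callsF$refStart, calls$refStart)
  expect_equal(callsF$refEnd, calls$refEnd)
})

test_that("shared calls are grouped at 50% reciprocal overlap", {
  a <- data.frame(refChrom = "chr6", refStart = 10e6, refEnd = 14e6,
                  query = "q1", nBlocks = 10L, span = 4e6 + 1,
                  scaleClass = "megabase", stringsAsFactors = FALSE)
  b <- data.frame(refChrom = "chr6",
                  refStart = c(10.5e6, 20e6), refEnd = c(14.2e6, 21e6),
                  query = "q2", nBlocks = c(9L, 3L),
                  span = c(3.7e6, 1e6) + 1,
                  scaleClass = c("megabase", "megabase"),
                  stringsAsFactors = FALSE)
  sh <- sharedInversions(list(spA = a, spB = b))
  expect_identical(sh$sharedWith[sh$species == "spA"], "spB")
  shB <- sh[sh$species == "spB", ]
  expect_identical(shB$sharedWith[shB$refStart == 10.5e6], "spA")
  expect_identical(shB$sharedWith[shB$refStart == 20e6], "")

  ## below the reciprocal threshold nothing is shared
  c2 <- b; c2$refStart <- c(13.5e6, 20e6); c2$refEnd <- c(17.5e6, 21e6)
  sh2 <- sharedInversions(list(spA = a, spB = c2))
  expect_true(all(sh2$sharedWith == ""))
})

test_that("noisy orientation flips are absorbed by run tolerance", {
  g <- makeGenome(1, 50e6, sex = "female")
  inv <- GRanges("aut1", IRanges(20e6, 24e6))
  hits <- vapply(1:10, function(s) {
    sb <- filterBlocks(simulateSynteny(g, inv, meanBlockLen = 2e5,
                                       seed = s, orientationNoise = 0.05))
    corr <- assignChromosomes(sb)
    calls <- callInversions(sb, corr, maxIntervening = 1L)
    mb <- calls[calls$scaleClass == "megabase", , drop = FALSE]
    nrow(mb) == 1 &&
      selkie:::.reciprocalOverlap(mb$refStart, mb$refEnd, 20e6, 24e6) >= 0.5
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
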