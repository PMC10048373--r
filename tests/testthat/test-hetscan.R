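## build a bare record set with given annotation fields at dummy positions
mkRecords <- function(qual, dp, gq, sp, chrom = "aut1",
                      pos = seq_along(qual), gt = "het") {
  gr <- GRanges(chrom, IRanges(pos, width = 1))
  mcols(gr) <- S4Vectors::DataFrame(qual = qual, dp = dp, gq = gq,
                                    sp = sp, gt = rep(gt, length.out =
                                                        length(gr)),
                                    isSnp = TRUE)
  gr
}

test_that("the filter applies strict thresholds and the inclusive depth band", {
  ## boundary: qual 19.9 fails the strict qual rule
  r <- mkRecords(qual = 19.9, dp = 10, gq = 30, sp = 5)
  out <- filterVariants(r, filterConfig(), meanCov = 20)
  expect_length(out$kept, 0)
  expect_equal(unname(out$tally["qual"]), 1)

  ## boundary semantics: equality passes every strict rule, and dp 5
  ## sits inside the closed 30-250% band of meanCov 10
  r2 <- mkRecords(qual = 20.0, dp = 5.0, gq = 20.0, sp = 60.0)
  out2 <- filterVariants(r2, filterConfig(), meanCov = 10)
  expect_length(out2$kept, 1)

  ## band removal: dp 5 is 25% of meanCov 20
  r3 <- mkRecords(qual = 50, dp = 5, gq = 30, sp = 5)
  out3 <- filterVariants(r3, filterConfig(), meanCov = 20)
  expect_length(out3$kept, 0)
  expect_equal(unname(out3$tally["covBand"]), 1)

  ## first-match attribution follows the written rule order
  r4 <- mkRecords(qual = c(10, 50, 50, 50), dp = c(1, 1, 10, 10),
                  gq = c(5, 5, 5, 30), sp = c(99, 99, 5, 99))
  t4 <- filterVariants(r4, filterConfig(), meanCov = 20)$tally
  expect_equal(unname(t4[c("qual", "sp", "dp", "gq")]), c(1, 2, 0, 1))

  ## records with missing fields are counted and skipped, run continues
  r5 <- mkRecords(qual = c(50, NA), dp = c(10, 10), gq = c(30, 30),
                  sp = c(5, 5))
  out5 <- filterVariants(r5, filterConfig(), meanCov = 20)
  expect_equal(unname(out5$tally["missing"]), 1)
  expect_length(out5$kept, 1)

  expect_error(filterVariants(r, filterConfig(), meanCov = 0), "meanCov")
})

test_that("the filter agrees with a record-by-record oracle and is idempotent", {
  set.seed(12)
  n <- 1000
  r <- mkRecords(qual = runif(n, 0, 100), dp = rpois(n, 20),
                 gq = runif(n, 0, 60), sp = abs(rnorm(n, sd = 30)))
  out <- filterVariants(r, filterConfig(), meanCov = 20)
  mc <- mcols(r)
  keepOracle <- filterOracle(mc$qual, mc$dp, mc$gq, mc$sp, meanCov = 20)
  expect_identical(start(out$kept), start(r)[keepOracle])
  expect_equal(unname(out$tally["kept"]), sum(keepOracle))
  expect_equal(sum(out$tally[c("qual", "sp", "dp", "gq", "covBand")]),
               n - sum(keepOracle))

  ## filtering the survivors removes nothing
  again <- filterVariants(out$kept, filterConfig(), meanCov = 20)
  expect_equal(length(again$kept), length(out$kept))
  expect_equal(sum(again$tally[c("qual", "sp", "dp", "gq", "covBand")]), 0)
})

test_that("the ploidy mask silences male non-PAR X heterozygotes only", {
  par <- GRanges("chrX", IRanges(1, 4e5))
  r <- mkRecords(qual = rep(50, 4), dp = rep(20, 4), gq = rep(50, 4),
                 sp = rep(1, 4), chrom = c("aut1", "chrX", "chrX", "chrX"),
                 pos = c(100, 1e5, 5e5, 9e5))
  m <- applyPloidyMask(r, "male", par, xName = "chrX")
  expect_identical(mcols(m)$gt, c("het", "het", "missing", "missing"))

  ## females are untouched
  f <- applyPloidyMask(r, "female", par, xName = "chrX")
  expect_identical(mcols(f)$gt, rep("het", 4))

  ## male without a resolved PAR: whole X masked, with a warning
  expect_warning(mAll <- applyPloidyMask(r, "male", NULL, xName = "chrX"),
                 "whole X")
  expect_identical(mcols(mAll)$gt, c("het", "missing", "missing",
                                     "missing"))
})

test_that("sliding-window counts equal a brute-force interval oracle", {
  chromLen <- c(aut1 = 1e7)
  set.seed(9)
  pos <- sort(sample.int(1e7, 600))
  r <- mkRecords(qual = rep(50, 600), dp = rep(20, 600),
                 gq = rep(50, 600), sp = rep(1, 600), pos = pos)
  ht <- hetWindows(r, chromLen)
  w <- trackWindows(ht)
  expect_equal(mcols(w)$count,
               bruteWindowCounts(pos, start(w), end(w)))
  full <- width(w) == 1e6
  expect_lt(abs(mean(mcols(w)$density[full]) - 0.06), 0.01)

  ## no variants: all densities zero
  ht0 <- hetWindows(r[0], chromLen)
  expect_true(all(mcols(trackWindows(ht0))$density == 0))

  ## chromosome of exactly 1 Mb: starts 1, 100001, ..., 900001, truncated
  ht1 <- hetWindows(r[0], c(c1 = 1e6))
  w1 <- trackWindows(ht1)
  expect_equal(start(w1), seq(1, 900001, by = 1e5))
  expect_true(all(end(w1) == 1e6))

  ## chromosome shorter than the step: one covering window
  ht2 <- hetWindows(r[0], c(tiny = 50000))
  expect_equal(length(trackWindows(ht2)), 1)
  expect_equal(width(trackWindows(ht2)), 50000)

  expect_error(hetWindows(r, chromLen, window = 1e6, step = 3e5),
               "multiple")
})

test_that("stacking windows conserve counts and interior SNPs hit window/step windows", {
  chromLen <- c(aut1 = 5e6)
  set.seed(10)
  pos <- sort(sample.int(5e6, 300))
  r <- mkRecords(qual = rep(50, 300), dp = rep(20, 300),
                 gq = rep(50, 300), sp = rep(1, 300), pos = pos)

  ## non-overlapping windows partition the SNPs
  stack <- hetWindows(r, chromLen, window = 1e6, step = 1e6)
  expect_equal(sum(mcols(trackWindows(stack))$count), 300)

  ## each interior SNP contributes to exactly window/step windows
  slide <- hetWindows(r, chromLen, window = 1e6, step = 1e5)
  w <- trackWindows(slide)
  interior <- pos[pos > 1e6 & pos <= 4e6]
  for (p in interior[1:20]) {
    nWin <- sum(start(w) <= p & end(w) >= p)
    expect_equal(nWin, 10)
  }
})

test_that("summaries report the histogram mode and a secondary zero mode", {
  ## constant track: everything collapses to the constant
  chromLen <- c(a = 3e6)
  r <- mkRecords(qual = rep(50, 1800), dp = rep(20, 1800),
                 gq = rep(50, 1800), sp = rep(1, 1800),
                 chrom = "a", pos = round(seq(1, 3e6, length.out = 1800)))
  ht <- hetWindows(r, chromLen)
  s <- hetSummary(ht)
  expect_lt(abs(s@median - 0.6), 0.05)
  expect_true(s@min <= s@median && s@median <= s@max)

  ## planted mixture: ~90% of windows near 0.6, a zero block near 0
  g <- makeGenome(1, 9e6, xLength = 1e6, parLength = 0, sex = "male")
  dens <- c(aut1 = 0.6, chrX = 0.6)
  v <- simulateVariants(g, simulationConfig(hetDensity = dens, seed = 13))
  ## male X without PAR emits nothing there: densities 0 on the X
  htM <- hetWindows(v, chromLengths(g), xName = "chrX")
  sM <- hetSummary(htM)
  expect_lt(abs(max(sM@modes) - 0.6), 0.021)    # within one bin
  expect_true(sM@zeroMode || 0 %in% sM@modes)
  expect_equal(sM@binWidth, 0.02)

  ## excluding the X removes the zero signature
  sX <- hetSummary(htM, excludeX = TRUE)
  expect_false(sX@zeroMode)
  expect_true(sX@xExcluded)
})

test_that("an empty heterozygosity track cannot be summarized", {
  r <- mkRecords(qual = 50, dp = 20, gq = 50, sp = 1)
  ht <- hetWindows(r, c(aut1 = 1e6))
  ht@windows <- ht@windows[0]
  expect_error(hetSummary(ht), "empty")
})
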