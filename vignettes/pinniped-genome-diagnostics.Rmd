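---
title: "Coverage, heterozygosity, synteny and assembly diagnostics with selkie"
author: "selkie authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage, heterozygosity, synteny and assembly diagnostics with selkie}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selkie)
library(GenomicRanges)
```

# Scope

`selkie` packages the analysis layer that sits downstream of read
alignment and variant calling in a chromosome-length mammalian genome
project, of the kind used for comparative pinniped genomics:

* coverage-based sex verification and pseudoautosomal region (PAR)
  detection from windowed read-depth medians;
* a ploidy-aware variant filter chain with per-rule removal accounting;
* sliding-window heterozygosity densities and their summary statistics;
* synteny-block filtering, chromosome correspondence assignment and
  inversion calling;
* assembly contiguity statistics, chromosome-scaffold cutoff detection,
  BUSCO percentage conversion and k-mer spectral genome-size estimation.

The real datasets these methods target are hundreds of gigabytes of
reads, so the package carries a seeded synthetic-data generator that
plants ground truth — PAR boundaries, SNP densities, inversions, k-mer
spectra — at desk scale. Every method is validated against that planted
truth rather than against downloads.

# The coverage model and PAR detection

## Model

A diploid autosome sequenced at mean depth $\mu$ yields per-base depths
we model as Poisson($\mu$), optionally over-dispersed: the generator's
`depthDispersion` $\phi \ge 1$ switches to a negative binomial with mean
$\mu$ and variance $\phi\mu$. A male's X is present in one copy outside
the PAR, so the hemizygous X is simulated (and, in real data, observed)
at depth $\mu/2$, while the PAR and a female X track $\mu$. The Poisson
baseline is the simplest model that exercises the median-window logic;
the dispersion knob exists because the depth distribution of real
libraries is not known in advance and is a free parameter, not an
inference target.

## Windowed medians and the genome level

Per-base depth is summarized as the median within stacking (tiling,
non-overlapping) windows of 10 kbp. Medians, unlike means, shrug off
collapsed-repeat pileups and zero-depth assembly gaps. The trailing
window of each chromosome may be shorter than nominal; it participates
with its actual median and a `partial` flag, because PARs are terminal
features and dropping edge windows would bias exactly the boundaries we
care about.

The *genome level* — the normalization denominator — is the median of
autosomal window medians. The choice of median-of-medians, and the
exclusion of the X, are deliberate: a male X at half depth would
otherwise drag the denominator down. Both choices are exposed
(`genomeLevel(track, autosomesOnly = )`).

## Sex inference

The ratio of the median normalized X window level to the autosomal
level clusters near 0.5 (male) or 1.0 (female). The decision threshold
defaults to the midpoint, 0.75; it is a parameter because no published
threshold exists for this decision.

## Two-pass PAR merging

PAR detection runs on the X:

1. **Pass 1.** Windows whose median reaches 70% of the genome level are
   marked; adjacent marked windows merge into diploid-coverage segments.
2. **Pass 2.** For each pair of consecutive segments, the pooled
   per-base median over the intervening gap is computed; gaps that also
   reach the threshold are closed. All qualifying gaps close
   simultaneously and the pass repeats until a fixed point, which makes
   the result independent of scan order.

The PAR is the segment abutting an X terminus with length at least
`minPar` (100 kbp by default, suppressing single-window noise
segments); when both termini qualify the longer segment wins. A segment
spanning the entire X is a female-like, fully diploid X: the call is
returned with `diploidX = TRUE` and no PAR, since a terminal boundary
is not resolvable there.

One mathematical note on pass 2: when the gap is a union of whole
windows that each individually failed pass 1, the pooled gap median is
(up to ties at even window sizes) also below the threshold — a median
over a partition cannot exceed every part's median. Pass 2 therefore
fires only on degenerate or non-tiling inputs; it is retained because
it is part of the published two-pass procedure and harmless when inert.
The practical consequence is that boundary accuracy rests on pass 1,
where a boundary falling inside a window moves the detected edge by at
most one window — hence the package's stated accuracy of plus or minus
one 10 kbp window.

## What the synthetic recovery study shows

The acceptance study (20 seeded males, 30-fold Poisson depth, planted
terminal PARs of 1–10 Mbp on a 12 Mbp X with two 3 Mbp autosomes;
females with a 6 Mbp diploid X) recovers every boundary within one
window and reports every female PAR absent. These problem sizes are the
package's chosen desk-scale study conditions. What this does *not*
show: robustness to mappability dropouts, collapsed repeats near the
PAR boundary, or X-transposed regions, none of which the generator
emulates.

# Variant filtering and heterozygosity

## The filter chain

A record is removed iff

```
QUAL < 20.0 || (SP > 60.0 | DP < 5.0 | GQ < 20.0)
```

with *strict* comparisons exactly as written (equality passes), and
survivors are kept iff sample depth lies in the *inclusive* band of
30–250% of the mean genome coverage. "Coverage" for the band is the
sample's FORMAT/DP; sample-level and site-level depth are not
distinguished here. The removal tally attributes each record to the
first failing rule in written order, which makes the accounting stable
and explainable; records missing a required field are counted and
skipped without aborting. The filter is idempotent by construction.
SP, the strand-bias Phred score, is simulated half-normal since only
its upper tail interacts with the threshold.

## Ploidy mask

True heterozygous genotypes cannot occur on a single-copy sequence, so
for males every heterozygous call on the X outside the PAR is an
artifact: `applyPloidyMask()` sets those genotypes to missing. A male
without a resolved PAR is handled conservatively by masking the whole X
(with a warning), trading a small loss of real PAR heterozygosity for
zero hemizygous artifacts.

## Sliding windows and summaries

Heterozygous SNPs (indels are excluded from counting, though they flow
through the filter) are counted in 1 Mbp windows advanced by 100 kbp —
an interior SNP contributes to exactly ten windows — and scaled to
SNPs/kbp of the window's *actual* span. End-of-chromosome windows are
truncated and rescaled rather than dropped, because chromosome-end
densities run high and dropping them would bias the tails.

Summaries report min/median/mean/max plus a histogram mode with bins of
width 0.02 SNPs/kbp centered on multiples of 0.02 (so modes print at
two decimals and zero is a representable bin center). In males the
hemizygous X floods the zero bin; when that bin is a local maximum the
summary raises `zeroMode`, mirroring the extra density mode at 0 that
male samples show.

# Synteny blocks, correspondence and inversions

Blocks are consumed, not computed: the package reads PSL-like tables
(reference and query intervals plus an orientation sign, query
coordinates always ascending). Blocks shorter than 50 kbp on the
reference are discarded, matching the usual minimum block size of
whole-genome-alignment synteny extraction.

Each query scaffold is assigned to the reference chromosome receiving
the most aligned bp. Naming follows karyotype practice: a
chromosome-painting (Zoo-FISH) map, when available, gives `chr<n>`
names; otherwise the scaffold matching the reference X is named `chrX`
— safe because the X is highly conserved across carnivores — and the
remaining scaffolds are numbered `aut1…autN` from longest to shortest.

The dominant orientation of a scaffold pair is the strand carrying the
majority of aligned bp (bp, not block count, so many tiny blocks cannot
outvote one long one). A scaffold with at least 80% of aligned bp in
reverse orientation is flagged whole-scaffold-inverted — assemblies
routinely store chromosomes reverse-complemented — and scaffolds where
neither strand reaches 80% are reported ambiguous.

Inversions are maximal runs of consecutive blocks opposing the pair's
dominant orientation. `maxIntervening` (default 0, strict runs) allows
a tolerated number of dominant-orientation blocks inside a run to
absorb alignment noise. A call spans the first to the last opposing
block; calls with span of at least 1 Mbp are classed `megabase`, the
rest `short`. The 1 Mbp class boundary and the 50% reciprocal overlap
used to group calls shared between query species are parameters: the
distinction between "dozens of short inversions" and a handful of
megabase-scale ones has no published cutoff, and sharing is asserted
visually in dot plots, so both defaults are package choices.

The recovery study plants 4 Mbp inversions in noiseless 300 kbp-scale
block tilings over 20 seeds: calls are exact in count with reciprocal
overlap above 0.9, and uniform-orientation sets yield zero calls. With
5% random orientation flips, single-block false runs appear but fall in
the `short` class; `maxIntervening = 1` keeps the planted call intact
in the large majority of seeds. Nested inversions are not modelled.

# Assembly statistics

* **N50/L50** use the "cumulative sum reaches half the total"
  convention, the most common one (the metric has no single published
  definition). It is property-tested against a brute-force
  sort-and-accumulate oracle on 1,000 random length lists.
* **Chromosome-scaffold cutoff**: on the descending length list, the
  rank maximizing $L_k / L_{k+1}$ (ties break to the smallest rank,
  searched over the top 64 ranks). The fold gap is rounded to the
  nearest integer for display — the convention that turns 57.63/1.99
  into "a 29-fold difference" — and a gap of at least 10-fold flags a
  chromosome-scale assembly.
* **BUSCO percentages** are `100 * count / total` rounded half-up to
  one decimal (base `round()` is banker's rounding, which published
  tables do not use). When published percentages are supplied for
  comparison, disagreements are flagged, never silently matched: one
  published row prints 4.4% where 399/9226 computes to 4.3%.
* **Genome size from a k-mer spectrum**: with trough $t$ (first strict
  local minimum after multiplicity 1, separating error from coverage
  k-mers) and peak $m$ (argmax count at or beyond $t$),
  $\hat G = \sum_{i \ge t} i\,c_i / m$. Flat spectra with no strict
  local minimum fail loudly and ask for an explicit `minMult` rather
  than guessing. The estimate is invariant to error mass below a fixed
  trough.

The simulated spectrum draws one multiplicity per genomic k-mer from a
discretised normal centred at the mean depth with Poisson-scale width,
floored at 1. A discretised symmetric distribution has an unambiguous
modal bin at the rounded mean; a Poisson(20) component would place
exactly tied mass on multiplicities 19 and 20 and make the argmax peak
a coin flip, which is a property of that discrete pmf rather than of
the estimator. The error component concentrates at multiplicities 1–2
(80/20), with its mass set so that the configured fraction of all k-mer
observations is erroneous.

# Numerical and convention choices

* **Coordinates** are 1-based closed `IRanges`/`GRanges` everywhere in
  memory; 0-based half-open coordinates appear only on disk (bedGraph,
  BED, the block TSV), converted at the I/O boundary.
* **Window medians** for even window sizes use the midpoint convention
  (mean of the two central order statistics), computed by a single
  radix sort of (window, value) pairs per chromosome.
* **Reads**: `standardizeReads()` cuts reads down to the target length
  (keeping the 5' end) and never pads — shorter reads are dropped —
  then subsamples without replacement to the target coverage, erroring
  with the achievable coverage when the budget cannot be met.
* **Determinism**: every generator consumes an explicit seed and
  restores the caller's RNG state, so identical configurations produce
  byte-identical artifacts.

# Study conditions used by the automated checks

The test suite and the acceptance script run entirely on generated
data, at sizes chosen to exercise each method's full logic: 18–22 Mbp
genomes for per-base coverage studies (20 male seeds, 5 female), 10 Mbp
chromosomes for heterozygosity recovery at a planted 0.6 SNPs/kbp,
50 Mbp reference chromosomes tiled by 300 kbp blocks for inversion
recovery, 10 Mbp genomes at 20-fold for k-mer spectra, and 1,000 random
length lists for the N50 oracle. These sizes are the package's own
choices of desk-scale study conditions; the statistical structure (not
the absolute scale) is what the methods consume.

# Limitations

* The coverage generator draws per-base depths independently; real
  depth tracks are autocorrelated through read length and mappability.
  Window medians are insensitive to this at the scales involved, but
  boundary accuracy claims transfer to real data only where coverage is
  well behaved.
* The variant generator plants only biallelic heterozygous SNPs;
  multi-allelic handling is exercised at the I/O layer (first ALT
  taken), not statistically.
* Synteny simulation tiles chromosomes completely; real block sets have
  alignment gaps, which affect coverage fractions but not orientation
  logic.
* PSMC-style demographic inference, repeat annotation, and the
  upstream alignment/calling pipeline are out of scope by design.

# A worked session

```{r worked, fig.width = 6, fig.height = 4}
g <- makeGenome(2, c(3e6, 3e6), xLength = 6e6, parLength = 1.5e6,
                sex = "male")
cfg <- simulationConfig(meanDepth = 30, hetDensity = 0.6, seed = 7)

cov <- simulateCoverage(g, cfg)
wt <- windowMedians(cov, 10000, xName = "chrX")
genomeLevel(wt)
inferSex(wt)
(pc <- detectPar(wt, cov))

v <- simulateVariants(g, cfg)
fv <- filterVariants(v, filterConfig(), meanCov = 30)
fv$tally
ht <- hetWindows(applyPloidyMask(fv$kept, "male", pc), chromLengths(g),
                 xName = "chrX")
hetSummary(ht)

h <- simulateKmerHistogram(5e6, cfg)
est <- genomeSizeFromKmers(h, minMult = 3)
plotKmerSpectrum(h, est)
```
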