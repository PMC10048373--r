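## Run expr with a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## depth draws: Poisson at dispersion 1, else NB with matching mean and
## variance mu * dispersion
.rdepth <- function(n, mu, dispersion) {
  if (n == 0L) return(integer())
  if (mu == 0) return(integer(n))
  if (dispersion <= 1) rpois(n, mu)
  else rnbinom(n, mu = mu, size = mu / (dispersion - 1))
}

#' Simulate a per-base read-depth track
#'
#' Draws independent per-base depths: autosomes, the PAR and a female X at
#' \code{meanDepth}; the male non-PAR X at \code{meanDepth / 2}
#' (hemizygous).  Depth noise is Poisson at \code{depthDispersion = 1},
#' negative binomial (variance \code{meanDepth * depthDispersion}) above.
#' The result can be written as bedGraph with
#' \code{\link{writeDepthBedgraph}}.
#'
#' @param genome a \code{\link{GenomeModel}}.
#' @param config a \code{\link{SimulationConfig}}; its \code{seed} makes
#'   the track reproducible byte-for-byte.
#' @return A named \code{RleList} of integer per-base depths, one element
#'   per chromosome.
#' @examples
#' g <- makeGenome(1, 2e5, xLength = 1e5, parLength = 4e4, sex = "male")
#' cov <- simulateCoverage(g, simulationConfig(meanDepth = 30, seed = 1))
#' round(sapply(cov, mean), 1)
#' @export
simulateCoverage <- function(genome, config) {
  stopifnot(is(genome, "GenomeModel"), is(config, "SimulationConfig"))
  validObject(genome); validObject(config)
  mu <- config@meanDepth
  disp <- config@depthDispersion
  .withSeed(config@seed, {
    out <- lapply(seq_along(genome@chromNames), function(i) {
      chrom <- genome@chromNames[i]
      n <- as.integer(genome@chromLengths[i])
      hemizygous <- genome@sex == "male" && !is.na(genome@xName) &&
        chrom == genome@xName
      if (!hemizygous) return(Rle(.rdepth(n, mu, disp)))
      ## male X: diploid depth inside the PAR, half depth outside
      d <- .rdepth(n, mu / 2, disp)
      par <- genome@par
      if (length(par) && as.character(seqnames(par)) == chrom) {
        idx <- start(par):end(par)
        d[idx] <- .rdepth(length(idx), mu, disp)
      }
      Rle(d)
    })
    names(out) <- genome@chromNames
    RleList(out, compress = FALSE)
  })
}
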