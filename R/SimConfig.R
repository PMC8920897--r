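#' Create a simulator configuration
#'
#' Constructor for [SimConfig-class]. Defaults reproduce the study
#' conditions the package was designed around: a tetraploid with H = 113x
#' somatic depth per haplotype, 717 pollen genomes at 0.18x, 1 SNP per
#' 60 bp between divergent haplotypes, ~50% of the genome in IBD blocks,
#' 10-kb depth windows merged into 50-kb coverage markers. Chromosome
#' count/length default to a desk-scale genome of 12 x 1 Mb.
#'
#' @param nChromosomes number of chromosomes (default 12).
#' @param chromLengthBp chromosome length in bp (default 1e6).
#' @param snpRateDivergent SNPs per bp between non-IBD haplotypes
#'   (default 1/60).
#' @param ibdFraction fraction of positions inside IBD blocks (default 0.5).
#' @param ibdBlockMeanBp mean IBD block size in bp (default 1e5).
#' @param ibdMultiplicityWeights probabilities that a block is shared by
#'   2/3/4 haplotypes (default c(0.8, 0.2, 0): four-way sharing is rare in
#'   a two-parent pedigree and off by default).
#' @param pericentromericIbd bias IBD blocks toward the chromosome middle
#'   (default FALSE, uniform).
#' @param nGametes number of diploid gametes (default 717).
#' @param gameteCoverage per-copy gamete sequencing depth (default 0.18).
#' @param somaticDepthPerHaplotype per-haplotype somatic depth H
#'   (default 113).
#' @param crossoversPerBivalentMean Poisson mean crossovers per bivalent
#'   (default 0.3: on a desk-scale 1-Mb chromosome this keeps the genetic
#'   distance between neighboring 50-kb markers small, the regime in which
#'   linkage grouping operates, while recombination stays clearly present;
#'   see the methods vignette).
#' @param doubleReductionRate double-reduction probability (default 0).
#' @param windowBp depth window size (default 10000).
#' @param markerBp coverage-marker size (default 50000).
#' @param readLengthBp gamete read length (default 150).
#' @param mode "counts" (default) or "sequence".
#' @param seed master seed (default 1).
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nChromosomes = 2, chromLengthBp = 2e5, nGametes = 100)
#' cfg
#' @export
simConfig <- function(nChromosomes = 12,
                      chromLengthBp = 1e6,
                      snpRateDivergent = 1 / 60,
                      ibdFraction = 0.5,
                      ibdBlockMeanBp = 1e5,
                      ibdMultiplicityWeights = c("2" = 0.8, "3" = 0.2,
                                                 "4" = 0),
                      pericentromericIbd = FALSE,
                      nGametes = 717,
                      gameteCoverage = 0.18,
                      somaticDepthPerHaplotype = 113,
                      crossoversPerBivalentMean = 0.3,
                      doubleReductionRate = 0,
                      windowBp = 10000,
                      markerBp = 50000,
                      readLengthBp = 150,
                      mode = c("counts", "sequence"),
                      seed = 1L) {
  mode <- match.arg(mode)
  w <- as.numeric(ibdMultiplicityWeights)
  names(w) <- c("2", "3", "4")
  new("SimConfig",
      nChromosomes = as.integer(nChromosomes),
      chromLengthBp = as.numeric(chromLengthBp),
      nHaplotypes = 4L,
      snpRateDivergent = snpRateDivergent,
      ibdFraction = ibdFraction,
      ibdBlockMeanBp = as.numeric(ibdBlockMeanBp),
      ibdMultiplicityWeights = w,
      pericentromericIbd = pericentromericIbd,
      nGametes = as.integer(nGametes),
      gameteCoverage = gameteCoverage,
      somaticDepthPerHaplotype = somaticDepthPerHaplotype,
      crossoversPerBivalentMean = crossoversPerBivalentMean,
      doubleReductionRate = doubleReductionRate,
      windowBp = as.numeric(windowBp),
      markerBp = as.numeric(markerBp),
      readLengthBp = as.numeric(readLengthBp),
      mode = mode,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:",
      object@nChromosomes, "chromosomes x",
      format(object@chromLengthBp, big.mark = ","), "bp,",
      object@nGametes, "gametes @", object@gameteCoverage, "x\n")
  cat("  H =", object@somaticDepthPerHaplotype,
      "| IBD fraction =", object@ibdFraction,
      "| SNP rate =", signif(object@snpRateDivergent, 3),
      "| crossovers/bivalent =", object@crossoversPerBivalentMean, "\n")
  cat("  window =", object@windowBp, "bp | marker =", object@markerBp,
      "bp | mode =", object@mode, "| seed =", object@seed, "\n")
})
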