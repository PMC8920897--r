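#' Simulation configuration for a synthetic tetraploid genome
#'
#' Holds all parameters of the bundled tetraploid + pollen simulator. The
#' defaults describe the study conditions the package targets: an
#' autotetraploid with a per-haplotype somatic depth of 113x, 717 diploid
#' pollen genomes sequenced at 0.18x, divergent haplotypes at ~1 SNP per
#' 60 bp, and about half of the genome inside identical-by-descent (IBD)
#' blocks shared by two (mostly) or three haplotypes.
#'
#' @slot nChromosomes number of chromosomes.
#' @slot chromLengthBp chromosome length in bp.
#' @slot nHaplotypes number of haplotypes; fixed at 4 (autotetraploid).
#' @slot snpRateDivergent substitutions per bp between non-IBD haplotype
#'   pairs (default 1/60).
#' @slot ibdFraction fraction of chromosome positions covered by IBD blocks.
#' @slot ibdBlockMeanBp mean IBD block length in bp.
#' @slot ibdMultiplicityWeights probabilities that a block is shared by
#'   2, 3 or 4 haplotypes (named "2","3","4").
#' @slot pericentromericIbd if TRUE, IBD blocks are biased toward the
#'   chromosome middle; default FALSE (uniform placement).
#' @slot nGametes number of diploid gametes (pollen nuclei).
#' @slot gameteCoverage sequencing depth per carried haplotype copy per
#'   gamete (x).
#' @slot somaticDepthPerHaplotype genome-wide somatic depth per haplotype,
#'   H (x).
#' @slot crossoversPerBivalentMean Poisson mean of crossovers per bivalent.
#' @slot doubleReductionRate probability that both chromatids of a gamete
#'   chromosome derive from the same bivalent (default 0).
#' @slot windowBp depth-typing window size (bp).
#' @slot markerBp coverage-marker target size (bp); multiple of windowBp.
#' @slot readLengthBp gamete (short) read length in bp.
#' @slot mode "counts" (no nucleotide sequences; fast) or "sequence"
#'   (haplotype FASTA emitted for the k-mer evaluation path).
#' @slot seed master RNG seed; every stochastic stage derives from it.
#' @export
setClass("SimConfig", representation(
  nChromosomes = "integer",
  chromLengthBp = "numeric",
  nHaplotypes = "integer",
  snpRateDivergent = "numeric",
  ibdFraction = "numeric",
  ibdBlockMeanBp = "numeric",
  ibdMultiplicityWeights = "numeric",
  pericentromericIbd = "logical",
  nGametes = "integer",
  gameteCoverage = "numeric",
  somaticDepthPerHaplotype = "numeric",
  crossoversPerBivalentMean = "numeric",
  doubleReductionRate = "numeric",
  windowBp = "numeric",
  markerBp = "numeric",
  readLengthBp = "numeric",
  mode = "character",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@nHaplotypes != 4L)
    msg <- c(msg, "nHaplotypes must be 4 (autotetraploid model)")
  if (object@ibdFraction < 0 || object@ibdFraction >= 1)
    msg <- c(msg, "ibdFraction must be in [0, 1)")
  for (s in c("nChromosomes", "chromLengthBp", "ibdBlockMeanBp", "nGametes",
              "gameteCoverage", "somaticDepthPerHaplotype", "windowBp",
              "markerBp", "readLengthBp")) {
    if (slot(object, s) <= 0) msg <- c(msg, paste(s, "must be positive"))
  }
  if (object@markerBp %% object@windowBp != 0)
    msg <- c(msg, "markerBp must be a multiple of windowBp")
  if (object@ibdFraction > 0 && object@ibdBlockMeanBp > object@chromLengthBp)
    msg <- c(msg, "ibdBlockMeanBp exceeds chromLengthBp")
  if (object@crossoversPerBivalentMean < 0)
    msg <- c(msg, "crossoversPerBivalentMean must be >= 0")
  if (object@doubleReductionRate < 0 || object@doubleReductionRate > 1)
    msg <- c(msg, "doubleReductionRate must be in [0, 1]")
  if (length(object@ibdMultiplicityWeights) != 3 ||
      any(object@ibdMultiplicityWeights < 0) ||
      sum(object@ibdMultiplicityWeights) <= 0)
    msg <- c(msg, "ibdMultiplicityWeights must be 3 non-negative weights")
  if (!object@mode %in% c("counts", "sequence"))
    msg <- c(msg, "mode must be 'counts' or 'sequence'")
  if (length(msg)) msg else TRUE
})

#' Ground-truth synthetic tetraploid genome
#'
#' Output of [simulateGenome()]: four labeled haplotypes per chromosome,
#' the IBD block annotation, and the contig tiling (one collapsed contig
#' per maximal IBD block, one haplotig per maximal non-IBD segment of each
#' haplotype). Haplotypes 1-2 descend from parent A, 3-4 from parent B.
#'
#' @slot config the [SimConfig-class] used.
#' @slot chromosomes chromosome names.
#' @slot chromLengthBp named chromosome lengths.
#' @slot ibdBlocks data.frame: chrom, start, end (0-based half-open),
#'   haps (comma-separated haplotype indices sharing the block).
#' @slot contigs data.frame: contig_id, chrom, start, end, haps, nHaps.
#' @slot sequences DNAStringSet of haplotype-chromosome sequences named
#'   \code{chr{c}_hap{h}}, or NULL in counts-only mode.
#' @slot parentOfHaplotype character(4), "A"/"B" per haplotype.
#' @export
setClass("TruthGenome", representation(
  config = "SimConfig",
  chromosomes = "character",
  chromLengthBp = "numeric",
  ibdBlocks = "data.frame",
  contigs = "data.frame",
  sequences = "ANY",
  parentOfHaplotype = "character"
))

setValidity("TruthGenome", function(object) {
  msg <- character(0)
  ctg <- object@contigs
  need <- c("contig_id", "chrom", "start", "end", "haps", "nHaps")
  if (!all(need %in% names(ctg)))
    msg <- c(msg, "contigs must have contig_id/chrom/start/end/haps/nHaps")
  if (length(object@parentOfHaplotype) != 4 ||
      !all(object@parentOfHaplotype %in% c("A", "B")))
    msg <- c(msg, "parentOfHaplotype must be 4 labels in {A,B}")
  if (length(msg)) msg else TRUE
})

#' Diploid gamete genomes
#'
#' Output of [simulateGametes()]: for every gamete and chromosome, the two
#' recombinant haplotype mosaics (chromatids, one per bivalent under the
#' default no-double-reduction model), stored as labeled intervals.
#'
#' @slot segments data.frame: gamete_id, chrom, mosaic (1 or 2), start,
#'   end (0-based half-open), hap (source haplotype index 1..4).
#' @slot crossovers data.frame: gamete_id, chrom, mosaic, pos.
#' @slot gameteIds gamete identifiers.
#' @export
setClass("GameteSet", representation(
  segments = "data.frame",
  crossovers = "data.frame",
  gameteIds = "character"
))

#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

#' Presence/absence patterns (PAPs) of coverage markers across gametes
#'
#' A \linkS4class{RangedSummarizedExperiment}: rows are coverage markers
#' (GRanges on contig coordinates, with \code{copyClass} and marker length
#' \code{W}), columns are gametes. Assays: \code{counts} (raw per-gamete
#' read counts) and \code{genotype} (normalized, rounded and domain-clipped
#' coverage genotypes; the PAP values). Column data carries each gamete's
#' total aligned reads N, the normalization mean m_r, and a usability flag.
#'
#' @export
setClass("PapSet", contains = "RangedSummarizedExperiment")

#' Haplotype grouping of contigs and markers
#'
#' Result of linkage clustering: per-haplotig group assignments, the
#' group-to-chromosome homology map, multi-assignments of collapsed
#' contigs, and the thresholded linkage graph edges for inspection.
#'
#' @slot contigGroups data.frame: contig_id, group_id, confidence,
#'   method ("graph" or "rescued"), flag.
#' @slot multiAssignments data.frame: contig_id, group_id, rank, score, flag.
#' @slot chromosomeMap data.frame: group_id, chromosome_id.
#' @slot edges data.frame: from, to, weight (linkage graph dump).
#' @slot params list of thresholds used.
#' @export
setClass("HaplotypeGrouping", representation(
  contigGroups = "data.frame",
  multiAssignments = "data.frame",
  chromosomeMap = "data.frame",
  edges = "data.frame",
  params = "list"
))

#' Trio-style phasing evaluation report
#'
#' Per haplotype assembly (or per linkage group in counts mode), the number
#' of parent-A-specific and parent-B-specific diagnostic k-mers/markers it
#' contains, the dominant parent, and the overall phasing precision
#' (sum of per-unit max counts over sum of all counts).
#'
#' @slot table data.frame: unit, countA, countB, dominant.
#' @slot precision overall precision in [0, 1].
#' @slot mode "kmer" or "marker".
#' @export
setClass("PhasingReport", representation(
  table = "data.frame",
  precision = "numeric",
  mode = "character"
))
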