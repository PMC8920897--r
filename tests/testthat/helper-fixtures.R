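# Shared fixtures, computed lazily once per session.

.fixtureEnv <- new.env(parent = emptyenv())

memoFixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureEnv)) {
    assign(name, builder(), envir = .fixtureEnv)
  }
  get(name, envir = .fixtureEnv)
}

# mid-size simulated pipeline: 3 chromosomes x 500 kb, 400 gametes
midSim <- function() {
  memoFixture("mid", function() {
    cfg <- simConfig(nChromosomes = 3, chromLengthBp = 5e5, nGametes = 400,
                     seed = 42)
    genome <- simulateGenome(cfg)
    gametes <- simulateGametes(genome)
    windows <- classifyWindows(simulateWindowDepths(genome),
                               cfg@somaticDepthPerHaplotype)
    markers <- mergeToMarkers(windows, cfg@markerBp)
    counts <- simulateMarkerCounts(genome, gametes, markers)
    paps <- buildPapMatrix(counts, markers, minInformative = 10)
    grouping <- suppressWarnings(clusterContigs(paps))
    list(cfg = cfg, genome = genome, gametes = gametes, windows = windows,
         markers = markers, counts = counts, paps = paps,
         grouping = grouping)
  })
}

# clean single-chromosome panel: no IBD, no crossovers, deep gamete
# coverage -- class-1 PAPs must equal the truth carrier indicators
cleanSim <- function() {
  memoFixture("clean", function() {
    cfg <- simConfig(nChromosomes = 1, chromLengthBp = 4e5, nGametes = 120,
                     ibdFraction = 0, crossoversPerBivalentMean = 0,
                     gameteCoverage = 18, seed = 9)
    genome <- simulateGenome(cfg)
    gametes <- simulateGametes(genome)
    windows <- classifyWindows(simulateWindowDepths(genome),
                               cfg@somaticDepthPerHaplotype)
    markers <- mergeToMarkers(windows, cfg@markerBp)
    counts <- simulateMarkerCounts(genome, gametes, markers)
    paps <- buildPapMatrix(counts, markers, minInformative = 3)
    list(cfg = cfg, genome = genome, gametes = gametes, windows = windows,
         markers = markers, counts = counts, paps = paps)
  })
}

# construct a PapSet directly from a genotype matrix; one marker per row,
# one single-marker contig per row by default
makePapSet <- function(geno, classes,
                       contigs = paste0("ctg", LETTERS[seq_len(nrow(geno))]),
                       W = rep(1e5, nrow(geno))) {
  stopifnot(nrow(geno) == length(classes), nrow(geno) == length(contigs))
  gids <- sprintf("g%03d", seq_len(ncol(geno)))
  colnames(geno) <- gids
  starts <- ave(seq_along(contigs), contigs, FUN = seq_along)
  gr <- GenomicRanges::GRanges(
    contigs,
    IRanges::IRanges(start = (starts - 1) * W + 1, width = W))
  S4Vectors::mcols(gr)$copyClass <- factor(as.character(classes),
                                           levels = c("1", "2", "3", "4",
                                                      "REP"))
  S4Vectors::mcols(gr)$W <- W
  names(gr) <- sprintf("%s:%d-%d", contigs,
                       GenomicRanges::start(gr) - 1L,
                       GenomicRanges::end(gr))
  rownames(geno) <- names(gr)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = geno, genotype = geno),
    rowRanges = gr,
    colData = S4Vectors::DataFrame(gamete_id = gids,
                                   N = rep(1e6, length(gids)),
                                   mR = rep(1, length(gids)),
                                   nInformative = rep(nrow(geno),
                                                      length(gids)),
                                   row.names = gids))
  new("PapSet", se)
}

# the six-contig worked example: two haplotype pairs plus one ungrouped
# haplotig and a diplotig spanning the first two haplotypes
toyPaps <- function() {
  pat <- function(s) as.integer(strsplit(s, "")[[1]])
  geno <- rbind(A = pat("111000"), B = pat("000111"), C = pat("111111"),
                D = pat("000111"), E = pat("101010"), F = pat("111000"))
  makePapSet(geno, classes = c("1", "1", "2", "1", "1", "1"),
             contigs = paste0("ctg", rownames(geno)))
}
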