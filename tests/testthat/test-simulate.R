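test_that("config validation enforces the model invariants", {
  expect_error(simConfig(ibdFraction = 1), "ibdFraction")
  expect_error(simConfig(ibdFraction = -0.1), "ibdFraction")
  expect_error(simConfig(markerBp = 45000), "multiple")
  expect_error(simConfig(chromLengthBp = 0), "positive")
  expect_error(simConfig(ibdFraction = 0.5, ibdBlockMeanBp = 2e6,
                         chromLengthBp = 1e6), "exceeds")
})

test_that("seeded genome simulation is reproducible", {
  cfg <- simConfig(nChromosomes = 2, chromLengthBp = 3e5, nGametes = 50,
                   seed = 5)
  g1 <- simulateGenome(cfg)
  g2 <- simulateGenome(cfg)
  expect_identical(contigTruth(g1), contigTruth(g2))
  expect_identical(ibdBlocks(g1), ibdBlocks(g2))
  gm1 <- simulateGametes(g1)
  gm2 <- simulateGametes(g2)
  expect_identical(gameteSegments(gm1), gameteSegments(gm2))
})

test_that("no IBD means every contig is a haplotig, one per haplotype", {
  cfg <- simConfig(nChromosomes = 3, chromLengthBp = 2e5, nGametes = 20,
                   ibdFraction = 0, seed = 2)
  g <- simulateGenome(cfg)
  ctg <- contigTruth(g)
  expect_equal(nrow(ctg), 4 * 3)
  expect_true(all(ctg$nHaps == 1))
  expect_equal(realizedIbdFraction(g), 0)
})

test_that("realized IBD fraction tracks the configured fraction", {
  for (f in c(0.3, 0.5)) {
    g <- simulateGenome(simConfig(nChromosomes = 4, chromLengthBp = 1e6,
                                  nGametes = 10, ibdFraction = f,
                                  seed = 31))
    expect_lt(abs(realizedIbdFraction(g) - f) / f, 0.1)
    # blocks identical across member haplotypes by construction: every
    # base of every haplotype in exactly one contig
    ctg <- contigTruth(g)
    for (h in 1:4) {
      hc <- ctg[vapply(strsplit(ctg$haps, ","),
                       function(s) h %in% as.integer(s), logical(1)), ]
      bp <- tapply(hc$end - hc$start, hc$chrom, sum)
      expect_true(all(bp == 1e6))
    }
  }
})

test_that("without crossovers each gamete carries 2 intact distinct haplotypes", {
  cfg <- simConfig(nChromosomes = 1, chromLengthBp = 2e5, nGametes = 60,
                   ibdFraction = 0, crossoversPerBivalentMean = 0, seed = 3)
  g <- simulateGenome(cfg)
  gam <- simulateGametes(g)
  seg <- gameteSegments(gam)
  perGam <- split(seg, seg$gamete_id)
  for (s in perGam) {
    expect_equal(nrow(s), 2)               # one intact segment per mosaic
    expect_equal(sort(unique(s$mosaic)), 1:2)
    expect_true(all(s$start == 0 & s$end == 2e5))
    expect_equal(length(unique(s$hap)), 2) # different bivalents
  }
  expect_equal(nrow(crossoverTable(gam)), 0)
})

test_that("unordered haplotype pairs are equiprobable (1/6 each)", {
  cfg <- simConfig(nChromosomes = 1, chromLengthBp = 1e5, nGametes = 3000,
                   ibdFraction = 0, crossoversPerBivalentMean = 0, seed = 8)
  gam <- simulateGametes(simulateGenome(cfg))
  seg <- gameteSegments(gam)
  pairs <- tapply(seg$hap, seg$gamete_id,
                  function(h) paste(sort(h), collapse = "-"))
  tab <- table(pairs)
  expect_equal(length(tab), 6)
  expect_true(all(abs(tab / 3000 - 1 / 6) < 0.03))
})

test_that("crossover counts are Poisson with the configured mean", {
  cfg <- simConfig(nChromosomes = 1, chromLengthBp = 1e5, nGametes = 2000,
                   ibdFraction = 0, crossoversPerBivalentMean = 1.5,
                   seed = 4)
  gam <- simulateGametes(simulateGenome(cfg))
  nMosaics <- 2000 * 2
  rate <- nrow(crossoverTable(gam)) / nMosaics
  expect_lt(abs(rate - 1.5), 3 * sqrt(1.5 / nMosaics) + 0.05)
})

test_that("double reduction draws both chromatids from one bivalent", {
  cfg <- simConfig(nChromosomes = 1, chromLengthBp = 1e5, nGametes = 500,
                   ibdFraction = 0, crossoversPerBivalentMean = 0,
                   doubleReductionRate = 1, seed = 6)
  gam <- simulateGametes(simulateGenome(cfg))
  seg <- gameteSegments(gam)
  pairings <- list(c(1, 2), c(3, 4), c(1, 3), c(2, 4), c(1, 4), c(2, 3))
  perGam <- split(seg$hap, seg$gamete_id)
  for (h in perGam) {
    expect_true(any(vapply(pairings, function(p)
      setequal(p, unique(h)) || all(h %in% p), logical(1))))
  }
})

test_that("marker counts follow the copy-number expectation", {
  fix <- cleanSim()   # no IBD: every marker is a 1-copy haplotig marker
  ctg <- contigTruth(fix$genome)
  ci <- match(as.character(GenomicRanges::seqnames(fix$markers)),
              ctg$contig_id)
  m1 <- which(ctg$nHaps[ci] == 1)[1]
  hap <- as.integer(ctg$haps[ci[m1]])
  mid <- ctg$start[ci[m1]] +
    (GenomicRanges::start(fix$markers)[m1] +
       GenomicRanges::end(fix$markers)[m1]) / 2
  carr <- carriersAt(fix$gametes, ctg$chrom[ci[m1]], mid)[, hap]
  cnt <- fix$counts[m1, names(carr)]
  # a gamete without the haplotype has Poisson(0) = 0 reads
  expect_true(all(cnt[carr == 0] == 0))
  expect_true(all(cnt[carr > 0] > 0))
  lam <- fix$cfg@gameteCoverage / fix$cfg@readLengthBp *
    S4Vectors::mcols(fix$markers)$W[m1]
  expect_lt(abs(mean(cnt[carr > 0]) / lam - 1), 0.05)
})

test_that("tetraplotig markers see both chromatids of every gamete", {
  cfg <- simConfig(nChromosomes = 1, chromLengthBp = 3e5, nGametes = 80,
                   ibdFraction = 0.4,
                   ibdMultiplicityWeights = c("2" = 0, "3" = 0, "4" = 1),
                   crossoversPerBivalentMean = 0, seed = 12)
  g <- simulateGenome(cfg)
  gam <- simulateGametes(g)
  win <- classifyWindows(simulateWindowDepths(g),
                         cfg@somaticDepthPerHaplotype)
  mks <- mergeToMarkers(win)
  cnt <- simulateMarkerCounts(g, gam, mks)
  ctg <- contigTruth(g)
  ci <- match(as.character(GenomicRanges::seqnames(mks)), ctg$contig_id)
  t4 <- which(ctg$nHaps[ci] == 4)
  expect_gt(length(t4), 0)
  lam2 <- 2 * cfg@gameteCoverage / cfg@readLengthBp *
    S4Vectors::mcols(mks)$W[t4]
  # every gamete samples c = 2, so counts are never zero and average 2x
  expect_true(all(cnt[t4, ] > 0))
  expect_lt(abs(mean(cnt[t4, ] / lam2) - 1), 0.05)
})

test_that("somatic depth peaks sit at H x copies", {
  fix <- midSim()
  w <- fix$windows
  d <- S4Vectors::mcols(w)$depth
  k <- S4Vectors::mcols(w)$trueCopies
  H <- fix$cfg@somaticDepthPerHaplotype
  for (copies in sort(unique(k))) {
    mu <- mean(d[k == copies])
    expect_lt(abs(mu - H * copies), 4 * sqrt(H * copies) /
                sqrt(sum(k == copies)) + 1)
  }
  # the diplotig expectation: 2H = 226 at H = 113
  if (any(k == 2)) expect_lt(abs(mean(d[k == 2]) - 226), 8)
})

test_that("marginal per-gamete coverage matches the configured coverage", {
  fix <- midSim()
  cfg <- fix$cfg
  ctg <- contigTruth(fix$genome)
  ci <- match(as.character(GenomicRanges::seqnames(fix$markers)),
              ctg$contig_id)
  expect_gt(length(fix$markers), 100)
  # expected reads per gamete: cov/RL x carried bp; carried bp per
  # chromosome is 2 x chromLength regardless of IBD structure
  carriedBp <- 2 * cfg@nChromosomes * cfg@chromLengthBp
  expReads <- cfg@gameteCoverage / cfg@readLengthBp * carriedBp
  obs <- colSums(fix$counts)
  expect_lt(abs(mean(obs) / expReads - 1), 0.05)
})

test_that("presence patterns collapse to 4 haplotype archetypes without recombination", {
  cfg <- simConfig(nChromosomes = 1, chromLengthBp = 3e5, nGametes = 100,
                   ibdFraction = 0, crossoversPerBivalentMean = 0,
                   gameteCoverage = 18, seed = 13)
  g <- simulateGenome(cfg)
  gam <- simulateGametes(g)
  win <- classifyWindows(simulateWindowDepths(g),
                         cfg@somaticDepthPerHaplotype)
  mks <- mergeToMarkers(win)
  cnt <- simulateMarkerCounts(g, gam, mks)
  pres <- (cnt > 0) * 1L
  pats <- unique(apply(pres, 1, paste, collapse = ""))
  expect_equal(length(pats), 4)
  # each gamete's column is the union of its two carried haplotypes
  ctg <- contigTruth(g)
  ci <- match(as.character(GenomicRanges::seqnames(mks)), ctg$contig_id)
  seg <- gameteSegments(gam)
  for (gid in colnames(pres)) {
    hp <- unique(seg$hap[seg$gamete_id == gid])
    want <- as.integer(ctg$haps[ci] %in% as.character(hp))
    expect_equal(unname(pres[, gid]), want)
  }
})

test_that("sequence mode: divergence ~ 1/60 outside IBD, identity inside", {
  cfg <- simConfig(nChromosomes = 1, chromLengthBp = 1.5e5, nGametes = 10,
                   mode = "sequence", seed = 21)
  g <- simulateGenome(cfg)
  seqs <- haplotypeSequences(g)
  expect_equal(names(seqs), paste0("chr1_hap", 1:4))
  ib <- ibdBlocks(g)
  s <- lapply(1:4, function(h)
    strsplit(as.character(seqs[[paste0("chr1_hap", h)]]), "")[[1]])
  # pairwise divergence in regions where neither haplotype is in a block
  mask <- rep(TRUE, cfg@chromLengthBp)
  for (i in seq_len(nrow(ib))) mask[(ib$start[i] + 1):ib$end[i]] <- FALSE
  div <- mean(s[[1]][mask] != s[[3]][mask])
  expect_lt(abs(div - 1 / 60), 3 * sqrt((1 / 60) / sum(mask)) + 1e-3)
  # members of a block are identical over the block
  for (i in seq_len(nrow(ib))) {
    hs <- as.integer(strsplit(ib$haps[i], ",")[[1]])
    idx <- (ib$start[i] + 1):ib$end[i]
    for (h in hs[-1])
      expect_identical(s[[hs[1]]][idx], s[[h]][idx])
  }
})
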