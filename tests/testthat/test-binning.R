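# toy marker catalog and grouping: contig A (two 50-kb haplotig markers,
# group 1), contig B (one diplotig marker, groups 2+3), contig U ungrouped
toyBinSetup <- function() {
  gr <- GenomicRanges::GRanges(
    c("ctgA", "ctgA", "ctgB", "ctgU"),
    IRanges::IRanges(c(1, 50001, 1, 1), c(50000, 100000, 50000, 50000)))
  S4Vectors::mcols(gr)$copyClass <- factor(c("1", "1", "2", "1"),
                                           levels = c("1", "2", "3", "4",
                                                      "REP"))
  S4Vectors::mcols(gr)$W <- GenomicRanges::width(gr)
  names(gr) <- sprintf("%s:%d-%d", as.character(
    GenomicRanges::seqnames(gr)), GenomicRanges::start(gr) - 1L,
    GenomicRanges::end(gr))
  grouping <- new("HaplotypeGrouping",
                  contigGroups = data.frame(contig_id = "ctgA",
                                            group_id = "grp001",
                                            confidence = 1,
                                            method = "graph", flag = "",
                                            stringsAsFactors = FALSE),
                  multiAssignments = data.frame(contig_id = c("ctgB",
                                                              "ctgB"),
                                                group_id = c("grp002",
                                                             "grp003"),
                                                rank = 1:2, score = 1,
                                                flag = "",
                                                stringsAsFactors = FALSE),
                  chromosomeMap = data.frame(group_id = paste0("grp00",
                                                               1:3),
                                             chromosome_id = "chrom01",
                                             stringsAsFactors = FALSE),
                  edges = data.frame(from = character(0),
                                     to = character(0),
                                     weight = numeric(0)),
                  params = list())
  list(markers = gr, grouping = grouping)
}

rec <- function(read, contig, start, end,
                aligned = end - start) {
  data.frame(read_id = read, contig_id = contig, start = start, end = end,
             aligned_bp = aligned, stringsAsFactors = FALSE)
}

test_that("the 500-bp overlap floor and largest-overlap rule decide assignment", {
  s <- toyBinSetup()
  # 600 bp on a grouped haplotig marker: assigned to its group
  out <- assignRead(rec("r1", "ctgA", 1000, 1600), s$grouping, s$markers)
  expect_equal(out$group_id, "grp001")
  expect_equal(out$winning_marker, "ctgA:0-50000")
  # 400 bp: below the floor, unassigned
  out <- assignRead(rec("r2", "ctgA", 1000, 1400), s$grouping, s$markers)
  expect_equal(out$group_id, "UNASSIGNED")
  # overlaps 900 bp vs 700 bp across a marker boundary: larger wins
  out <- assignRead(rec("r3", "ctgA", 49100, 50700), s$grouping, s$markers)
  expect_equal(out$winning_marker, "ctgA:0-50000")
  expect_equal(out$overlap_bp, 900)
})

test_that("split alignments to one marker accumulate before thresholding", {
  s <- toyBinSetup()
  records <- rbind(rec("r1", "ctgA", 1000, 1300),
                   rec("r1", "ctgA", 2000, 2300))
  out <- assignRead(records, s$grouping, s$markers)
  expect_equal(out$group_id, "grp001")   # 300 + 300 = 600 >= 500
  expect_equal(out$overlap_bp, 600)
})

test_that("exact overlap ties break to the earlier marker and are flagged", {
  s <- toyBinSetup()
  out <- assignRead(rec("r1", "ctgA", 49400, 50600), s$grouping, s$markers)
  expect_equal(out$winning_marker, "ctgA:0-50000")
  expect_match(out$flag, "overlap_tie")
})

test_that("reads on multi-copy markers are randomized reproducibly", {
  s <- toyBinSetup()
  n <- 2000
  records <- rec(sprintf("r%04d", 1:n), "ctgB", 0, 15000)
  out1 <- binReads(records, s$grouping, s$markers, seed = 7)
  out2 <- binReads(records[sample(n), ], s$grouping, s$markers, seed = 7)
  expect_identical(out1$assignments, out2$assignments)
  tab <- table(out1$assignments$group_id)
  expect_equal(sort(names(tab)), c("grp002", "grp003"))
  # binomial split about 50/50
  expect_lt(abs(tab[["grp002"]] / n - 0.5), 3 * sqrt(0.25 / n) + 0.01)
  # a different seed reshuffles reads
  out3 <- binReads(records, s$grouping, s$markers, seed = 8)
  expect_false(identical(out1$assignments$group_id,
                         out3$assignments$group_id))
  # single-read assignment matches the full run
  one <- assignRead(records[17, ], s$grouping, s$markers, seed = 7)
  expect_equal(one, out1$assignments[out1$assignments$read_id ==
                                       records$read_id[17], ],
               ignore_attr = TRUE)
})

test_that("multi-copy randomization can be disabled into an AMBIGUOUS bucket", {
  s <- toyBinSetup()
  records <- rbind(rec("r1", "ctgB", 0, 15000),
                   rec("r2", "ctgA", 0, 15000))
  out <- binReads(records, s$grouping, s$markers,
                  randomizeMultiCopy = FALSE)
  a <- setNames(out$assignments$group_id, out$assignments$read_id)
  expect_equal(a[["r1"]], "AMBIGUOUS")
  expect_equal(a[["r2"]], "grp001")
  expect_equal(sum(out$summary$reads), 2)   # conservation
  expect_equal(out$assignedFraction, 0.5)
})

test_that("reads on ungrouped contigs and empty inputs are handled", {
  s <- toyBinSetup()
  out <- assignRead(rec("r1", "ctgU", 0, 15000), s$grouping, s$markers)
  expect_equal(out$group_id, "UNASSIGNED")
  empty <- binReads(rec(character(0), character(0), numeric(0),
                        numeric(0)),
                    s$grouping, s$markers)
  expect_equal(nrow(empty$assignments), 0)
  expect_error(binReads(rec("r1", "nope", 0, 1000), s$grouping,
                        s$markers), "unknown contig")
  expect_error(binReads(rec("r1", "ctgA", 0, 1000, aligned = 2000),
                        s$grouping, s$markers), "aligned_bp")
})

test_that("per-group counts plus unassigned conserve the read total", {
  fix <- midSim()
  records <- simulateReadAlignments(fix$genome, 5000, 15000, seed = 3)
  out <- binReads(records, fix$grouping, fix$markers, seed = 3)
  expect_equal(sum(out$summary$reads), 5000)
  expect_gte(out$assignedFraction, 0.999)
  # shuffling record order leaves every assignment unchanged
  out2 <- binReads(records[rev(seq_len(nrow(records))), ], fix$grouping,
                   fix$markers, seed = 3)
  expect_identical(out$assignments, out2$assignments)
})

test_that("diplotig-region reads split about evenly between their groups", {
  fix <- midSim()
  tr <- contigTruth(fix$genome)
  ma <- multiAssignments(fix$grouping)
  di <- intersect(tr$contig_id[tr$nHaps == 2 &
                                 (tr$end - tr$start) >= 3e4],
                  ma$contig_id)
  records <- rec(sprintf("d%04d", 1:1000), di[1], 0, 15000)
  out <- binReads(records, fix$grouping, fix$markers, seed = 5)
  tab <- table(out$assignments$group_id)
  expect_equal(length(tab), 2)
  expect_lt(abs(tab[[1]] / 1000 - 0.5), 0.05)
})
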