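test_that("the six-contig worked example clusters as {A,F}, {B,D}, {E}", {
  paps <- toyPaps()
  grp <- suppressWarnings(clusterContigs(paps))
  cg <- groupAssignments(grp)
  expect_equal(nGroups(grp), 3)
  grpOf <- setNames(cg$group_id, cg$contig_id)
  expect_equal(grpOf[["ctgA"]], grpOf[["ctgF"]])
  expect_equal(grpOf[["ctgB"]], grpOf[["ctgD"]])
  expect_false(grpOf[["ctgE"]] %in% grpOf[c("ctgA", "ctgB")])
  # the diplotig C extends the {A,F} and {B,D} clusters
  ma <- multiAssignments(grp)
  expect_equal(sort(ma$group_id[ma$contig_id == "ctgC"]),
               sort(unname(grpOf[c("ctgA", "ctgB")])))
})

test_that("linkage edges follow end-marker correlations and the 0.55 threshold", {
  paps <- toyPaps()
  g <- buildLinkageGraph(paps)
  ep <- igraph::as_edgelist(g)
  edges <- sort(apply(ep, 1, function(r) paste(sort(r), collapse = "-")))
  expect_equal(edges, c("ctgA-ctgF", "ctgB-ctgD"))
  # E correlates 1/3 with A: below threshold, no edge
  w <- igraph::edge_attr(g, "weight")
  expect_true(all(w > 0.55))
})

test_that("two disjoint cliques give two groups", {
  p1 <- c(1L, 1L, 1L, 0L, 0L, 0L, 1L, 0L)
  p2 <- c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L)
  geno <- rbind(p1, p1, p1, p2, p2, p2)
  paps <- makePapSet(geno, classes = rep("1", 6),
                     contigs = paste0("ctg", 1:6))
  grp <- suppressWarnings(clusterContigs(paps))
  expect_equal(nGroups(grp), 2)
})

test_that("a chimeric vertex pair violating the homolog bound is split", {
  # U and V share one end-marker pattern (edge) but their other ends are
  # complementary (conflict below -0.25): the edge must be removed
  p <- c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)
  q <- c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L)
  geno <- rbind(u1 = p, u2 = q, v1 = q, v2 = 1L - p)
  paps <- makePapSet(geno, classes = rep("1", 4),
                     contigs = c("ctgU", "ctgU", "ctgV", "ctgV"))
  g <- buildLinkageGraph(paps)
  expect_equal(length(igraph::E(g)), 1)   # max end correlation = 1
  cg <- clusterGraph(g, paps)
  expect_equal(length(unique(cg$group_id)), 2)
})

test_that("homologous groups join into chromosomes via anticorrelation", {
  paps <- toyPaps()
  grp <- suppressWarnings(clusterContigs(paps))
  cm <- chromosomeMap(grp)
  # A/F vs B/D are complementary (cor -1 < -0.25): same chromosome
  cg <- groupAssignments(grp)
  grpOf <- setNames(cg$group_id, cg$contig_id)
  chrOf <- setNames(cm$chromosome_id, cm$group_id)
  expect_equal(chrOf[[grpOf[["ctgA"]]]], chrOf[[grpOf[["ctgB"]]]])
})

test_that("independent groups land on different chromosomes", {
  set.seed(5)
  p1 <- rbinom(60, 1, 0.5); p2 <- rbinom(60, 1, 0.5)
  geno <- rbind(a1 = p1, a2 = p1, b1 = p2, b2 = p2)
  storage.mode(geno) <- "integer"
  paps <- makePapSet(geno, classes = rep("1", 4),
                     contigs = c("ctgA", "ctgA", "ctgB", "ctgB"))
  grp <- suppressWarnings(clusterContigs(paps))
  cm <- chromosomeMap(grp)
  expect_equal(length(unique(cm$chromosome_id)),
               length(unique(cm$group_id)))
})

test_that("small haplotigs are rescued into the best-correlated group", {
  p1 <- c(1L, 1L, 1L, 0L, 0L, 0L, 1L, 0L)
  p2 <- c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L)
  geno <- rbind(p1, p2, p1)
  paps <- makePapSet(geno, classes = rep("1", 3),
                     contigs = c("ctgA", "ctgB", "ctgS"),
                     W = c(2e5, 2e5, 6e4))   # ctgS below the vertex floor
  grp <- suppressWarnings(clusterContigs(paps))
  cg <- groupAssignments(grp)
  expect_equal(cg$method[cg$contig_id == "ctgS"], "rescued")
  expect_equal(cg$group_id[cg$contig_id == "ctgS"],
               cg$group_id[cg$contig_id == "ctgA"])
  expect_equal(cg$confidence[cg$contig_id == "ctgS"], 1)
})

test_that("rescue ties break to the lowest group id and are flagged", {
  p1 <- c(1L, 1L, 1L, 0L, 0L, 0L)
  cg0 <- data.frame(contig_id = c("ctgA", "ctgB"),
                    group_id = c("grp001", "grp002"),
                    confidence = 1, method = "graph", flag = "",
                    stringsAsFactors = FALSE)
  geno <- rbind(p1, p1, p1)   # both groups correlate 1.0 with the orphan
  paps <- makePapSet(geno, classes = rep("1", 3),
                     contigs = c("ctgA", "ctgB", "ctgS"),
                     W = c(2e5, 2e5, 6e4))
  out <- rescueSmallHaplotigs(cg0, paps)
  row <- out[out$contig_id == "ctgS", ]
  expect_equal(row$group_id, "grp001")
  expect_equal(row$flag, "tie")
})

test_that("AND-rule identity holds exhaustively for disjoint X + Y at G = 6", {
  # all per-position combinations of (x, y) in {(0,0),(1,0),(0,1)}
  combos <- expand.grid(rep(list(0:2), 6))
  for (i in seq_len(nrow(combos))) {
    code <- as.integer(combos[i, ])
    x <- as.integer(code == 1)
    y <- as.integer(code == 2)
    z <- x + y
    bz <- as.integer(z > 0)
    expect_identical(as.integer(bz & x), x)
    expect_identical(as.integer(bz & y), y)
  }
})

test_that("a diplotig Z = X + Y is assigned to the groups of X and Y", {
  # exhaustive over disjoint non-degenerate X, Y at G = 6
  combos <- expand.grid(rep(list(0:2), 6))
  decoy <- c(1L, 0L, 0L, 1L, 0L, 1L)
  checked <- checkedDecoy <- 0
  emptyMap <- data.frame(group_id = character(0),
                         chromosome_id = character(0))
  for (i in seq_len(nrow(combos))) {
    code <- as.integer(combos[i, ])
    x <- as.integer(code == 1)
    y <- as.integer(code == 2)
    if (sd(x) == 0 || sd(y) == 0) next
    z <- x + y
    geno <- rbind(x, y, z)
    paps <- makePapSet(geno, classes = c("1", "1", "2"),
                       contigs = c("ctgX", "ctgY", "ctgZ"))
    cg <- data.frame(contig_id = c("ctgX", "ctgY"),
                     group_id = c("grp001", "grp002"),
                     confidence = 1, method = "graph", flag = "",
                     stringsAsFactors = FALSE)
    ma <- assignMulticopyContigs(cg, emptyMap, paps)
    got <- sort(ma$group_id[ma$contig_id == "ctgZ"])
    expect_identical(got, c("grp001", "grp002"))
    checked <- checked + 1

    # with a third group whose pattern the AND rule can distinguish
    # (it has presence where Z is absent), the decoy never wins
    if (any(decoy == 1 & z == 0) && !identical(x, decoy) &&
        !identical(y, decoy)) {
      geno2 <- rbind(x, y, decoy, z)
      paps2 <- makePapSet(geno2, classes = c("1", "1", "1", "2"),
                          contigs = c("ctgX", "ctgY", "ctgD", "ctgZ"))
      cg2 <- rbind(cg, data.frame(contig_id = "ctgD",
                                  group_id = "grp003", confidence = 1,
                                  method = "graph", flag = "",
                                  stringsAsFactors = FALSE))
      ma2 <- assignMulticopyContigs(cg2, emptyMap, paps2)
      got2 <- sort(ma2$group_id[ma2$contig_id == "ctgZ"])
      expect_identical(got2, c("grp001", "grp002"))
      checkedDecoy <- checkedDecoy + 1
    }
  }
  expect_gt(checked, 300)
  expect_gt(checkedDecoy, 100)
})

test_that("clustering is invariant to marker and contig input order", {
  fix <- midSim()
  paps <- fix$paps
  set.seed(88)
  perm <- sample(nrow(paps))
  papsShuffled <- paps[perm, ]
  g1 <- suppressWarnings(clusterContigs(paps))
  g2 <- suppressWarnings(clusterContigs(papsShuffled))
  a1 <- groupAssignments(g1)
  a2 <- groupAssignments(g2)
  expect_identical(a1[order(a1$contig_id), ],
                   a2[order(a2$contig_id), ])
  expect_identical(chromosomeMap(g1), chromosomeMap(g2))
})

test_that("exact haplotype partition is recovered in the clean regime", {
  # no IBD, no crossovers, deep gamete coverage
  fix <- cleanSim()
  grp <- suppressWarnings(clusterContigs(fix$paps))
  expect_equal(nGroups(grp), 4)
  acc <- groupingAccuracy(grp, fix$genome, fix$paps)
  expect_equal(unname(acc$accuracy), 1)
  expect_true(all(acc$purity == 1))
})

test_that("chromosome count never exceeds group count", {
  for (f in list(toyPaps(), midSim()$paps)) {
    grp <- suppressWarnings(clusterContigs(f))
    expect_lte(length(unique(chromosomeMap(grp)$chromosome_id)),
               nGroups(grp))
  }
})

test_that("grouping accuracy arithmetic is exact on crafted inputs", {
  fix <- midSim()
  acc <- groupingAccuracy(fix$grouping, fix$genome, fix$paps)
  expect_true(acc$accuracy >= 0 && acc$accuracy <= 1)
  # mid-size default simulation recovers the partition
  expect_equal(length(unique(fix$grouping@contigGroups$group_id)), 12)
  expect_gte(acc$accuracy, 0.996)
})

test_that("tetraplotig contigs are only grouped through a groupable marker", {
  p1 <- c(1L, 1L, 1L, 0L, 0L, 0L, 1L, 0L)
  geno <- rbind(p1, rep(2L, 8))
  paps <- makePapSet(geno, classes = c("1", "4"),
                     contigs = c("ctgA", "ctgT"))
  cg <- data.frame(contig_id = "ctgA", group_id = "grp001",
                   confidence = 1, method = "graph", flag = "",
                   stringsAsFactors = FALSE)
  # without a chromosome map entry the tetraplotig stays unassigned
  ma <- assignMulticopyContigs(cg, data.frame(group_id = character(0),
                                              chromosome_id = character(0)),
                               paps)
  row <- ma[ma$contig_id == "ctgT", ]
  expect_true(all(is.na(row$group_id)))
  expect_true(all(row$flag == "tetraplotig_unassigned"))
})
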