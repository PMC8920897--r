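#' @importFrom igraph graph_from_data_frame components make_empty_graph
#'   V E delete_edges edge_attr vertex_attr incident_edges ends
NULL

#' Per-contig copy-class summary
#'
#' Aggregates coverage markers per contig: total length, majority copy
#' class by bp, and the marker names. The majority class decides whether a
#' contig is treated as a haplotig (class 1) vertex, a collapsed contig
#' (class 2-4) for multi-assignment, or repetitive.
#'
#' @param markers coverage-marker GRanges (from [mergeToMarkers()]).
#' @return data.frame: contig_id, lengthBp, majorityClass.
#' @export
contigClassSummary <- function(markers) {
  ctg <- as.character(seqnames(markers))
  W <- mcols(markers)$W
  cls <- as.character(mcols(markers)$copyClass)
  ids <- unique(ctg)
  maj <- vapply(ids, function(id) {
    i <- ctg == id
    bp <- tapply(W[i], cls[i], sum)
    names(bp)[which.max(bp)]
  }, character(1))
  data.frame(contig_id = ids,
             lengthBp = as.numeric(tapply(W, ctg, sum)[ids]),
             majorityClass = maj,
             stringsAsFactors = FALSE, row.names = NULL)
}

# class-1 markers with defined (non-zero) PAP variance, indexed per contig
usableHaplotigMarkers <- function(paps) {
  G <- papGenotypes(paps)
  cls <- markerClasses(paps)
  v <- apply(G, 1, function(x) length(unique(x)) > 1)
  which(cls == "1" & v & !is.na(rowSums(G)))
}

#' Build the haplotig linkage graph
#'
#' Vertices are haplotig contigs of at least \code{minHaplotigBp}; two
#' vertices are connected if the highest PAP correlation between the
#' markers at the two ends of the two haplotigs exceeds
#' \code{thetaLink}. End markers are the first and last usable class-1
#' marker of the contig (identical if there is only one).
#'
#' @param paps a [PapSet-class].
#' @param thetaLink edge threshold on the end-marker correlation
#'   (default 0.55).
#' @param minHaplotigBp minimum haplotig length for a vertex
#'   (default 1e5).
#' @return an igraph graph with edge attribute \code{weight}; haplotigs
#'   without usable markers are excluded with a warning.
#' @export
buildLinkageGraph <- function(paps, thetaLink = 0.55, minHaplotigBp = 1e5) {
  info <- contigClassSummary(rowRanges(paps))
  hap <- info[info$majorityClass == "1" &
                info$lengthBp >= minHaplotigBp, , drop = FALSE]
  hap <- hap[order(hap$contig_id), , drop = FALSE]
  mk <- usableHaplotigMarkers(paps)
  mkCtg <- as.character(seqnames(rowRanges(paps)))[mk]
  mkStart <- start(rowRanges(paps))[mk]

  ends1 <- ends2 <- integer(nrow(hap))
  ok <- logical(nrow(hap))
  for (i in seq_len(nrow(hap))) {
    mi <- mk[mkCtg == hap$contig_id[i]]
    if (!length(mi)) next
    ok[i] <- TRUE
    sts <- mkStart[mkCtg == hap$contig_id[i]]
    ends1[i] <- mi[which.min(sts)]
    ends2[i] <- mi[which.max(sts)]
  }
  if (any(!ok))
    warning(sum(!ok), " haplotig(s) >= minHaplotigBp without usable ",
            "markers excluded from the linkage graph")
  hap <- hap[ok, , drop = FALSE]
  ends1 <- ends1[ok]; ends2 <- ends2[ok]
  nV <- nrow(hap)
  g <- make_empty_graph(n = 0, directed = FALSE)
  if (nV == 0) return(g)

  G <- papGenotypes(paps)
  emk <- unique(c(ends1, ends2))
  C <- papCorrelationMatrix(t(G[emk, , drop = FALSE]))
  i1 <- match(ends1, emk); i2 <- match(ends2, emk)
  # contig-level weight: max over the <= 4 end-marker pairs
  R <- pmax(C[i1, , drop = FALSE], C[i2, , drop = FALSE])
  Wm <- pmax(R[, i1, drop = FALSE], R[, i2, drop = FALSE])
  dimnames(Wm) <- list(hap$contig_id, hap$contig_id)

  pair <- which(upper.tri(Wm) & !is.na(Wm) & Wm > thetaLink, arr.ind = TRUE)
  edges <- data.frame(from = hap$contig_id[pair[, 1]],
                      to = hap$contig_id[pair[, 2]],
                      weight = Wm[pair],
                      stringsAsFactors = FALSE)
  g <- graph_from_data_frame(edges, directed = FALSE,
                             vertices = data.frame(
                               name = hap$contig_id,
                               lengthBp = hap$lengthBp,
                               endMarker1 = ends1, endMarker2 = ends2))
  g
}

#' Cluster the linkage graph into haplotype groups
#'
#' Connected components of the thresholded graph form the initial groups.
#' A component that contains two member end-markers with correlation below
#' \code{thetaHom} mixes homologous haplotypes; such components are split
#' by repeatedly removing their minimum-weight edge until no conflict
#' remains. Group ids are assigned canonically by each group's
#' alphabetically first contig, making the result invariant to input
#' order.
#'
#' @param graph igraph from [buildLinkageGraph()].
#' @param paps the [PapSet-class] used to build the graph.
#' @param thetaHom homolog (conflict) threshold (default -0.25).
#' @return data.frame: contig_id, group_id, confidence, method, flag.
#' @export
clusterGraph <- function(graph, paps, thetaHom = -0.25) {
  if (length(V(graph)) == 0)
    return(data.frame(contig_id = character(0), group_id = character(0),
                      confidence = numeric(0), method = character(0),
                      flag = character(0), stringsAsFactors = FALSE))
  G <- papGenotypes(paps)
  e1 <- vertex_attr(graph, "endMarker1")
  e2 <- vertex_attr(graph, "endMarker2")
  emk <- unique(c(e1, e2))
  C <- papCorrelationMatrix(t(G[emk, , drop = FALSE]))
  i1 <- match(e1, emk); i2 <- match(e2, emk)
  # vertex-pair minimum over end-marker correlations, for conflict checks
  Rmin <- pmin(C[i1, , drop = FALSE], C[i2, , drop = FALSE])
  Mmin <- pmin(Rmin[, i1, drop = FALSE], Rmin[, i2, drop = FALSE])

  repeat {
    comp <- components(graph)
    conflict <- FALSE
    for (k in seq_len(comp$no)) {
      vidx <- which(comp$membership == k)
      if (length(vidx) < 2) next
      sub <- Mmin[vidx, vidx, drop = FALSE]
      if (any(!is.na(sub) & sub < thetaHom)) {
        conflict <- TRUE
        eid <- unique(unlist(incident_edges(graph, vidx)))
        w <- edge_attr(graph, "weight", eid)
        graph <- delete_edges(graph, eid[which.min(w)])
        break
      }
    }
    if (!conflict) break
  }

  comp <- components(graph)
  names <- vertex_attr(graph, "name")
  first <- vapply(seq_len(comp$no), function(k)
    min(names[comp$membership == k]), character(1))
  ord <- rank(first, ties.method = "first")
  gid <- sprintf("grp%03d", ord[comp$membership])
  data.frame(contig_id = names, group_id = gid,
             confidence = 1, method = "graph", flag = "",
             stringsAsFactors = FALSE)[order(names), ]
}

# markers usable for group-level correlation tests, per group; ordered by
# genomic position so subsampling is invariant to input row order
groupMarkerIndex <- function(contigGroups, paps, cap = 50) {
  mk <- usableHaplotigMarkers(paps)
  rr <- rowRanges(paps)
  mkCtg <- as.character(seqnames(rr))[mk]
  mk <- mk[order(mkCtg, start(rr)[mk])]
  mkCtg <- as.character(seqnames(rr))[mk]
  out <- lapply(split(contigGroups$contig_id, contigGroups$group_id),
                function(ids) {
    mi <- mk[mkCtg %in% ids]
    if (length(mi) > cap) mi <- mi[round(seq(1, length(mi), length.out = cap))]
    mi
  })
  out[order(names(out))]
}

#' Detect homologous groups and map them to chromosomes
#'
#' Two groups are homologous (same chromosome, different haplotypes) if
#' the lowest PAP correlation between any pair of their markers is below
#' \code{thetaHom}: homologs are anticorrelated because haplotypes enter
#' gametes in a pairwise manner. Chromosomes are the transitive closure of
#' the homology relation; with complete data each chromosome has exactly
#' four member groups (a warning reports deviations).
#'
#' @param contigGroups grouping data.frame from [clusterGraph()] (plus
#'   rescued haplotigs, if already added).
#' @param paps the [PapSet-class].
#' @param thetaHom homolog threshold (default -0.25).
#' @param maxMarkersPerGroup per-group marker cap for the pairwise test
#'   (default 50; markers are subsampled evenly along the group).
#' @return data.frame: group_id, chromosome_id.
#' @export
detectHomologousGroups <- function(contigGroups, paps, thetaHom = -0.25,
                                   maxMarkersPerGroup = 50) {
  gm <- groupMarkerIndex(contigGroups, paps, cap = maxMarkersPerGroup)
  gids <- names(gm)
  nG <- length(gids)
  if (nG == 0)
    return(data.frame(group_id = character(0), chromosome_id = character(0),
                      stringsAsFactors = FALSE))
  allm <- unlist(gm, use.names = FALSE)
  G <- papGenotypes(paps)
  C <- papCorrelationMatrix(t(G[allm, , drop = FALSE]))
  off <- cumsum(c(0, lengths(gm)))
  adj <- matrix(FALSE, nG, nG)
  for (a in seq_len(nG - 1)) {
    ia <- (off[a] + 1):off[a + 1]
    for (b in (a + 1):nG) {
      ib <- (off[b] + 1):off[b + 1]
      sub <- C[ia, ib, drop = FALSE]
      if (any(!is.na(sub) & sub < thetaHom)) adj[a, b] <- adj[b, a] <- TRUE
    }
  }
  g <- graph_from_data_frame(
    data.frame(from = gids[which(adj & upper.tri(adj), arr.ind = TRUE)[, 1]],
               to = gids[which(adj & upper.tri(adj), arr.ind = TRUE)[, 2]]),
    directed = FALSE, vertices = data.frame(name = gids))
  comp <- components(g)
  first <- vapply(seq_len(comp$no), function(k)
    min(gids[comp$membership == k]), character(1))
  ord <- rank(first, ties.method = "first")
  cid <- sprintf("chrom%02d", ord[comp$membership])
  sizes <- table(cid)
  if (any(sizes != 4))
    warning("chromosome(s) with group count != 4: ",
            paste(names(sizes)[sizes != 4], sizes[sizes != 4],
                  sep = "=", collapse = ", "))
  data.frame(group_id = gids, chromosome_id = cid,
             stringsAsFactors = FALSE)
}

#' Rescue ungrouped small haplotigs
#'
#' Every haplotig not in the linkage graph (shorter than the vertex
#' minimum) is integrated into the group whose markers show the highest
#' correlation with any of the haplotig's markers. Ties break to the
#' lowest group id and are flagged; haplotigs whose correlations are all
#' undefined stay unassigned and are reported.
#'
#' @param contigGroups grouping data.frame from [clusterGraph()].
#' @param paps the [PapSet-class].
#' @param maxMarkersPerGroup per-group marker cap (default 50).
#' @return updated grouping data.frame with rescued rows
#'   (method = "rescued", confidence = the winning correlation).
#' @export
rescueSmallHaplotigs <- function(contigGroups, paps,
                                 maxMarkersPerGroup = 50) {
  info <- contigClassSummary(rowRanges(paps))
  todo <- setdiff(info$contig_id[info$majorityClass == "1"],
                  contigGroups$contig_id)
  if (!length(todo)) return(contigGroups)
  gm <- groupMarkerIndex(contigGroups, paps, cap = maxMarkersPerGroup)
  gids <- names(gm)
  allm <- unlist(gm, use.names = FALSE)
  grpOf <- rep(gids, lengths(gm))
  mk <- usableHaplotigMarkers(paps)
  mkCtg <- as.character(seqnames(rowRanges(paps)))[mk]
  G <- papGenotypes(paps)

  rows <- list()
  for (id in sort(todo)) {
    mi <- mk[mkCtg == id]
    if (!length(mi)) {
      warning("haplotig ", id, " has no usable marker; left unassigned")
      next
    }
    C <- papCorrelationMatrix(t(G[mi, , drop = FALSE]),
                              t(G[allm, , drop = FALSE]))
    best <- suppressWarnings(vapply(gids, function(g)
      max(C[, grpOf == g], na.rm = TRUE), numeric(1)))
    best[!is.finite(best)] <- NA
    if (all(is.na(best))) {
      warning("haplotig ", id, " has only undefined correlations; ",
              "left unassigned")
      next
    }
    top <- max(best, na.rm = TRUE)
    winners <- gids[!is.na(best) & best == top]
    flag <- if (length(winners) > 1) "tie" else ""
    rows[[id]] <- data.frame(contig_id = id, group_id = min(winners),
                             confidence = top, method = "rescued",
                             flag = flag, stringsAsFactors = FALSE)
  }
  out <- rbind(contigGroups, do.call(rbind, rows))
  rownames(out) <- NULL
  out[order(out$contig_id), ]
}

#' Assign collapsed contigs to multiple groups via the AND rule
#'
#' A class-k collapsed contig (PAP Z) is expected to satisfy
#' \eqn{Z \approx X + Y} for the PAPs X, Y of its constituent haplotypes,
#' hence \eqn{Z \& X \approx X} under bitwise AND of the binarized
#' patterns. Each candidate group is scored by
#' \code{max over its end markers X of cor(binarize(Z) & binarize(X),
#' binarize(X))} and the k top-scoring groups win. Score ties are broken
#' by the plain PAP correlation \code{cor(Z, X)} (informative when the
#' binarized Z is saturated, as for every triplotig), then by lowest
#' group id (flagged). Tetraplotig-only contigs cannot be linked to a
#' chromosome and stay unassigned; a class-4 contig with at least one
#' groupable non-class-4 marker is assigned to all four groups of that
#' marker's chromosome.
#'
#' @param contigGroups grouping of haplotigs (graph + rescued).
#' @param chromosomeMap data.frame from [detectHomologousGroups()].
#' @param paps the [PapSet-class].
#' @return data.frame: contig_id, group_id, rank, score, flag.
#' @export
assignMulticopyContigs <- function(contigGroups, chromosomeMap, paps) {
  info <- contigClassSummary(rowRanges(paps))
  multi <- info[info$majorityClass %in% c("2", "3", "4"), , drop = FALSE]
  if (!nrow(multi))
    return(data.frame(contig_id = character(0), group_id = character(0),
                      rank = integer(0), score = numeric(0),
                      flag = character(0), stringsAsFactors = FALSE))
  gm <- groupMarkerIndex(contigGroups, paps, cap = 10)
  gids <- names(gm)
  G <- papGenotypes(paps)
  cls <- markerClasses(paps)
  mCtg <- as.character(seqnames(rowRanges(paps)))
  W <- mcols(rowRanges(paps))$W

  rows <- list()
  for (i in order(multi$contig_id)) {
    id <- multi$contig_id[i]
    k <- as.integer(multi$majorityClass[i])
    zi <- selectContigPap(id, k, mCtg, cls, W, G)
    if (is.na(zi)) {
      rows[[id]] <- data.frame(contig_id = id, group_id = NA_character_,
                               rank = NA_integer_, score = NA_real_,
                               flag = "no_usable_marker",
                               stringsAsFactors = FALSE)
      next
    }
    sc <- scoreGroupsAndRule(G[zi, ], gm, G)
    # AND scores equal up to floating jitter must tie, so the secondary
    # criterion can rank saturated (e.g. triplotig) patterns
    sc$and <- round(sc$and, 9)
    if (k == 4L) {
      rows[[id]] <- assignTetraplotig(id, sc, chromosomeMap, gids)
      next
    }
    ok <- which(!is.na(sc$and))
    if (length(ok) < k) {
      rows[[id]] <- if (length(ok)) {
        okOrd <- ok[order(-sc$and[ok])]
        data.frame(contig_id = id, group_id = gids[okOrd],
                   rank = seq_along(okOrd), score = sc$and[okOrd],
                   flag = "partial", stringsAsFactors = FALSE)
      } else {
        data.frame(contig_id = id, group_id = NA_character_,
                   rank = NA_integer_, score = NA_real_,
                   flag = "partial", stringsAsFactors = FALSE)
      }
      next
    }
    ord <- order(-sc$and, -ifelse(is.na(sc$plain), -Inf, sc$plain), gids,
                 na.last = TRUE)
    chosen <- ord[seq_len(k)]
    # boundary tie: rank k and k+1 indistinguishable on both criteria
    tied <- length(ord) > k && !is.na(sc$and[ord[k + 1]]) &&
      sc$and[ord[k]] == sc$and[ord[k + 1]] &&
      (identical(sc$plain[ord[k]], sc$plain[ord[k + 1]]) ||
         (is.na(sc$plain[ord[k]]) && is.na(sc$plain[ord[k + 1]])))
    rows[[id]] <- data.frame(contig_id = id, group_id = gids[chosen],
                             rank = seq_len(k), score = sc$and[chosen],
                             flag = if (isTRUE(tied)) "tie" else "",
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# the contig's representative collapsed PAP: its longest usable marker of
# the majority class (falling back to any non-REP class)
selectContigPap <- function(id, k, mCtg, cls, W, G) {
  mi <- which(mCtg == id & cls == as.character(k))
  if (!length(mi)) mi <- which(mCtg == id & cls != "REP")
  if (!length(mi)) return(NA_integer_)
  mi <- mi[order(names(cls)[mi])]   # position order for determinism
  mi[which.max(W[mi])]
}

# AND-rule and plain-correlation scores of one collapsed PAP against all
# groups (max over each group's representative markers)
scoreGroupsAndRule <- function(z, gm, G) {
  bz <- binarizePap(z)
  andS <- plainS <- rep(NA_real_, length(gm))
  for (gi in seq_along(gm)) {
    best <- bestPlain <- NA_real_
    for (mi in gm[[gi]]) {
      bx <- binarizePap(G[mi, ])
      s <- papCorrelation(bz & bx, bx)
      p <- papCorrelation(z, G[mi, ])
      if (!is.na(s) && (is.na(best) || s > best)) best <- s
      if (!is.na(p) && (is.na(bestPlain) || p > bestPlain)) bestPlain <- p
    }
    andS[gi] <- best; plainS[gi] <- bestPlain
  }
  list(and = andS, plain = plainS)
}

# a class-4 contig maps to a chromosome only through a groupable
# non-class-4 marker; then it joins all four groups of that chromosome
assignTetraplotig <- function(id, sc, chromosomeMap, gids) {
  ok <- which(!is.na(sc$and))
  if (!length(ok) || !nrow(chromosomeMap))
    return(data.frame(contig_id = id, group_id = NA_character_,
                      rank = NA_integer_, score = NA_real_,
                      flag = "tetraplotig_unassigned",
                      stringsAsFactors = FALSE))
  ord <- ok[order(-sc$and[ok], -ifelse(is.na(sc$plain[ok]), -Inf,
                                       sc$plain[ok]), gids[ok])]
  topGrp <- gids[ord[1]]
  chr <- chromosomeMap$chromosome_id[chromosomeMap$group_id == topGrp]
  if (!length(chr))
    return(data.frame(contig_id = id, group_id = NA_character_,
                      rank = NA_integer_, score = NA_real_,
                      flag = "tetraplotig_unassigned",
                      stringsAsFactors = FALSE))
  grp <- sort(chromosomeMap$group_id[chromosomeMap$chromosome_id == chr])
  data.frame(contig_id = id, group_id = grp, rank = seq_along(grp),
             score = sc$and[ord[1]], flag = "via_chromosome",
             stringsAsFactors = FALSE)
}

#' Full linkage clustering of a PAP panel
#'
#' Convenience wrapper chaining [buildLinkageGraph()], [clusterGraph()],
#' [rescueSmallHaplotigs()], [detectHomologousGroups()] and
#' [assignMulticopyContigs()] into a [HaplotypeGrouping-class].
#'
#' @param paps a [PapSet-class].
#' @param thetaLink edge threshold (default 0.55).
#' @param thetaHom homolog threshold (default -0.25).
#' @param minHaplotigBp vertex length floor (default 1e5).
#' @param maxMarkersPerGroup marker cap in group-level tests (default 50).
#' @return a [HaplotypeGrouping-class].
#' @examples
#' \donttest{
#' cfg <- simConfig(nChromosomes = 2, chromLengthBp = 5e5, nGametes = 300,
#'                  seed = 7)
#' g <- simulateGenome(cfg)
#' gam <- simulateGametes(g)
#' win <- simulateWindowDepths(g)
#' mks <- mergeToMarkers(classifyWindows(win,
#'   H = cfg@somaticDepthPerHaplotype))
#' paps <- buildPapMatrix(simulateMarkerCounts(g, gam, mks), mks)
#' clusterContigs(paps)
#' }
#' @export
clusterContigs <- function(paps, thetaLink = 0.55, thetaHom = -0.25,
                           minHaplotigBp = 1e5, maxMarkersPerGroup = 50) {
  if (ncol(paps) == 0)
    stop("no usable gametes in the PAP panel")
  graph <- buildLinkageGraph(paps, thetaLink, minHaplotigBp)
  cg <- clusterGraph(graph, paps, thetaHom)
  cg <- rescueSmallHaplotigs(cg, paps, maxMarkersPerGroup)
  cm <- detectHomologousGroups(cg, paps, thetaHom, maxMarkersPerGroup)
  ma <- assignMulticopyContigs(cg, cm, paps)
  ed <- if (length(E(graph)) > 0) {
    ep <- ends(graph, E(graph))
    data.frame(from = ep[, 1], to = ep[, 2],
               weight = edge_attr(graph, "weight"),
               stringsAsFactors = FALSE)
  } else data.frame(from = character(0), to = character(0),
                    weight = numeric(0))
  new("HaplotypeGrouping", contigGroups = cg, multiAssignments = ma,
      chromosomeMap = cm, edges = ed,
      params = list(thetaLink = thetaLink, thetaHom = thetaHom,
                    minHaplotigBp = minHaplotigBp))
}

#' @rdname HaplotypeGrouping-class
#' @export
setMethod("groupAssignments", "HaplotypeGrouping",
          function(x) x@contigGroups)

#' @rdname HaplotypeGrouping-class
#' @export
setMethod("multiAssignments", "HaplotypeGrouping",
          function(x) x@multiAssignments)

#' @rdname HaplotypeGrouping-class
#' @export
setMethod("chromosomeMap", "HaplotypeGrouping", function(x) x@chromosomeMap)

#' @rdname HaplotypeGrouping-class
#' @export
setMethod("linkageEdges", "HaplotypeGrouping", function(x) x@edges)

#' @rdname HaplotypeGrouping-class
#' @export
setMethod("nGroups", "HaplotypeGrouping",
          function(x) length(unique(x@contigGroups$group_id)))

setMethod("show", "HaplotypeGrouping", function(object) {
  cat("HaplotypeGrouping:", nGroups(object), "groups over",
      nrow(object@contigGroups), "haplotigs;",
      length(unique(object@chromosomeMap$chromosome_id)),
      "chromosomes\n")
  if (nrow(object@multiAssignments))
    cat("  collapsed contigs multi-assigned:",
        length(unique(object@multiAssignments$contig_id)), "\n")
  cat("  linkage edges:", nrow(object@edges), "| thresholds:",
      object@params$thetaLink, "/", object@params$thetaHom, "\n")
})

#' Compare a grouping against simulator truth
#'
#' Per-group purity (majority-haplotype fraction of grouped haplotig
#' marker bp) and overall accuracy (correctly grouped bp over all grouped
#' bp). A group's true haplotype is its majority (chromosome, haplotype)
#' among member haplotig contigs, weighted by bp.
#'
#' @param grouping a [HaplotypeGrouping-class].
#' @param genome the [TruthGenome-class] the pipeline ran on.
#' @param paps the [PapSet-class] (for marker sizes).
#' @return list: \code{accuracy} (overall bp fraction), \code{purity}
#'   (named per group), \code{groupTruth} (group -> chrom/hap).
#' @export
groupingAccuracy <- function(grouping, genome, paps) {
  cg <- grouping@contigGroups
  if (!nrow(cg)) stop("grouping contains no grouped haplotigs")
  truth <- contigTruth(genome)
  if (!all(cg$contig_id %in% truth$contig_id))
    stop("grouping contains contigs unknown to the truth genome")
  info <- contigClassSummary(rowRanges(paps))
  bp <- setNames(info$lengthBp, info$contig_id)
  ti <- match(cg$contig_id, truth$contig_id)
  keep <- truth$nHaps[ti] == 1   # only true haplotigs are unambiguous
  d <- data.frame(group = cg$group_id[keep],
                  key = paste0(truth$chrom[ti][keep], "_hap",
                               truth$haps[ti][keep]),
                  bp = bp[cg$contig_id[keep]])
  tot <- tapply(d$bp, d$group, sum)
  groupTruth <- setNames(character(length(tot)), names(tot))
  pur <- setNames(numeric(length(tot)), names(tot))
  for (g in names(tot)) {
    sub <- d[d$group == g, ]
    byKey <- tapply(sub$bp, sub$key, sum)
    groupTruth[g] <- names(byKey)[which.max(byKey)]
    pur[g] <- max(byKey) / sum(byKey)
  }
  correct <- sum(vapply(names(tot), function(g) {
    sub <- d[d$group == g, ]
    sum(sub$bp[sub$key == groupTruth[g]])
  }, numeric(1)))
  list(accuracy = correct / sum(d$bp), purity = pur,
       groupTruth = groupTruth)
}
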