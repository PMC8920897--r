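#' Marker-to-group lookup table
#'
#' Maps every coverage marker to the group(s) of its contig: one group
#' for grouped haplotigs (graph-clustered or rescued), k groups for
#' multi-assigned collapsed contigs. Markers on unassigned contigs are
#' absent.
#'
#' @param grouping a [HaplotypeGrouping-class].
#' @param markers coverage-marker GRanges.
#' @return data.frame: marker, contig_id, group_id.
#' @export
markerGroupTable <- function(grouping, markers) {
  cg <- grouping@contigGroups[, c("contig_id", "group_id")]
  ma <- grouping@multiAssignments
  ma <- ma[!is.na(ma$group_id), c("contig_id", "group_id"), drop = FALSE]
  map <- rbind(cg, ma)
  mk <- data.frame(marker = names(markers),
                   contig_id = as.character(seqnames(markers)),
                   stringsAsFactors = FALSE)
  out <- merge(mk, map, by = "contig_id", sort = FALSE)
  out[order(out$marker, out$group_id), c("marker", "contig_id", "group_id")]
}

#' Bin long reads into haplotype groups
#'
#' Implements the read-separation rules: a read's overlap with each
#' coverage marker is accumulated over its alignment records (gapped
#' alignments contribute proportionally to their aligned bp); markers with
#' less than \code{minOverlapBp} of the read aligned are discarded; the
#' marker with the largest overlap wins (ties break toward the marker
#' earlier in (contig, start) order and are flagged). A read on a grouped
#' haplotig marker goes to that group; a read on a multi-assigned
#' (collapsed) marker is assigned uniformly at random among the marker's
#' groups using a per-read hash xor \code{seed}, so assignment is
#' reproducible and independent of input order. Reads with no qualifying
#' grouped marker are UNASSIGNED.
#'
#' @param records data.frame of alignment summaries: read_id, contig_id,
#'   start, end (0-based half-open contig coordinates), aligned_bp.
#' @param grouping a [HaplotypeGrouping-class].
#' @param markers coverage-marker GRanges.
#' @param minOverlapBp minimum read-marker overlap (default 500).
#' @param seed randomization seed for multi-copy markers (default 1).
#' @param randomizeMultiCopy if FALSE, reads whose winning marker maps to
#'   several groups are labeled AMBIGUOUS instead of randomized.
#' @return list with \code{assignments} (read_id, group_id,
#'   winning_marker, overlap_bp, flag) and \code{summary} (per-group read
#'   counts, UNASSIGNED count and \code{assignedFraction}).
#' @export
binReads <- function(records, grouping, markers, minOverlapBp = 500,
                     seed = 1L, randomizeMultiCopy = TRUE) {
  need <- c("read_id", "contig_id", "start", "end", "aligned_bp")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  lv <- GenomeInfoDb::seqlevels(markers)
  if (nrow(records) && !all(records$contig_id %in% lv))
    stop("alignment record references unknown contig")
  reads <- sort(unique(records$read_id))
  nR <- length(reads)
  empty <- data.frame(read_id = character(0), group_id = character(0),
                      winning_marker = character(0), overlap_bp = numeric(0),
                      flag = character(0), stringsAsFactors = FALSE)
  if (nR == 0)
    return(list(assignments = empty,
                summary = data.frame(group_id = character(0),
                                     reads = integer(0)),
                assignedFraction = NaN))

  span <- records$end - records$start
  if (any(records$aligned_bp > span | span <= 0))
    stop("aligned_bp exceeds record span or empty span")
  q <- GRanges(factor(records$contig_id, levels = lv),
               IRanges(records$start + 1, records$end))
  ov <- findOverlaps(q, markers)
  qh <- queryHits(ov); sh <- subjectHits(ov)
  w <- width(pintersect(q[qh], markers[sh])) *
    (records$aligned_bp[qh] / span[qh])
  ri <- match(records$read_id, reads)[qh]
  key <- (sh - 1) * nR + ri
  acc <- rowsum(w, key)
  keyv <- as.numeric(rownames(acc))
  ovBp <- acc[, 1]
  pairRead <- (keyv - 1) %% nR + 1
  pairMk <- (keyv - 1) %/% nR + 1
  keep <- ovBp >= minOverlapBp
  pairRead <- pairRead[keep]; pairMk <- pairMk[keep]; ovBp <- ovBp[keep]

  # canonical marker order for deterministic tie-breaks
  mrank <- order(order(as.character(seqnames(markers)), start(markers)))
  o <- order(pairRead, -ovBp, mrank[pairMk])
  pairRead <- pairRead[o]; pairMk <- pairMk[o]; ovBp <- ovBp[o]
  firstIdx <- !duplicated(pairRead)
  winRead <- pairRead[firstIdx]
  winMk <- pairMk[firstIdx]
  winOv <- ovBp[firstIdx]
  # flag exact overlap ties with the runner-up marker
  nxt <- which(firstIdx) + 1L
  tied <- nxt <= length(pairRead) & !firstIdx[pmin(nxt, length(pairRead))] &
    abs(ovBp[pmin(nxt, length(pairRead))] - winOv) < 1e-9

  mgt <- markerGroupTable(grouping, markers)
  grpByMarker <- split(mgt$group_id, mgt$marker)
  mkNames <- names(markers)

  groupId <- rep("UNASSIGNED", nR)
  winMarker <- rep(NA_character_, nR)
  overlap <- rep(NA_real_, nR)
  flag <- rep("", nR)
  winMarker[winRead] <- mkNames[winMk]
  overlap[winRead] <- winOv
  flag[winRead][tied] <- "overlap_tie"

  grps <- grpByMarker[mkNames[winMk]]
  ng <- lengths(grps)
  ng[vapply(grps, is.null, logical(1))] <- 0L
  single <- which(ng == 1L)
  groupId[winRead[single]] <- unlist(grps[single], use.names = FALSE)
  multi <- which(ng > 1L)
  if (length(multi)) {
    if (randomizeMultiCopy) {
      h <- hashStrings(reads[winRead[multi]])
      pick <- vapply(seq_along(multi), function(i) {
        g <- sort(grps[[multi[i]]])
        g[(bitwXor(as.integer(h[i]), as.integer(seed)) %% length(g)) + 1]
      }, character(1))
      groupId[winRead[multi]] <- pick
      flag[winRead[multi]] <- paste0(flag[winRead[multi]],
                                     ifelse(flag[winRead[multi]] == "", "",
                                            ";"), "randomized")
    } else {
      groupId[winRead[multi]] <- "AMBIGUOUS"
    }
  }

  assignments <- data.frame(read_id = reads, group_id = groupId,
                            winning_marker = winMarker,
                            overlap_bp = overlap, flag = flag,
                            stringsAsFactors = FALSE)
  tab <- table(groupId)
  summary <- data.frame(group_id = names(tab),
                        reads = as.integer(tab),
                        stringsAsFactors = FALSE)
  summary <- summary[order(summary$group_id), ]
  rownames(summary) <- NULL
  assigned <- sum(!groupId %in% c("UNASSIGNED", "AMBIGUOUS"))
  list(assignments = assignments, summary = summary,
       assignedFraction = assigned / nR)
}

#' Assign a single read
#'
#' Applies the binning rules of [binReads()] to the records of one read;
#' the result is identical to the read's row in a full [binReads()] run
#' with the same seed.
#'
#' @param records alignment records of one read.
#' @inheritParams binReads
#' @return one-row assignment data.frame.
#' @export
assignRead <- function(records, grouping, markers, minOverlapBp = 500,
                       seed = 1L) {
  if (length(unique(records$read_id)) != 1)
    stop("assignRead expects records of exactly one read")
  binReads(records, grouping, markers, minOverlapBp, seed)$assignments
}
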