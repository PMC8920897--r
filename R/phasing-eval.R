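#' @importFrom Biostrings DNAStringSet reverseComplement writeXStringSet
#'   readDNAStringSet
NULL

# all canonical (strand-collapsed) k-mers of a set of sequences
canonicalKmers <- function(x, k) {
  if (is(x, "DNAStringSet") || is(x, "DNAString"))
    x <- as.character(x)
  x <- x[nchar(x) >= k]
  if (!length(x)) return(character(0))
  km <- unlist(lapply(x, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1), k:n)
  }), use.names = FALSE)
  rc <- as.character(reverseComplement(DNAStringSet(km)))
  pmin(km, rc)
}

#' Extract parent-specific k-mer sets
#'
#' Canonical k-mers found in parent A but not parent B, and vice versa.
#' When a parent is given as sequencing reads, its k-mers can be filtered
#' to a coverage (multiplicity) window — e.g. 6-12 and 5-11 copies for
#' parents sequenced at slightly different depths — which removes
#' error k-mers (low copy) and repeats (high copy). When parents are
#' given as truth assemblies, no window is applied.
#'
#' @param parentA,parentB DNAStringSet (or character vectors) of parent
#'   sequences or reads.
#' @param k k-mer size (default 21).
#' @param coverageA,coverageB optional c(lo, hi) multiplicity windows.
#' @return list with disjoint character sets \code{setA}, \code{setB} and
#'   \code{k}.
#' @export
extractParentKmers <- function(parentA, parentB, k = 21,
                               coverageA = NULL, coverageB = NULL) {
  kmA <- canonicalKmers(parentA, k)
  kmB <- canonicalKmers(parentB, k)
  if (!length(kmA) || !length(kmB))
    warning("k exceeds sequence length for at least one parent; ",
            "k-mer set(s) empty")
  filt <- function(km, win) {
    if (is.null(win)) return(unique(km))
    tab <- table(km)
    names(tab)[tab >= win[1] & tab <= win[2]]
  }
  uA <- filt(kmA, coverageA)
  uB <- filt(kmB, coverageB)
  list(setA = setdiff(uA, uB), setB = setdiff(uB, uA), k = k)
}

#' Count parent-specific k-mers in a haplotype assembly
#'
#' Intersects the assembly's distinct canonical k-mers with the two
#' parent-specific sets. A correctly phased haplotype carries k-mers of
#' only one parent.
#'
#' @param assembly DNAStringSet or character of the haplotype sequence(s).
#' @param sets parent k-mer sets from [extractParentKmers()].
#' @return named numeric c(countA, countB).
#' @export
scoreHaplotype <- function(assembly, sets) {
  km <- unique(canonicalKmers(assembly, sets$k))
  c(countA = sum(km %in% sets$setA),
    countB = sum(km %in% sets$setB))
}

makePhasingReport <- function(tab, mode) {
  scored <- tab$countA + tab$countB > 0
  if (!any(scored))
    stop("no unit carries any parent-specific k-mer/marker; ",
         "precision undefined")
  if (any(!scored))
    warning(sum(!scored), " unit(s) without parent-specific ",
            "k-mers/markers excluded from precision")
  tab$dominant <- ifelse(tab$countA >= tab$countB, "A", "B")
  sub <- tab[scored, , drop = FALSE]
  prec <- sum(pmax(sub$countA, sub$countB)) /
    sum(sub$countA + sub$countB)
  new("PhasingReport", table = tab, precision = prec, mode = mode)
}

#' Overall phasing precision
#'
#' Each haplotype assembly (or linkage group) can only descend from one
#' parent, so its correctly phased k-mers/markers are
#' \code{max(countA, countB)}; precision is the sum of correctly phased
#' over the sum of all investigated, across units. Units with zero counts
#' are excluded and reported.
#'
#' @param x a [PhasingReport-class], or a data.frame with columns
#'   \code{countA} and \code{countB} (one row per haplotype/group).
#' @return precision in [0, 1].
#' @examples
#' phasingPrecision(data.frame(countA = c(99, 0), countB = c(1, 100)))
#' @export
phasingPrecision <- function(x) {
  if (is(x, "PhasingReport")) return(x@precision)
  if (!all(c("countA", "countB") %in% names(x)))
    stop("need countA/countB columns")
  tab <- data.frame(unit = rownames(x) %||% seq_len(nrow(x)),
                    countA = x$countA, countB = x$countB)
  makePhasingReport(tab, mode = "generic")@precision
}

#' k-mer phasing report over haplotype assemblies
#'
#' @param assemblies named list of DNAStringSet/character, one per
#'   haplotype assembly (e.g. from [buildGroupSequences()]).
#' @param sets parent k-mer sets from [extractParentKmers()].
#' @return a [PhasingReport-class] (mode "kmer").
#' @export
kmerPhasingReport <- function(assemblies, sets) {
  cnt <- t(vapply(assemblies, scoreHaplotype, numeric(2), sets = sets))
  tab <- data.frame(unit = names(assemblies) %||%
                      paste0("asm", seq_along(assemblies)),
                    countA = cnt[, "countA"], countB = cnt[, "countB"],
                    stringsAsFactors = FALSE, row.names = NULL)
  makePhasingReport(tab, mode = "kmer")
}

#' Marker-level (counts-mode) phasing report from simulator truth
#'
#' Uses the truth parent label of each grouped haplotig marker as the
#' diagnostic signal: for every linkage group, counts its markers whose
#' true haplotype descends from parent A vs parent B. This mirrors the
#' k-mer evaluation without needing sequences.
#'
#' @param grouping a [HaplotypeGrouping-class].
#' @param genome the [TruthGenome-class].
#' @param paps the [PapSet-class] (marker catalog).
#' @return a [PhasingReport-class] (mode "marker").
#' @export
markerPhasingReport <- function(grouping, genome, paps) {
  cg <- grouping@contigGroups
  truth <- contigTruth(genome)
  ti <- match(cg$contig_id, truth$contig_id)
  if (anyNA(ti)) stop("grouping contains contigs unknown to the truth")
  keep <- truth$nHaps[ti] == 1
  parent <- parentLabels(genome)[as.integer(truth$haps[ti])]
  mCtg <- as.character(seqnames(rowRanges(paps)))
  nMk <- table(factor(mCtg, levels = truth$contig_id))
  d <- data.frame(group = cg$group_id[keep], parent = parent[keep],
                  n = as.integer(nMk[cg$contig_id[keep]]))
  gids <- sort(unique(d$group))
  tab <- data.frame(
    unit = gids,
    countA = vapply(gids, function(g)
      sum(d$n[d$group == g & d$parent == "A"]), numeric(1)),
    countB = vapply(gids, function(g)
      sum(d$n[d$group == g & d$parent == "B"]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  makePhasingReport(tab, mode = "marker")
}

#' Pseudo-assembly sequences per linkage group
#'
#' Concatenates, per group, the true sequences of the group's member
#' contigs (haplotig contigs contribute their haplotype's sequence over
#' the contig interval; collapsed contigs contribute their shared
#' sequence to every group they were assigned to). This emulates the
#' per-group reassembly step for the k-mer evaluation path.
#'
#' @param genome a [TruthGenome-class] simulated in "sequence" mode.
#' @param grouping a [HaplotypeGrouping-class].
#' @return named DNAStringSet, one sequence per group.
#' @export
buildGroupSequences <- function(genome, grouping) {
  seqs <- haplotypeSequences(genome)
  if (is.null(seqs))
    stop("genome was simulated in counts mode; no sequences available")
  chrSeq <- setNames(as.character(seqs), names(seqs))
  truth <- contigTruth(genome)
  contigSeq <- function(row) {
    h <- as.integer(strsplit(row$haps, ",")[[1]])[1]
    substr(chrSeq[[paste0(row$chrom, "_hap", h)]], row$start + 1, row$end)
  }
  map <- rbind(grouping@contigGroups[, c("contig_id", "group_id")],
               grouping@multiAssignments[
                 !is.na(grouping@multiAssignments$group_id),
                 c("contig_id", "group_id"), drop = FALSE])
  gids <- sort(unique(map$group_id))
  out <- vapply(gids, function(g) {
    ids <- sort(map$contig_id[map$group_id == g])
    paste(vapply(ids, function(id)
      contigSeq(truth[truth$contig_id == id, ]), character(1)),
      collapse = "")
  }, character(1))
  DNAStringSet(out)
}

#' @rdname PhasingReport-class
#' @export
setMethod("reportTable", "PhasingReport", function(x) x@table)

setMethod("show", "PhasingReport", function(object) {
  cat("PhasingReport (", object@mode, " mode): ",
      nrow(object@table), " units, precision = ",
      sprintf("%.4f", object@precision), "\n", sep = "")
})
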