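#' @importFrom GenomicRanges GRanges seqnames start end width mcols mcols<-
#' @importFrom IRanges IRanges findOverlaps pintersect
#' @importFrom S4Vectors queryHits subjectHits DataFrame metadata metadata<-
NULL

#' Simulate somatic sequencing depth in contig windows
#'
#' Tiles every contig of the truth genome into \code{windowBp} windows and
#' draws the somatic depth of a window with \eqn{k} collapsed haplotypes
#' from Normal(\eqn{Hk}, sd = sqrt(\eqn{Hk})) truncated at 0 — a
#' Poisson-like noise model that reproduces well-separated depth peaks at
#' H, 2H, 3H and 4H.
#'
#' @param genome a [TruthGenome-class].
#' @param config a [SimConfig-class]; defaults to the genome's.
#' @return a GRanges on contig coordinates with metadata columns
#'   \code{depth} (simulated) and \code{trueCopies} (simulator truth).
#' @export
simulateWindowDepths <- function(genome, config = genome@config) {
  stopifnot(is(genome, "TruthGenome"))
  withSeed(deriveSeed(config@seed, 303L), {
    ctg <- genome@contigs
    H <- config@somaticDepthPerHaplotype
    wbp <- config@windowBp
    len <- ctg$end - ctg$start
    nw <- pmax(1L, as.integer(ceiling(len / wbp)))
    contig <- rep(ctg$contig_id, nw)
    copies <- rep(ctg$nHaps, nw)
    off <- unlist(lapply(nw, function(n) seq_len(n) - 1L)) * wbp
    cstart <- off + 1
    cend <- pmin(off + wbp, rep(len, nw))
    depth <- pmax(0, rnorm(length(cstart), H * copies, sqrt(H * copies)))
    gr <- GRanges(contig, IRanges(cstart, cend),
                  depth = depth, trueCopies = copies,
                  seqinfo = contigSeqinfo(ctg))
    gr
  })
}

contigSeqinfo <- function(ctg) {
  GenomeInfoDb::Seqinfo(seqnames = ctg$contig_id,
                        seqlengths = ctg$end - ctg$start)
}

#' Simulate per-gamete read counts at coverage markers
#'
#' The expected read count of marker \eqn{m} (length \eqn{W}) in gamete
#' \eqn{g} is \eqn{\lambda = cov/RL \times W \times c}, where \eqn{cov} is
#' the per-copy gamete coverage, \eqn{RL} the read length and \eqn{c} the
#' (fractional) number of the gamete's two chromatids that carry, over the
#' marker interval, a haplotype represented by the marker's contig. Counts
#' are Poisson(\eqn{\lambda}).
#'
#' @param genome a [TruthGenome-class].
#' @param gametes a [GameteSet-class].
#' @param markers a GRanges of coverage markers on contig coordinates
#'   (from [mergeToMarkers()]).
#' @param config a [SimConfig-class]; defaults to the genome's.
#' @return integer matrix markers x gametes of read counts (dimnames:
#'   marker names, gamete ids).
#' @export
simulateMarkerCounts <- function(genome, gametes, markers,
                                 config = genome@config) {
  stopifnot(is(genome, "TruthGenome"), is(gametes, "GameteSet"))
  withSeed(deriveSeed(config@seed, 404L), {
    ctg <- genome@contigs
    seg <- gametes@segments
    gids <- gametes@gameteIds
    mContig <- as.character(seqnames(markers))
    ci <- match(mContig, ctg$contig_id)
    if (anyNA(ci)) stop("marker on unknown contig")
    # absolute 0-based marker intervals on the chromosome
    mAbsStart <- ctg$start[ci] + start(markers) - 1
    mAbsEnd <- ctg$start[ci] + end(markers)
    mChrom <- ctg$chrom[ci]
    hapSets <- strsplit(ctg$haps, ",")

    covBp <- matrix(0, nrow = length(markers), ncol = length(gids),
                    dimnames = list(names(markers), gids))
    segIdxByChrom <- split(seq_len(nrow(seg)), seg$chrom)
    for (cix in unique(ci)) {
      mi <- which(ci == cix)
      S <- as.integer(hapSets[[cix]])
      si <- segIdxByChrom[[ctg$chrom[cix]]]
      si <- si[seg$hap[si] %in% S]
      if (!length(si)) next
      q <- IRanges(seg$start[si] + 1, seg$end[si])
      s <- IRanges(mAbsStart[mi] + 1, mAbsEnd[mi])
      ov <- findOverlaps(q, s)
      if (!length(ov)) next
      w <- width(pintersect(q[queryHits(ov)], s[subjectHits(ov)]))
      rows <- mi[subjectHits(ov)]
      cols <- match(seg$gamete_id[si[queryHits(ov)]], gids)
      # accumulate overlap bp per (marker, gamete)
      acc <- rowsum(w, group = (cols - 1) * length(markers) + rows)
      idx <- as.integer(rownames(acc))
      covBp[idx] <- covBp[idx] + acc[, 1]
    }
    lambda <- config@gameteCoverage / config@readLengthBp * covBp
    counts <- matrix(rpois(length(lambda), lambda),
                     nrow = nrow(covBp), dimnames = dimnames(covBp))
    counts
  })
}

#' Simulate long-read-to-marker alignment summaries
#'
#' Samples read start positions uniformly over the (multiplicity-weighted)
#' assembly: a contig collapsing \eqn{k} haplotypes receives reads in
#' proportion to \eqn{k \times} its length. Reads are fully contained in
#' their contig. The result is the PAF-like per-read alignment summary
#' consumed by [binReads()].
#'
#' @param genome a [TruthGenome-class].
#' @param nReads number of reads.
#' @param readBp read length in bp (default 15000).
#' @param seed RNG seed.
#' @return data.frame: read_id, contig_id, start, end (0-based half-open
#'   contig coordinates), aligned_bp.
#' @export
simulateReadAlignments <- function(genome, nReads, readBp = 15000,
                                   seed = genome@config@seed) {
  stopifnot(is(genome, "TruthGenome"))
  withSeed(deriveSeed(seed, 505L), {
    ctg <- genome@contigs
    len <- ctg$end - ctg$start
    ok <- len >= readBp
    if (!any(ok)) stop("no contig is long enough for readBp")
    w <- len[ok] * ctg$nHaps[ok]
    pick <- sample(which(ok), nReads, replace = TRUE, prob = w)
    maxStart <- len[pick] - readBp
    st <- floor(runif(nReads, 0, maxStart + 1))
    data.frame(read_id = sprintf("read%06d", seq_len(nReads)),
               contig_id = ctg$contig_id[pick],
               start = st, end = st + readBp,
               aligned_bp = readBp,
               stringsAsFactors = FALSE)
  })
}
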