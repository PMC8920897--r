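#' Simulate a labeled tetraploid genome with IBD blocks
#'
#' Generates four haplotypes per chromosome, places identical-by-descent
#' (IBD) blocks covering \code{ibdFraction} of each chromosome (block
#' boundaries snapped to the depth-window grid so that depth windows are
#' copy-number pure), and derives the contig tiling: one collapsed contig
#' per maximal IBD block (representing the 2-4 haplotypes that share it)
#' and one haplotig per maximal non-IBD segment of each haplotype. In
#' "sequence" mode, nucleotide sequences are generated such that non-IBD
#' haplotype pairs differ at \code{snpRateDivergent} per bp while IBD block
#' members are identical.
#'
#' @param config a [SimConfig-class].
#' @return a [TruthGenome-class].
#' @examples
#' g <- simulateGenome(simConfig(nChromosomes = 1, chromLengthBp = 3e5,
#'                               nGametes = 50))
#' contigTruth(g)
#' @export
simulateGenome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  withSeed(deriveSeed(config@seed, 101L), {
    L <- config@chromLengthBp
    wbp <- config@windowBp
    Lw <- as.integer(L / wbp)  # chromosome length in windows
    chroms <- paste0("chr", seq_len(config@nChromosomes))

    blocks <- list()
    for (ci in seq_along(chroms)) {
      bl <- placeIbdBlocks(Lw, config)
      if (nrow(bl)) {
        bl$chrom <- chroms[ci]
        bl$start <- bl$start_w * wbp
        bl$end <- bl$end_w * wbp
        blocks[[ci]] <- bl[, c("chrom", "start", "end", "haps")]
      }
    }
    blocks <- if (length(blocks)) do.call(rbind, blocks) else
      data.frame(chrom = character(0), start = numeric(0),
                 end = numeric(0), haps = character(0))
    rownames(blocks) <- NULL

    contigs <- tileContigs(chroms, L, blocks)

    seqs <- NULL
    if (config@mode == "sequence") {
      seqs <- simulateHaplotypeSequences(chroms, L, blocks, config)
    }

    new("TruthGenome",
        config = config,
        chromosomes = chroms,
        chromLengthBp = setNames(rep(L, length(chroms)), chroms),
        ibdBlocks = blocks,
        contigs = contigs,
        sequences = seqs,
        parentOfHaplotype = c("A", "A", "B", "B"))
  })
}

# Place non-overlapping IBD blocks on one chromosome, in window units.
# Alternating gap/block lengths are drawn as normalized exponentials so the
# realized covered fraction equals the target up to window rounding.
placeIbdBlocks <- function(Lw, config) {
  targetW <- round(config@ibdFraction * Lw)
  if (targetW < 1)
    return(data.frame(start_w = integer(0), end_w = integer(0),
                      haps = character(0)))
  meanW <- max(1, round(config@ibdBlockMeanBp / config@windowBp))
  nb <- max(1L, round(targetW / meanW))
  # interior gaps need >= 1 window to keep blocks maximal/disjoint
  gapW <- Lw - targetW
  nb <- min(nb, gapW + 1L, targetW)
  if (nb < 1L) nb <- 1L

  blens <- rexp(nb)
  blens <- pmax(1, round(blens / sum(blens) * targetW))
  blens <- fixTotal(blens, targetW, minv = 1)

  gw <- rexp(nb + 1)
  if (config@pericentromericIbd) {
    # fatter terminal gaps push blocks toward the chromosome middle
    gw[c(1, nb + 1)] <- gw[c(1, nb + 1)] * 4
  }
  glens <- round(gw / sum(gw) * gapW)
  if (nb > 1) glens[2:nb] <- pmax(1, glens[2:nb])
  glens <- fixTotal(glens, gapW, minv = c(0, rep(1, max(0, nb - 1)), 0))

  starts <- cumsum(glens[seq_len(nb)]) + cumsum(c(0, blens[-nb]))
  ends <- starts + blens

  haps <- vapply(seq_len(nb), function(i) {
    s <- sample(2:4, 1, prob = config@ibdMultiplicityWeights)
    paste(sort(sample(1:4, s)), collapse = ",")
  }, character(1))

  data.frame(start_w = starts, end_w = ends, haps = haps,
             stringsAsFactors = FALSE)
}

# adjust an integer partition so it sums to 'total' without dropping below
# per-element minima
fixTotal <- function(x, total, minv) {
  minv <- rep_len(minv, length(x))
  d <- total - sum(x)
  while (d != 0) {
    if (d > 0) {
      i <- which.max(x)
      x[i] <- x[i] + 1
      d <- d - 1
    } else {
      ok <- which(x > minv)
      i <- ok[which.max(x[ok])]
      x[i] <- x[i] - 1
      d <- d + 1
    }
  }
  x
}

# contig tiling: one collapsed contig per IBD block, one haplotig per
# maximal non-IBD segment of each haplotype
tileContigs <- function(chroms, L, blocks) {
  rows <- list()
  for (ch in chroms) {
    bl <- blocks[blocks$chrom == ch, , drop = FALSE]
    bl <- bl[order(bl$start), , drop = FALSE]
    if (nrow(bl)) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, start = bl$start, end = bl$end, haps = bl$haps,
        stringsAsFactors = FALSE)
    }
    for (h in 1:4) {
      inb <- bl[vapply(strsplit(bl$haps, ","),
                       function(s) h %in% as.integer(s), logical(1)), ,
                drop = FALSE]
      segStart <- c(0, inb$end)
      segEnd <- c(inb$start, L)
      keep <- segEnd > segStart
      if (any(keep)) {
        rows[[length(rows) + 1]] <- data.frame(
          chrom = ch, start = segStart[keep], end = segEnd[keep],
          haps = as.character(h), stringsAsFactors = FALSE)
      }
    }
  }
  ctg <- do.call(rbind, rows)
  ctg$nHaps <- vapply(strsplit(ctg$haps, ","), length, integer(1))
  ord <- order(match(ctg$chrom, chroms), ctg$start, ctg$haps)
  ctg <- ctg[ord, , drop = FALSE]
  ctg$contig_id <- sprintf("ctg%05d", seq_len(nrow(ctg)))
  rownames(ctg) <- NULL
  ctg[, c("contig_id", "chrom", "start", "end", "haps", "nHaps")]
}

# haplotype sequences: per-haplotype mutations at half the pairwise rate on
# a shared ancestor, then IBD members copied from the lowest member so
# blocks are identical
simulateHaplotypeSequences <- function(chroms, L, blocks, config) {
  bases <- c("A", "C", "G", "T")
  mu <- config@snpRateDivergent / 2
  out <- character(0)
  for (ch in chroms) {
    anc <- sample(bases, L, replace = TRUE)
    hapSeq <- vector("list", 4)
    for (h in 1:4) {
      s <- anc
      pos <- which(runif(L) < mu)
      if (length(pos)) {
        # substitute with one of the three other bases
        shift <- sample(1:3, length(pos), replace = TRUE)
        cur <- match(s[pos], bases)
        s[pos] <- bases[((cur - 1 + shift) %% 4) + 1]
      }
      hapSeq[[h]] <- s
    }
    bl <- blocks[blocks$chrom == ch, , drop = FALSE]
    if (nrow(bl)) {
      for (i in seq_len(nrow(bl))) {
        mem <- as.integer(strsplit(bl$haps[i], ",")[[1]])
        idx <- (bl$start[i] + 1):bl$end[i]
        for (h in mem[-1]) hapSeq[[h]][idx] <- hapSeq[[mem[1]]][idx]
      }
    }
    for (h in 1:4) {
      out[paste0(ch, "_hap", h)] <- paste(hapSeq[[h]], collapse = "")
    }
  }
  Biostrings::DNAStringSet(out)
}

#' @rdname TruthGenome-class
#' @export
setMethod("contigTruth", "TruthGenome", function(x) x@contigs)

#' @rdname TruthGenome-class
#' @export
setMethod("ibdBlocks", "TruthGenome", function(x) x@ibdBlocks)

#' @rdname TruthGenome-class
#' @export
setMethod("haplotypeSequences", "TruthGenome", function(x) x@sequences)

#' @rdname TruthGenome-class
#' @export
setMethod("parentLabels", "TruthGenome", function(x) x@parentOfHaplotype)

#' @rdname TruthGenome-class
#' @export
setMethod("realizedIbdFraction", "TruthGenome", function(x) {
  tot <- sum(x@chromLengthBp)
  if (nrow(x@ibdBlocks) == 0) return(0)
  sum(x@ibdBlocks$end - x@ibdBlocks$start) / tot
})

setMethod("show", "TruthGenome", function(object) {
  ctg <- object@contigs
  cat("TruthGenome:", length(object@chromosomes), "chromosomes x",
      format(object@chromLengthBp[1], big.mark = ","), "bp\n")
  cat("  contigs:", nrow(ctg),
      sprintf("(haplotigs %d, collapsed %d)", sum(ctg$nHaps == 1),
              sum(ctg$nHaps > 1)), "\n")
  cat("  realized IBD fraction:",
      signif(realizedIbdFraction(object), 3), "\n")
  cat("  sequences:", if (is.null(object@sequences)) "none (counts mode)"
      else paste(length(object@sequences), "haplotype-chromosomes"), "\n")
})
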