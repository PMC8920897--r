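#' Simulate diploid gamete genomes by tetraploid meiosis
#'
#' For every gamete and chromosome the four haplotypes are partitioned
#' uniformly at random into two bivalents (the three pairings are
#' equiprobable). Each bivalent contributes one recombinant chromatid
#' carrying Poisson(\code{crossoversPerBivalentMean}) crossovers at
#' uniform positions, alternating between the two paired haplotypes from a
#' random phase. With probability \code{doubleReductionRate} both
#' chromatids derive from the same (randomly chosen) bivalent.
#'
#' @param genome a [TruthGenome-class] from [simulateGenome()].
#' @param config the same [SimConfig-class]; defaults to the genome's.
#' @return a [GameteSet-class].
#' @examples
#' g <- simulateGenome(simConfig(nChromosomes = 1, chromLengthBp = 2e5,
#'                               nGametes = 20))
#' gam <- simulateGametes(g)
#' head(gameteSegments(gam))
#' @export
simulateGametes <- function(genome, config = genome@config) {
  stopifnot(is(genome, "TruthGenome"))
  withSeed(deriveSeed(config@seed, 202L), {
    G <- config@nGametes
    L <- config@chromLengthBp
    chroms <- genome@chromosomes
    xmean <- config@crossoversPerBivalentMean
    dr <- config@doubleReductionRate
    gids <- sprintf("gam%04d", seq_len(G))
    pairings <- list(c(1L, 2L, 3L, 4L), c(1L, 3L, 2L, 4L),
                     c(1L, 4L, 2L, 3L))

    segGam <- segChrom <- segMos <- vector("list", G * length(chroms))
    segStart <- segEnd <- segHap <- vector("list", G * length(chroms))
    xoGam <- xoChrom <- xoMos <- xoPos <- vector("list", G * length(chroms))
    k <- 0L
    for (gi in seq_len(G)) {
      for (ci in seq_along(chroms)) {
        p <- pairings[[sample.int(3L, 1L)]]
        biv <- list(p[1:2], p[3:4])
        if (dr > 0 && runif(1) < dr) {
          b <- sample.int(2L, 1L)
          biv <- list(biv[[b]], biv[[b]])
        }
        k <- k + 1L
        st <- en <- hp <- ms <- numeric(0)
        xp <- xm <- numeric(0)
        for (m in 1:2) {
          ch <- chromatid(biv[[m]], L, xmean)
          st <- c(st, ch$start); en <- c(en, ch$end)
          hp <- c(hp, ch$hap); ms <- c(ms, rep(m, length(ch$hap)))
          if (length(ch$xo)) {
            xp <- c(xp, ch$xo); xm <- c(xm, rep(m, length(ch$xo)))
          }
        }
        segGam[[k]] <- rep(gi, length(hp)); segChrom[[k]] <- rep(ci, length(hp))
        segMos[[k]] <- ms; segStart[[k]] <- st; segEnd[[k]] <- en
        segHap[[k]] <- hp
        if (length(xp)) {
          xoGam[[k]] <- rep(gi, length(xp)); xoChrom[[k]] <- rep(ci, length(xp))
          xoMos[[k]] <- xm; xoPos[[k]] <- xp
        }
      }
    }
    segments <- data.frame(
      gamete_id = gids[unlist(segGam)],
      chrom = chroms[unlist(segChrom)],
      mosaic = as.integer(unlist(segMos)),
      start = unlist(segStart),
      end = unlist(segEnd),
      hap = as.integer(unlist(segHap)),
      stringsAsFactors = FALSE)
    crossovers <- data.frame(
      gamete_id = gids[unlist(xoGam)],
      chrom = chroms[unlist(xoChrom)],
      mosaic = as.integer(unlist(xoMos)),
      pos = unlist(xoPos),
      stringsAsFactors = FALSE)
    new("GameteSet", segments = segments, crossovers = crossovers,
        gameteIds = gids)
  })
}

# one recombinant chromatid from a bivalent (pair of haplotype indices)
chromatid <- function(pair, L, xmean) {
  nx <- rpois(1, xmean)
  xo <- if (nx > 0) sort(runif(nx, 0, L)) else numeric(0)
  phase <- sample.int(2L, 1L)
  bounds <- c(0, xo, L)
  haps <- pair[((seq_len(nx + 1) + phase) %% 2) + 1]
  # merge runs where consecutive crossovers cancel (same source hap)
  keep <- c(TRUE, haps[-1] != haps[-(nx + 1)])
  st <- bounds[-(nx + 2)][keep]
  en <- c(st[-1], L)
  list(start = st, end = en, hap = haps[keep], xo = xo)
}

#' @rdname GameteSet-class
#' @export
setMethod("gameteSegments", "GameteSet", function(x) x@segments)

#' @rdname GameteSet-class
#' @export
setMethod("crossoverTable", "GameteSet", function(x) x@crossovers)

setMethod("show", "GameteSet", function(object) {
  cat("GameteSet:", length(object@gameteIds), "diploid gametes,",
      nrow(object@segments), "mosaic segments,",
      nrow(object@crossovers), "crossovers\n")
})

#' Carrier matrix of haplotypes per gamete at given positions
#'
#' For truth-based checks: which haplotypes does each gamete carry at a
#' chromosome interval (counting a haplotype once per mosaic that covers
#' the full interval midpoint).
#'
#' @param gametes a [GameteSet-class].
#' @param chrom chromosome name.
#' @param pos position in bp.
#' @return integer matrix gametes x 4 of carried-copy counts at pos.
#' @export
carriersAt <- function(gametes, chrom, pos) {
  seg <- gametes@segments
  seg <- seg[seg$chrom == chrom & seg$start <= pos & seg$end > pos, ,
             drop = FALSE]
  m <- matrix(0L, nrow = length(gametes@gameteIds), ncol = 4,
              dimnames = list(gametes@gameteIds, paste0("hap", 1:4)))
  if (nrow(seg)) {
    idx <- cbind(match(seg$gamete_id, gametes@gameteIds), seg$hap)
    for (i in seq_len(nrow(seg))) m[idx[i, 1], idx[i, 2]] <-
        m[idx[i, 1], idx[i, 2]] + 1L
  }
  m
}
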