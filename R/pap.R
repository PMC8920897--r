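#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowRanges colData
NULL

#' Normalize a per-gamete marker read count
#'
#' \eqn{n_r = r \times (10^4 / W) \times (10^6 / N)}: the raw count is
#' scaled to a 10-kb marker and one million aligned reads, making counts
#' comparable across markers of different length and gametes of different
#' sequencing depth.
#'
#' @param r raw read count(s), >= 0.
#' @param W marker length in bp, > 0.
#' @param N total reads of the gamete aligned to the assembly, > 0.
#' @return normalized count(s).
#' @examples
#' normalizeCount(7, 50000, 1e6)   # 1.4
#' @export
normalizeCount <- function(r, W, N) {
  if (any(W <= 0) || any(N <= 0)) stop("W and N must be positive")
  if (any(r < 0)) stop("read counts must be non-negative")
  r * (1e4 / W) * (1e6 / N)
}

# allowed genotype values per copy class
classDomain <- function(copyClass) {
  switch(as.character(copyClass),
         "1" = c(0L, 1L),
         "2" = c(0L, 2L),
         "3" = c(1L, 2L),
         "4" = c(2L, 2L),
         stop("no genotype domain for class ", copyClass))
}

#' Round a normalized coverage into a class-constrained genotype
#'
#' The coverage genotype is \code{roundHalfUp(n_r / m_r)}, then clipped
#' into the class value domain: \{0,1\} for haplotig markers, \{0,1,2\}
#' for diplotigs, \{1,2\} for triplotigs, \{2\} for tetraplotigs.
#'
#' @param nr normalized count(s) from [normalizeCount()].
#' @param mr the gamete's mean normalized count over informative markers,
#'   > 0.
#' @param copyClass marker copy class ("1".."4").
#' @return integer genotype(s) within the class domain.
#' @examples
#' genotypeMarker(1.8, 1, "1")  # rounds to 2, clips to 1
#' genotypeMarker(0.2, 1, "3")  # rounds to 0, clips to 1
#' @export
genotypeMarker <- function(nr, mr, copyClass) {
  if (any(mr <= 0)) stop("m_r must be positive (gamete unusable)")
  dom <- classDomain(copyClass)
  g <- roundHalfUp(nr / mr)
  as.integer(pmin(pmax(g, dom[1]), dom[2]))
}

#' Pearson correlation of two PAP vectors
#'
#' Direct evaluation of
#' \deqn{cor_{XY} = \frac{\sum (x_i - m_x)(y_i - m_y)}
#'   {\sqrt{\sum (x_i - m_x)^2}\sqrt{\sum (y_i - m_y)^2}}}
#' over the gamete panel. If either vector has zero variance the
#' correlation is undefined and \code{NA} is returned (such markers are
#' excluded from all thresholding).
#'
#' @param x,y equal-length numeric/integer PAP vectors.
#' @return correlation in [-1, 1], or NA if undefined.
#' @examples
#' papCorrelation(c(1,1,1,0,0,0), c(1,0,1,0,1,0))  # 1/3
#' @export
papCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("PAPs must have equal length")
  dx <- x - mean(x)
  dy <- y - mean(y)
  den <- sqrt(sum(dx^2)) * sqrt(sum(dy^2))
  if (den == 0) return(NA_real_)
  sum(dx * dy) / den
}

# column-wise Pearson correlation matrix with NA for zero-variance columns
papCorrelationMatrix <- function(M, M2 = NULL) {
  sc <- function(A) {
    A <- sweep(A, 2, colMeans(A))
    ss <- sqrt(colSums(A^2))
    ss[ss == 0] <- NA
    sweep(A, 2, ss, "/")
  }
  X <- sc(M)
  Y <- if (is.null(M2)) X else sc(M2)
  crossprod(X, Y)
}

#' Build the PAP matrix from marker read counts
#'
#' Computes per-gamete normalizers (total aligned reads \eqn{N}; mean
#' normalized count \eqn{m_r} over informative markers, i.e. markers with
#' raw count above \eqn{7 \times N/10^6}), converts counts to normalized
#' coverages, and rounds them into class-constrained genotypes — one PAP
#' per marker across the gamete panel. Gametes with fewer than
#' \code{minInformative} informative markers (or zero aligned reads) are
#' dropped panel-wide and reported in the object metadata.
#'
#' @param counts integer matrix markers x gametes (e.g. from
#'   [simulateMarkerCounts()]); rows must match \code{markers}.
#' @param markers coverage-marker GRanges with \code{copyClass} and
#'   \code{W} (from [mergeToMarkers()]).
#' @param minInformative minimum informative markers per usable gamete
#'   (default 50).
#' @return a [PapSet-class]; dropped gamete ids are in
#'   \code{metadata(x)$droppedGametes}.
#' @export
buildPapMatrix <- function(counts, markers, minInformative = 50) {
  if (nrow(counts) != length(markers))
    stop("counts rows must match markers")
  if (is.null(rownames(counts))) rownames(counts) <- names(markers)
  gids <- colnames(counts) %||% sprintf("gam%04d", seq_len(ncol(counts)))
  colnames(counts) <- gids

  N <- colSums(counts)
  thr <- 7 * N / 1e6
  W <- mcols(markers)$W
  # normalized counts: scale rows by 1e4/W and columns by 1e6/N
  nr <- counts * (1e4 / W)
  nr <- sweep(nr, 2, ifelse(N > 0, 1e6 / N, NA), "*")
  informative <- sweep(counts, 2, thr, ">")
  nInf <- colSums(informative)
  mr <- vapply(seq_along(gids), function(j) {
    i <- informative[, j]
    if (!any(i)) return(NA_real_)
    mean(nr[i, j])
  }, numeric(1))
  usable <- N > 0 & !is.na(mr) & mr > 0 & nInf >= minInformative
  dropped <- gids[!usable]
  if (length(dropped))
    warning(length(dropped), " gamete(s) dropped (too few informative ",
            "markers)")

  keep <- which(usable)
  cls <- as.character(mcols(markers)$copyClass)
  geno <- matrix(NA_integer_, nrow = length(markers), ncol = length(keep),
                 dimnames = list(rownames(counts), gids[keep]))
  for (cl in c("1", "2", "3", "4")) {
    ri <- which(cls == cl)
    if (!length(ri)) next
    dom <- classDomain(cl)
    g <- roundHalfUp(sweep(nr[ri, keep, drop = FALSE], 2, mr[keep], "/"))
    geno[ri, ] <- as.integer(pmin(pmax(g, dom[1]), dom[2]))
  }

  se <- SummarizedExperiment(
    assays = list(counts = counts[, keep, drop = FALSE], genotype = geno),
    rowRanges = markers,
    colData = DataFrame(gamete_id = gids[keep], N = N[keep], mR = mr[keep],
                        nInformative = nInf[keep], row.names = gids[keep]))
  ps <- new("PapSet", se)
  metadata(ps)$droppedGametes <- dropped
  ps
}

#' @rdname PapSet-class
#' @export
setMethod("papGenotypes", "PapSet", function(x) assay(x, "genotype"))

#' @rdname PapSet-class
#' @export
setMethod("papCounts", "PapSet", function(x) assay(x, "counts"))

#' @rdname PapSet-class
#' @export
setMethod("gameteStats", "PapSet",
          function(x) as.data.frame(colData(x)))

#' @rdname PapSet-class
#' @export
setMethod("markerClasses", "PapSet",
          function(x) setNames(as.character(mcols(rowRanges(x))$copyClass),
                               rownames(x)))

setMethod("show", "PapSet", function(object) {
  cls <- table(markerClasses(object))
  cat("PapSet:", nrow(object), "coverage markers x", ncol(object),
      "gametes\n")
  cat("  marker classes:",
      paste(names(cls), cls, sep = ":", collapse = " "), "\n")
  dropped <- metadata(object)$droppedGametes
  if (length(dropped)) cat("  dropped gametes:", length(dropped), "\n")
})
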