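#' Copy-number class boundaries from the per-haplotype depth
#'
#' The upper depth bound of copy class \eqn{i} (windows collapsing
#' \eqn{i} haplotypes) is \eqn{H \times (i + 1/2)}, rounded half-up.
#' With H = 113 this yields bounds 170, 283, 396 and 509: windows in
#' [0, 170], [171, 283], [284, 396], [397, 509] and [>= 510] are classed
#' haplotig, diplotig, triplotig, tetraplotig and replotig.
#'
#' @param H genome-wide somatic depth per haplotype (x), > 0.
#' @param nClasses number of copy classes (default 4).
#' @return numeric vector of \code{nClasses} upper bounds.
#' @examples
#' classBounds(113)   # 170 283 396 509
#' @export
classBounds <- function(H, nClasses = 4L) {
  if (!is.numeric(H) || length(H) != 1 || H <= 0)
    stop("H must be a single positive depth")
  roundHalfUp(H * (seq_len(nClasses) + 0.5))
}

#' Classify depth windows into copy-number classes
#'
#' Assigns each window the copy class implied by its mean depth and the
#' [classBounds()] of H: class \eqn{i} covers (bound[i-1], bound[i]] with
#' class 1 starting at 0; depths above the last bound are "REP"
#' (repetitive/replotig).
#'
#' @param windows GRanges with a \code{depth} metadata column (x coverage),
#'   or a data.frame with contig_id/start/end/depth (0-based half-open).
#' @param H per-haplotype depth.
#' @param nClasses number of copy classes (default 4).
#' @return the windows GRanges with an added \code{copyClass} factor with
#'   levels "1".."4","REP".
#' @export
classifyWindows <- function(windows, H, nClasses = 4L) {
  if (is.data.frame(windows)) windows <- windowsToGRanges(windows)
  depth <- mcols(windows)$depth
  if (is.null(depth)) stop("windows must carry a 'depth' column")
  if (any(depth < 0)) stop("negative window depth")
  bounds <- classBounds(H, nClasses)
  cls <- cut(depth, breaks = c(-Inf, bounds, Inf),
             labels = c(as.character(seq_len(nClasses)), "REP"),
             right = TRUE)
  mcols(windows)$copyClass <- factor(cls,
                                     levels = c(as.character(seq_len(nClasses)),
                                                "REP"))
  windows
}

windowsToGRanges <- function(df) {
  need <- c("contig_id", "start", "end", "depth")
  if (!all(need %in% names(df)))
    stop("window data.frame needs columns: ", paste(need, collapse = ", "))
  if (any(df$end <= df$start)) stop("window end must exceed start")
  GRanges(df$contig_id, IRanges(df$start + 1, df$end), depth = df$depth)
}

#' Merge same-class windows into coverage markers
#'
#' Maximal runs of adjacent same-class windows along a contig are merged
#' and cut into chunks of \code{markerBp}; a trailing remainder shorter
#' than \code{markerBp/2} is merged into the previous chunk (keeping
#' marker sizes near the target so the per-gamete read signal stays
#' comparable), otherwise it becomes its own marker. Runs shorter than
#' \code{markerBp} yield a single marker of the run length.
#'
#' @param windows classified windows from [classifyWindows()].
#' @param markerBp target marker size in bp (default 50000).
#' @return GRanges of coverage markers with metadata columns
#'   \code{copyClass} and \code{W} (marker length in bp), named
#'   \code{contig:start0-end0}.
#' @export
mergeToMarkers <- function(windows, markerBp = 50000) {
  cls <- mcols(windows)$copyClass
  if (is.null(cls)) stop("windows must be classified first")
  ctg <- as.character(seqnames(windows))
  o <- order(ctg, start(windows))
  if (!identical(o, seq_along(windows)))
    windows <- windows[o]
  ctg <- as.character(seqnames(windows))
  st <- start(windows); en <- end(windows)
  cls <- as.character(mcols(windows)$copyClass)
  n <- length(windows)
  if (n == 0) stop("no windows to merge")
  if (n > 1) {
    same <- ctg[-1] == ctg[-n]
    if (any(same & st[-1] <= en[-n]))
      stop("windows overlap or are unsorted within a contig")
  }
  newRun <- c(TRUE,
              ctg[-1] != ctg[-n] | cls[-1] != cls[-n] | st[-1] != en[-n] + 1)
  runStart <- st[newRun]
  runEnd <- en[c(which(newRun)[-1] - 1L, n)]
  runCtg <- ctg[newRun]
  runCls <- cls[newRun]

  outCtg <- outSt <- outEn <- outCls <- vector("list", length(runStart))
  for (i in seq_along(runStart)) {
    brk <- chunkRun(runStart[i], runEnd[i], markerBp)
    outCtg[[i]] <- rep(runCtg[i], nrow(brk))
    outSt[[i]] <- brk[, 1]; outEn[[i]] <- brk[, 2]
    outCls[[i]] <- rep(runCls[i], nrow(brk))
  }
  gr <- GRanges(unlist(outCtg), IRanges(unlist(outSt), unlist(outEn)))
  mcols(gr)$copyClass <- factor(unlist(outCls), levels = levels(
    mcols(windows)$copyClass))
  mcols(gr)$W <- width(gr)
  names(gr) <- sprintf("%s:%d-%d", as.character(seqnames(gr)),
                       start(gr) - 1L, end(gr))
  gr
}

# cut a run [st, en] (1-based closed) into markerBp chunks; trailing
# remainder < markerBp/2 merges into the previous chunk
chunkRun <- function(st, en, markerBp) {
  len <- en - st + 1
  if (len <= markerBp) return(cbind(st, en))
  nFull <- floor(len / markerBp)
  rem <- len - nFull * markerBp
  starts <- st + (seq_len(nFull) - 1) * markerBp
  ends <- starts + markerBp - 1
  if (rem == 0) {
    # nothing trailing
  } else if (rem < markerBp / 2) {
    ends[nFull] <- en
  } else {
    starts <- c(starts, ends[nFull] + 1)
    ends <- c(ends, en)
  }
  cbind(starts, ends)
}
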