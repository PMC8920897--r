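#' @importFrom tools md5sum
NULL

# TSV dialect: tab-separated, '#' comments, CRLF tolerated, all genomic
# coordinates 0-based half-open
readTsv <- function(path) {
  lines <- gsub("\r$", "", readLines(path))
  lines <- lines[!grepl("^#", lines)]
  if (!length(lines)) stop("empty table: ", path)
  con <- textConnection(lines)
  on.exit(close(con))
  tryCatch(
    read.delim(con, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("malformed TSV ", path, ": ",
                             conditionMessage(e)))
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write per-window depth tables
#'
#' BED-like TSV with columns contig_id, start, end, depth; coordinates
#' 0-based half-open (pass \code{oneBased = TRUE} for 1-based inclusive
#' input, converted on read).
#'
#' @param path file path.
#' @param oneBased input is 1-based inclusive (start - 1 applied).
#' @return GRanges with a \code{depth} column.
#' @export
readWindowDepths <- function(path, oneBased = FALSE) {
  df <- readTsv(path)
  checkCols(df, c("contig_id", "start", "end", "depth"), path)
  if (oneBased) df$start <- df$start - 1
  windowsToGRanges(df)
}

#' @rdname readWindowDepths
#' @param windows GRanges with \code{depth}.
#' @export
writeWindowDepths <- function(windows, path) {
  writeTsv(data.frame(contig_id = as.character(seqnames(windows)),
                      start = start(windows) - 1L,
                      end = end(windows),
                      depth = mcols(windows)$depth), path)
}

#' Read and write coverage-marker tables
#'
#' TSV with columns contig_id, start, end, copy_class, W (0-based
#' half-open).
#'
#' @param path file path.
#' @return GRanges with \code{copyClass} and \code{W}.
#' @export
readMarkers <- function(path) {
  df <- readTsv(path)
  checkCols(df, c("contig_id", "start", "end", "copy_class", "W"), path)
  gr <- GRanges(df$contig_id, IRanges(df$start + 1, df$end))
  mcols(gr)$copyClass <- factor(as.character(df$copy_class),
                                levels = c("1", "2", "3", "4", "REP"))
  mcols(gr)$W <- df$W
  names(gr) <- sprintf("%s:%d-%d", df$contig_id, df$start, df$end)
  gr
}

#' @rdname readMarkers
#' @param markers marker GRanges.
#' @export
writeMarkers <- function(markers, path) {
  writeTsv(data.frame(contig_id = as.character(seqnames(markers)),
                      start = start(markers) - 1L,
                      end = end(markers),
                      copy_class = as.character(mcols(markers)$copyClass),
                      W = mcols(markers)$W), path)
}

#' Read and write marker-by-gamete count matrices
#'
#' TSV with a \code{marker_id} column followed by one integer column per
#' gamete.
#'
#' @param path file path.
#' @return integer matrix with marker rownames and gamete colnames.
#' @export
readCountsMatrix <- function(path) {
  df <- readTsv(path)
  if (names(df)[1] != "marker_id") stop("first column must be marker_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$marker_id
  storage.mode(m) <- "integer"
  m
}

#' @rdname readCountsMatrix
#' @param counts integer matrix markers x gametes.
#' @export
writeCountsMatrix <- function(counts, path) {
  writeTsv(data.frame(marker_id = rownames(counts), counts,
                      check.names = FALSE), path)
}

#' Write a PAP (genotype) matrix with marker classes
#'
#' @param paps a [PapSet-class].
#' @param path file path.
#' @export
writePapMatrix <- function(paps, path) {
  writeTsv(data.frame(marker_id = rownames(paps),
                      copy_class = markerClasses(paps),
                      papGenotypes(paps), check.names = FALSE), path)
}

#' Write per-gamete normalizer statistics (N, m_r)
#'
#' @param paps a [PapSet-class].
#' @param path file path.
#' @export
writeGameteStats <- function(paps, path) {
  writeTsv(gameteStats(paps), path)
}

#' Read and write grouping tables
#'
#' One TSV holding both single assignments of haplotigs and
#' multi-assignments of collapsed contigs (column \code{assignment});
#' chromosome ids joined from the homology map.
#'
#' @param grouping a [HaplotypeGrouping-class].
#' @param path file path.
#' @export
writeGrouping <- function(grouping, path) {
  cg <- grouping@contigGroups
  cm <- grouping@chromosomeMap
  single <- data.frame(contig_id = cg$contig_id, group_id = cg$group_id,
                       assignment = cg$method, rank = 1L,
                       confidence = cg$confidence, flag = cg$flag,
                       stringsAsFactors = FALSE)
  ma <- grouping@multiAssignments
  multi <- data.frame(contig_id = ma$contig_id, group_id = ma$group_id,
                      assignment = "multicopy", rank = ma$rank,
                      confidence = ma$score, flag = ma$flag,
                      stringsAsFactors = FALSE)
  out <- rbind(single, multi)
  out$chromosome_id <- cm$chromosome_id[match(out$group_id, cm$group_id)]
  writeTsv(out, path)
}

#' @rdname writeGrouping
#' @return \code{readGrouping}: a [HaplotypeGrouping-class] (without the
#'   linkage-graph edge dump).
#' @export
readGrouping <- function(path) {
  df <- readTsv(path)
  checkCols(df, c("contig_id", "group_id", "assignment", "rank",
                  "confidence", "flag", "chromosome_id"), path)
  df$flag[is.na(df$flag)] <- ""
  sg <- df[df$assignment %in% c("graph", "rescued"), , drop = FALSE]
  ma <- df[df$assignment == "multicopy", , drop = FALSE]
  cm <- unique(df[!is.na(df$chromosome_id),
                  c("group_id", "chromosome_id")])
  cm <- cm[order(cm$group_id), ]
  rownames(cm) <- NULL
  new("HaplotypeGrouping",
      contigGroups = data.frame(contig_id = sg$contig_id,
                                group_id = sg$group_id,
                                confidence = sg$confidence,
                                method = sg$assignment, flag = sg$flag,
                                stringsAsFactors = FALSE),
      multiAssignments = data.frame(contig_id = ma$contig_id,
                                    group_id = ma$group_id,
                                    rank = ma$rank, score = ma$confidence,
                                    flag = ma$flag,
                                    stringsAsFactors = FALSE),
      chromosomeMap = cm,
      edges = data.frame(from = character(0), to = character(0),
                         weight = numeric(0)),
      params = list())
}

#' Read and write long-read alignment summaries
#'
#' PAF-like TSV: read_id, contig_id, start, end (0-based half-open),
#' aligned_bp.
#'
#' @param path file path.
#' @param oneBased input is 1-based inclusive.
#' @return data.frame of alignment records.
#' @export
readReadAlignments <- function(path, oneBased = FALSE) {
  df <- readTsv(path)
  checkCols(df, c("read_id", "contig_id", "start", "end", "aligned_bp"),
            path)
  if (oneBased) df$start <- df$start - 1
  df
}

#' @rdname readReadAlignments
#' @param records alignment record data.frame.
#' @export
writeReadAlignments <- function(records, path) {
  writeTsv(records, path)
}

#' Write haplotype FASTA
#'
#' One record per haplotype-chromosome, named \code{chr{c}_hap{h}}.
#'
#' @param genome a [TruthGenome-class] in sequence mode.
#' @param path file path.
#' @export
writeHaplotypeFasta <- function(genome, path) {
  seqs <- haplotypeSequences(genome)
  if (is.null(seqs)) stop("genome has no sequences (counts mode)")
  writeXStringSet(seqs, path)
  invisible(path)
}

#' Write simulator truth tables
#'
#' \code{writeContigTruth}: contig_id, chrom, start, end, haplotype_set;
#' \code{writeGameteTruth}: per-mosaic intervals of every gamete. All
#' coordinates 0-based half-open.
#'
#' @param genome a [TruthGenome-class].
#' @param path file path.
#' @export
writeContigTruth <- function(genome, path) {
  ctg <- contigTruth(genome)
  writeTsv(data.frame(contig_id = ctg$contig_id, chrom = ctg$chrom,
                      start = ctg$start, end = ctg$end,
                      haplotype_set = ctg$haps), path)
}

#' @rdname writeContigTruth
#' @param gametes a [GameteSet-class].
#' @export
writeGameteTruth <- function(gametes, path) {
  writeTsv(gameteSegments(gametes), path)
}

checkCols <- function(df, need, path) {
  if (!all(need %in% names(df)))
    stop(path, ": missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  invisible(TRUE)
}

#' Write a JSON run manifest
#'
#' Records parameters, seed, package version and md5 digests of the
#' stage's input and output files so any result can be traced to its
#' provenance.
#'
#' @param path manifest path.
#' @param stage stage name.
#' @param params named list of parameters.
#' @param inputs,outputs character vectors of file paths.
#' @export
writeRunManifest <- function(path, stage, params, inputs = character(0),
                             outputs = character(0)) {
  digest <- function(fs) {
    fs <- fs[file.exists(fs)]
    as.list(md5sum(fs))
  }
  obj <- list(stage = stage,
              package = "polygamete",
              version = as.character(utils::packageVersion("polygamete")),
              timestamp = format(Sys.time(), tz = "UTC"),
              params = params,
              inputs = digest(inputs),
              outputs = digest(outputs))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
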