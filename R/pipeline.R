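#' Run the full gamete-binning pipeline on a simulated genome
#'
#' Chains all stages end to end: simulate genome and gametes, simulate
#' somatic window depths, classify windows and merge coverage markers,
#' simulate gamete read counts and build PAPs, cluster contigs into
#' haplotype groups, simulate and bin long reads, and evaluate
#' marker-level phasing precision against the simulator truth. Every
#' stage writes its TSV artifact plus a JSON manifest into \code{outdir};
#' all randomness derives from \code{config@seed}, so a rerun with the
#' same configuration is byte-identical.
#'
#' @param config a [SimConfig-class].
#' @param outdir output directory (created if missing).
#' @param nReads number of simulated long reads for the binning stage
#'   (default 20000; 0 skips the stage).
#' @param readBp simulated long-read length (default 15000).
#' @param thetaLink,thetaHom,minHaplotigBp clustering parameters.
#' @param minOverlapBp read-binning overlap floor (default 500).
#' @param minInformative minimum informative markers per usable gamete
#'   (default 50; lower it for toy genomes with few markers).
#' @param evaluate run the truth-based evaluation stage (default TRUE).
#' @return (invisibly) a list with the stage objects: genome, gametes,
#'   windows, markers, paps, grouping, binning, report, and the paths of
#'   all written files.
#' @export
runPipeline <- function(config, outdir, nReads = 20000, readBp = 15000,
                        thetaLink = 0.55, thetaHom = -0.25,
                        minHaplotigBp = 1e5, minOverlapBp = 500,
                        minInformative = 50, evaluate = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outdir, f)
  stageFail <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", stage, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  files <- character(0)
  stages <- character(0)

  message("[simulate] genome + gametes (seed ", config@seed, ")")
  genome <- stageFail("simulate", simulateGenome(config))
  gametes <- stageFail("simulate", simulateGametes(genome, config))
  writeContigTruth(genome, pth("contig_truth.tsv"))
  writeGameteTruth(gametes, pth("gamete_truth.tsv"))
  if (config@mode == "sequence")
    writeHaplotypeFasta(genome, pth("haplotypes.fa"))
  files <- c(files, pth("contig_truth.tsv"), pth("gamete_truth.tsv"))
  stages <- c(stages, "simulate")

  message("[type-depth] windows + coverage markers")
  windows <- stageFail("type-depth", simulateWindowDepths(genome, config))
  windows <- classifyWindows(windows, config@somaticDepthPerHaplotype)
  markers <- mergeToMarkers(windows, config@markerBp)
  writeWindowDepths(windows, pth("windows.tsv"))
  writeMarkers(markers, pth("markers.tsv"))
  clsBp <- tapply(mcols(markers)$W, mcols(markers)$copyClass, sum)
  clsBp[is.na(clsBp)] <- 0
  message("  marker bp by class: ",
          paste(names(clsBp), format(clsBp), sep = "=", collapse = " "))
  files <- c(files, pth("windows.tsv"), pth("markers.tsv"))
  stages <- c(stages, "type-depth")

  message("[build-paps] gamete counts + PAP matrix")
  counts <- stageFail("build-paps",
                      simulateMarkerCounts(genome, gametes, markers, config))
  paps <- stageFail("build-paps",
                    buildPapMatrix(counts, markers,
                                   minInformative = minInformative))
  writeCountsMatrix(counts, pth("counts.tsv"))
  writePapMatrix(paps, pth("paps.tsv"))
  writeGameteStats(paps, pth("gamete_stats.tsv"))
  files <- c(files, pth("counts.tsv"), pth("paps.tsv"),
             pth("gamete_stats.tsv"))
  stages <- c(stages, "build-paps")

  message("[cluster] linkage grouping")
  grouping <- stageFail("cluster",
                        clusterContigs(paps, thetaLink, thetaHom,
                                       minHaplotigBp))
  writeGrouping(grouping, pth("grouping.tsv"))
  writeTsv(grouping@edges, pth("linkage_edges.tsv"))
  message("  groups: ", nGroups(grouping), " | chromosomes: ",
          length(unique(grouping@chromosomeMap$chromosome_id)))
  files <- c(files, pth("grouping.tsv"), pth("linkage_edges.tsv"))
  stages <- c(stages, "cluster")

  binning <- NULL
  if (nReads > 0) {
    message("[bin-reads] ", nReads, " simulated reads")
    records <- stageFail("bin-reads",
                         simulateReadAlignments(genome, nReads, readBp))
    writeReadAlignments(records, pth("read_alignments.tsv"))
    binning <- stageFail("bin-reads",
                         binReads(records, grouping, markers,
                                  minOverlapBp = minOverlapBp,
                                  seed = config@seed))
    writeTsv(binning$assignments, pth("read_assignments.tsv"))
    writeTsv(binning$summary, pth("read_summary.tsv"))
    message("  assigned fraction: ",
            sprintf("%.4f", binning$assignedFraction))
    files <- c(files, pth("read_alignments.tsv"),
               pth("read_assignments.tsv"), pth("read_summary.tsv"))
    stages <- c(stages, "bin-reads")
  }

  report <- NULL
  if (evaluate) {
    message("[evaluate] marker-level phasing precision")
    report <- stageFail("evaluate",
                        markerPhasingReport(grouping, genome, paps))
    writeTsv(reportTable(report), pth("phasing_report.tsv"))
    message("  precision: ", sprintf("%.4f", phasingPrecision(report)))
    files <- c(files, pth("phasing_report.tsv"))
    stages <- c(stages, "evaluate")
  }

  writeRunManifest(pth("manifest.json"), stage = "phase",
                   params = list(
                     seed = config@seed,
                     nChromosomes = config@nChromosomes,
                     chromLengthBp = config@chromLengthBp,
                     nGametes = config@nGametes,
                     gameteCoverage = config@gameteCoverage,
                     H = config@somaticDepthPerHaplotype,
                     thetaLink = thetaLink, thetaHom = thetaHom,
                     minHaplotigBp = minHaplotigBp,
                     minOverlapBp = minOverlapBp,
                     nReads = nReads, readBp = readBp,
                     completedStages = stages),
                   outputs = files)
  invisible(list(genome = genome, gametes = gametes, windows = windows,
                 markers = markers, paps = paps, grouping = grouping,
                 binning = binning, report = report,
                 files = c(files, pth("manifest.json"))))
}
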