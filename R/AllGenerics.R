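#' @rdname TruthGenome-class
#' @param x,object a package object.
#' @export
setGeneric("contigTruth", function(x) standardGeneric("contigTruth"))

#' @rdname TruthGenome-class
#' @export
setGeneric("ibdBlocks", function(x) standardGeneric("ibdBlocks"))

#' @rdname TruthGenome-class
#' @export
setGeneric("haplotypeSequences",
           function(x) standardGeneric("haplotypeSequences"))

#' @rdname TruthGenome-class
#' @export
setGeneric("parentLabels", function(x) standardGeneric("parentLabels"))

#' @rdname TruthGenome-class
#' @export
setGeneric("realizedIbdFraction",
           function(x) standardGeneric("realizedIbdFraction"))

#' @rdname GameteSet-class
#' @export
setGeneric("gameteSegments", function(x) standardGeneric("gameteSegments"))

#' @rdname GameteSet-class
#' @export
setGeneric("crossoverTable", function(x) standardGeneric("crossoverTable"))

#' @rdname PapSet-class
#' @export
setGeneric("papGenotypes", function(x) standardGeneric("papGenotypes"))

#' @rdname PapSet-class
#' @export
setGeneric("papCounts", function(x) standardGeneric("papCounts"))

#' @rdname PapSet-class
#' @export
setGeneric("gameteStats", function(x) standardGeneric("gameteStats"))

#' @rdname PapSet-class
#' @export
setGeneric("markerClasses", function(x) standardGeneric("markerClasses"))

#' @rdname HaplotypeGrouping-class
#' @export
setGeneric("groupAssignments",
           function(x) standardGeneric("groupAssignments"))

#' @rdname HaplotypeGrouping-class
#' @export
setGeneric("multiAssignments",
           function(x) standardGeneric("multiAssignments"))

#' @rdname HaplotypeGrouping-class
#' @export
setGeneric("chromosomeMap", function(x) standardGeneric("chromosomeMap"))

#' @rdname HaplotypeGrouping-class
#' @export
setGeneric("linkageEdges", function(x) standardGeneric("linkageEdges"))

#' @rdname HaplotypeGrouping-class
#' @export
setGeneric("nGroups", function(x) standardGeneric("nGroups"))

#' @rdname PhasingReport-class
#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))
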