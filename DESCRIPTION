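Package: polygamete
Title: Gamete Binning for Haplotype Phasing of Autotetraploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Haplotype phasing of autotetraploid genome assemblies by gamete
    binning. Contig windows are classified into copy-number classes from
    somatic sequencing depth and merged into coverage markers; per-gamete
    read counts at the markers are normalized and rounded into
    presence/absence patterns (PAPs) across hundreds of low-coverage diploid
    gamete (pollen) genomes; haplotigs are clustered into haplotype linkage
    groups by PAP correlation, homologous groups are joined into chromosomes
    by anticorrelation, collapsed contigs are multi-assigned via a bitwise
    AND rule, and long reads are binned into haplotype-specific read sets.
    Phasing precision is evaluated trio-style from parent-specific k-mers or
    parent-labeled markers. A seeded simulator of tetraploid genomes with
    identical-by-descent blocks, meiotic crossovers and Poisson-sampled
    gamete read counts makes the whole pipeline exercisable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
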