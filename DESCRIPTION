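Package: methylWindows
Title: Window-Based Differential Methylation Analysis for Whole-Genome
    Bisulfite Sequencing
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for whole-genome bisulfite sequencing (WGBS) differential
    methylation analysis between two groups of replicated methylomes.
    Implements per-site methylation levels, genome-wide and seven-region
    metagene summaries in CG, CHG and CHH contexts, differentially
    methylated region (DMR) calling on non-overlapping five-cytosine
    windows by Fisher's exact test with a twofold level-change filter and
    a span-level neighbor-merging rule, promoter and gene-body annotation
    of differentially methylated genes (DMGs) with hyper/hypo direction,
    hypergeometric gene-set over-representation with Bonferroni
    correction, and relative transcript quantification by the comparative
    Ct (2^-ddCt) method. A seeded simulator generates toy annotations and
    paired-group methylomes with planted DMRs so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
biocViews: DNAMethylation, DifferentialMethylation, Epigenetics,
    Sequencing, Coverage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
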