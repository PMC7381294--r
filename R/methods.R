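#' Construct a MethylomeSample from site vectors
#'
#' Low-level constructor used by the reader and the simulator. Sites are
#' sorted by (chromosome, position, strand); duplicate keys are an
#' error.
#'
#' @param chrom,pos,strand,context,n_meth,n_unmeth parallel site vectors.
#' @param sampleId sample label.
#' @param group `"reference"` or `"treatment"`.
#' @return a [MethylomeSample-class].
#' @examples
#' methylomeSample(chrom = "chr1", pos = c(10, 20), strand = "+",
#'                 context = "CG", n_meth = c(8, 0), n_unmeth = c(2, 5),
#'                 sampleId = "s1", group = "reference")
#' @export
methylomeSample <- function(chrom = character(), pos = integer(),
                            strand = character(), context = character(),
                            n_meth = integer(), n_unmeth = integer(),
                            sampleId = "sample", group = "reference") {
    n <- length(pos)
    gr <- GenomicRanges::GRanges(
        seqnames = rep_len(as.character(chrom), n),
        ranges = IRanges::IRanges(start = as.integer(pos), width = 1L),
        strand = rep_len(as.character(strand), n))
    mcols(gr)$n_meth <- as.integer(rep_len(n_meth, n))
    mcols(gr)$n_unmeth <- as.integer(rep_len(n_unmeth, n))
    mcols(gr)$context <- rep_len(as.character(context), n)
    o <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr),
               as.character(GenomicRanges::strand(gr)))
    gr <- gr[o]
    new("MethylomeSample", gr, sampleId = as.character(sampleId),
        group = match.arg(group, .GROUPS))
}

#' @rdname MethylomeSample-class
#' @export
setMethod("sampleId", "MethylomeSample", function(object) object@sampleId)

#' @rdname MethylomeSample-class
#' @export
setMethod("sampleGroup", "MethylomeSample", function(object) object@group)

setMethod("show", "MethylomeSample", function(object) {
    cov <- mcols(object)$n_meth + mcols(object)$n_unmeth
    cat(sprintf("MethylomeSample '%s' (%s): %d cytosine sites\n",
                object@sampleId, object@group, length(object)))
    if (length(object)) {
        tab <- table(factor(mcols(object)$context, levels = .CONTEXTS))
        cat(sprintf("  sites per context: CG %d, CHG %d, CHH %d\n",
                    tab["CG"], tab["CHG"], tab["CHH"]))
        cat(sprintf("  covered sites (depth >= 1): %d; median depth %.0f\n",
                    sum(cov > 0L), stats::median(cov)))
    }
    invisible(object)
})

#' Construct a GeneModels object
#'
#' @param genes a named [GenomicRanges::GRanges] of transcript spans
#'   (names are gene ids, strand `+`/`-`).
#' @param exons a [GenomicRanges::GRangesList] parallel to `genes`.
#' @return a [GeneModels-class].
#' @export
geneModels <- function(genes, exons) {
    if (is.list(exons)) exons <- GenomicRanges::GRangesList(exons)
    new("GeneModels", genes = genes, exons = exons)
}

#' @rdname GeneModels-class
#' @export
setMethod("geneIds", "GeneModels", function(object) names(object@genes))

#' @rdname GeneModels-class
#' @export
setMethod("geneRanges", "GeneModels", function(object) object@genes)

#' @rdname GeneModels-class
#' @export
setMethod("exonRanges", "GeneModels", function(object) object@exons)

#' @rdname GeneModels-class
#' @param x a `GeneModels`.
#' @export
setMethod("length", "GeneModels", function(x) length(x@genes))

setMethod("show", "GeneModels", function(object) {
    n_ex <- S4Vectors::elementNROWS(object@exons)
    cat(sprintf("GeneModels: %d genes", length(object)))
    if (length(object))
        cat(sprintf(" on %d chromosome(s); exons per gene %d-%d",
                    length(unique(as.character(
                        GenomicRanges::seqnames(object@genes)))),
                    min(n_ex), max(n_ex)))
    cat("\n")
    invisible(object)
})

#' @rdname GeneRegionIndex-class
#' @export
setMethod("promoterRanges", "GeneRegionIndex",
          function(object) object@promoters)

#' @rdname GeneRegionIndex-class
#' @export
setMethod("geneBodyRanges", "GeneRegionIndex",
          function(object) object@geneBodies)

setMethod("show", "GeneRegionIndex", function(object) {
    cat(sprintf("GeneRegionIndex: %d genes, promoter_bp = %d\n",
                length(object@promoters), as.integer(object@promoterBp)))
    invisible(object)
})

#' Parameters for the window DMR caller
#'
#' @param windowSites,minFold,alpha,minDepth,pseudocount,maxMergeGap,fdr
#'   see [DmrParams-class]. Defaults encode the five-site / twofold /
#'   p <= 0.05 rule with unlimited-distance merging and raw p-values.
#' @return a validated [DmrParams-class].
#' @examples
#' dmrParams()
#' dmrParams(minDepth = 10, maxMergeGap = 1000)
#' @export
dmrParams <- function(windowSites = 5L, minFold = 2, alpha = 0.05,
                      minDepth = 4L, pseudocount = 0.5,
                      maxMergeGap = Inf, fdr = FALSE) {
    new("DmrParams", windowSites = as.integer(windowSites),
        minFold = as.numeric(minFold), alpha = as.numeric(alpha),
        minDepth = as.integer(minDepth),
        pseudocount = as.numeric(pseudocount),
        maxMergeGap = as.numeric(maxMergeGap), fdr = isTRUE(fdr))
}

setMethod("show", "DmrParams", function(object) {
    cat(sprintf(paste0("DmrParams: %d-site windows, fold >= %.2g, ",
                       "p <= %.3g (%s), min depth %d/group, ",
                       "pseudocount %.2g, merge gap %s\n"),
                object@windowSites, object@minFold, object@alpha,
                if (object@fdr) "BH-adjusted" else "raw",
                object@minDepth, object@pseudocount,
                if (is.infinite(object@maxMergeGap)) "unlimited"
                else sprintf("<= %d bp", as.integer(object@maxMergeGap))))
    invisible(object)
})
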