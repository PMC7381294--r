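#' @import methods
#' @import GenomicRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom IRanges IRanges
NULL

.CONTEXTS <- c("CG", "CHG", "CHH")
.GROUPS   <- c("reference", "treatment")

#' MethylomeSample: one sample's per-cytosine methylation counts
#'
#' A `MethylomeSample` is a [GenomicRanges::GRanges] of width-1 cytosine
#' sites carrying, for every site, the number of reads reporting
#' methylation (`n_meth`, the Nm of the level formula), the number of
#' reads reporting non-methylation (`n_unmeth`, Nnm), and the sequence
#' context (`CG`, `CHG` or `CHH`, where H is A, C or T). The `+` and `-`
#' cytosines of a CpG dyad are independent sites and are never collapsed.
#' Sites are kept sorted by (chromosome, position, strand) with no
#' duplicate keys; zero-coverage sites are retained (they carry position
#' information) but excluded from all statistics.
#'
#' @slot sampleId single character label for the sample.
#' @slot group `"reference"` or `"treatment"`.
#'
#' @seealso [readCytosineReport()], [globalSummary()], [callDmrs()]
#' @export
setClass("MethylomeSample",
    contains = "GRanges",
    representation(sampleId = "character", group = "character"))

setValidity("MethylomeSample", function(object) {
    msg <- character()
    if (length(object@sampleId) != 1L)
        msg <- c(msg, "'sampleId' must be a single string")
    if (length(object@group) != 1L || !object@group %in% .GROUPS)
        msg <- c(msg, "'group' must be 'reference' or 'treatment'")
    mc <- mcols(object)
    need <- c("n_meth", "n_unmeth", "context")
    if (!all(need %in% colnames(mc))) {
        msg <- c(msg, sprintf("metadata columns %s are required",
                              paste(need, collapse = ", ")))
        return(if (length(msg)) msg else TRUE)
    }
    if (length(object)) {
        if (any(GenomicRanges::width(object) != 1L))
            msg <- c(msg, "all sites must have width 1")
        if (any(as.character(GenomicRanges::strand(object)) == "*"))
            msg <- c(msg, "every site needs an explicit strand (+/-)")
        if (any(mc$n_meth < 0L) || any(mc$n_unmeth < 0L))
            msg <- c(msg, "counts must be non-negative")
        if (!all(mc$context %in% .CONTEXTS))
            msg <- c(msg, "context must be one of CG, CHG, CHH")
        key <- paste(GenomicRanges::seqnames(object),
                     GenomicRanges::start(object),
                     GenomicRanges::strand(object))
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate (chrom, pos, strand) site keys")
        o <- order(as.character(GenomicRanges::seqnames(object)),
                   GenomicRanges::start(object),
                   as.character(GenomicRanges::strand(object)))
        if (!identical(o, seq_along(object)))
            msg <- c(msg, "sites must be sorted by (chrom, pos, strand)")
    }
    if (length(msg)) msg else TRUE
})

#' GeneModels: a set of single-transcript gene models
#'
#' One model per gene: the transcript span (1-based inclusive) and its
#' exons, sorted by genomic position, each exon within the span. For
#' multi-transcript annotations the longest transcript represents the
#' gene. Used for the seven-region metagene partition and for
#' promoter/gene-body DMG annotation.
#'
#' @slot genes [GenomicRanges::GRanges] of transcript spans; names are
#'   gene identifiers.
#' @slot exons [GenomicRanges::GRangesList] parallel to `genes`, one
#'   element per gene, exons sorted by genomic position.
#' @export
setClass("GeneModels",
    representation(genes = "GRanges", exons = "GRangesList"))

setValidity("GeneModels", function(object) {
    msg <- character()
    g <- object@genes
    e <- object@exons
    if (length(g) != length(e))
        msg <- c(msg, "'genes' and 'exons' must be parallel")
    if (length(g) && is.null(names(g)))
        msg <- c(msg, "'genes' must be named by gene id")
    if (length(g) && anyDuplicated(names(g)))
        msg <- c(msg, "duplicate gene ids")
    if (length(g)) {
        n_ex <- S4Vectors::elementNROWS(e)
        if (any(n_ex < 1L))
            msg <- c(msg, "every gene needs at least one exon")
        for (i in seq_along(g)) {
            ex <- e[[i]]
            if (any(GenomicRanges::start(ex) < GenomicRanges::start(g)[i]) ||
                any(GenomicRanges::end(ex) > GenomicRanges::end(g)[i])) {
                msg <- c(msg, sprintf("exon outside transcript bounds for gene '%s'",
                                      names(g)[i]))
                break
            }
            if (is.unsorted(GenomicRanges::start(ex))) {
                msg <- c(msg, sprintf("exons of gene '%s' are not position-sorted",
                                      names(g)[i]))
                break
            }
        }
    }
    if (length(msg)) msg else TRUE
})

#' GeneRegionIndex: promoter and gene-body intervals for DMG assignment
#'
#' Strand-aware promoters (a `promoterBp`-long interval ending at the
#' TSS) and gene bodies (TSS..TES, exon/intron-agnostic), clipped at
#' position 1. Built by [buildRegionIndex()] and consumed by
#' [assignDmgs()].
#'
#' @slot promoters [GenomicRanges::GRanges] named by gene id.
#' @slot geneBodies [GenomicRanges::GRanges] named by gene id.
#' @slot promoterBp promoter length in bp.
#' @export
setClass("GeneRegionIndex",
    representation(promoters = "GRanges", geneBodies = "GRanges",
                   promoterBp = "numeric"))

setValidity("GeneRegionIndex", function(object) {
    msg <- character()
    if (length(object@promoters) != length(object@geneBodies))
        msg <- c(msg, "'promoters' and 'geneBodies' must be parallel")
    if (length(object@promoterBp) != 1L || object@promoterBp < 1)
        msg <- c(msg, "'promoterBp' must be a single value >= 1")
    if (length(object@promoters) &&
        any(GenomicRanges::start(object@promoters) < 1L))
        msg <- c(msg, "promoter starts must be clipped at 1")
    if (length(msg)) msg else TRUE
})

#' DmrParams: parameters of the window DMR caller
#'
#' Defaults encode the published rule: windows of five same-context
#' cytosine sites, at least a twofold change in pooled methylation level,
#' Fisher exact p <= 0.05, and unlimited-distance joining of neighboring
#' same-direction DMRs whenever the joined span itself shows a twofold
#' change.
#'
#' @slot windowSites sites per window (>= 2; default 5).
#' @slot minFold minimum fold change on pseudocounted levels (> 1;
#'   default 2).
#' @slot alpha Fisher p-value gate (default 0.05). Inclusive: p <= alpha.
#' @slot minDepth minimum pooled reads per site per group for a site to
#'   be eligible (default 4).
#' @slot pseudocount added to methylated and unmethylated counts when
#'   forming the fold-change ratio (default 0.5, Jeffreys).
#' @slot maxMergeGap maximum gap in bp between neighboring DMRs for the
#'   joining rule; `Inf` (default) imposes no distance limit.
#' @slot fdr if `TRUE`, gate windows on Benjamini-Hochberg adjusted
#'   p-values instead of raw p (off by default, matching the published
#'   raw-p rule).
#' @seealso [dmrParams()], [callDmrs()]
#' @export
setClass("DmrParams",
    representation(windowSites = "integer", minFold = "numeric",
                   alpha = "numeric", minDepth = "integer",
                   pseudocount = "numeric", maxMergeGap = "numeric",
                   fdr = "logical"))

setValidity("DmrParams", function(object) {
    msg <- character()
    if (object@windowSites < 2L)
        msg <- c(msg, "'windowSites' must be >= 2")
    if (object@minFold <= 1)
        msg <- c(msg, "'minFold' must be > 1")
    if (object@alpha <= 0 || object@alpha > 1)
        msg <- c(msg, "'alpha' must be in (0, 1]")
    if (object@minDepth < 1L)
        msg <- c(msg, "'minDepth' must be >= 1")
    if (object@pseudocount <= 0)
        msg <- c(msg, "'pseudocount' must be > 0")
    if (object@maxMergeGap < 0)
        msg <- c(msg, "'maxMergeGap' must be >= 0 (Inf for unlimited)")
    if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the synthetic methylome generator
#'
#' The generator emulates a two-group WGBS design of replicated animal
#' methylomes: CG sites methylated near 80 percent, CHG/CHH near 1
#' percent, a methylation dip around transcription start sites,
#' Poisson-distributed read depth, binomially sampled methylation calls
#' with a symmetric bisulfite conversion/sequencing error, and planted
#' differential regions spanning a configurable number of sites. One
#' seed fixes every random draw.
#'
#' @slot seed integer seed fixing all draws.
#' @slot nChroms,chromLengthBp genome shape.
#' @slot nGenes number of non-overlapping genes to place.
#' @slot exonsPerGene length-2 integer range of exon counts.
#' @slot siteDensity named sites-per-kbp per context.
#' @slot baselineLevels named true methylation level per context.
#' @slot tssDipHalfWidth,tssDipMultiplier the TSS dip: within the
#'   half-width of any TSS the true CG/CHG/CHH level is multiplied by
#'   the multiplier.
#' @slot depthMean Poisson mean read depth per site per replicate.
#' @slot conversionError probability a read reports the wrong
#'   methylation state (default 0.005, i.e. ~99.5 percent conversion).
#' @slot replicatesPerGroup methylomes per group (default 3).
#' @slot plantedDmrs data.frame with columns `context`, `n_sites`,
#'   `level_ref`, `level_trt`, `placement` (promoter | gene_body |
#'   intergenic).
#' @seealso [simulationConfig()], [simulateMethylomes()]
#' @export
setClass("SimulationConfig",
    representation(seed = "integer", nChroms = "integer",
                   chromLengthBp = "integer", nGenes = "integer",
                   exonsPerGene = "integer", siteDensity = "numeric",
                   baselineLevels = "numeric", tssDipHalfWidth = "integer",
                   tssDipMultiplier = "numeric", depthMean = "numeric",
                   conversionError = "numeric",
                   replicatesPerGroup = "integer",
                   plantedDmrs = "data.frame"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (!all(.CONTEXTS %in% names(object@siteDensity)))
        msg <- c(msg, "'siteDensity' needs entries for CG, CHG, CHH")
    if (!all(.CONTEXTS %in% names(object@baselineLevels)))
        msg <- c(msg, "'baselineLevels' needs entries for CG, CHG, CHH")
    lv <- object@baselineLevels
    if (any(lv < 0 | lv > 1))
        msg <- c(msg, "baseline levels must lie in [0, 1]")
    if (object@conversionError < 0 || object@conversionError >= 1)
        msg <- c(msg, "'conversionError' must lie in [0, 1)")
    if (object@tssDipMultiplier < 0 || object@tssDipMultiplier > 1)
        msg <- c(msg, "'tssDipMultiplier' must lie in [0, 1]")
    if (object@replicatesPerGroup < 1L)
        msg <- c(msg, "'replicatesPerGroup' must be >= 1")
    if (length(object@exonsPerGene) != 2L ||
        any(object@exonsPerGene < 1L) ||
        object@exonsPerGene[1] > object@exonsPerGene[2])
        msg <- c(msg, "'exonsPerGene' must be an increasing length-2 range >= 1")
    pd <- object@plantedDmrs
    if (nrow(pd)) {
        need <- c("context", "n_sites", "level_ref", "level_trt", "placement")
        if (!all(need %in% colnames(pd)))
            msg <- c(msg, sprintf("'plantedDmrs' needs columns %s",
                                  paste(need, collapse = ", ")))
        else {
            if (!all(pd$context %in% .CONTEXTS))
                msg <- c(msg, "planted DMR contexts must be CG/CHG/CHH")
            if (!all(pd$placement %in% c("promoter", "gene_body", "intergenic")))
                msg <- c(msg, "planted DMR placement must be promoter/gene_body/intergenic")
            if (any(pd$level_ref < 0 | pd$level_ref > 1 |
                    pd$level_trt < 0 | pd$level_trt > 1))
                msg <- c(msg, "planted DMR levels must lie in [0, 1]")
        }
    }
    if (length(msg)) msg else TRUE
})
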