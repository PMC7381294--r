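#' Build promoter and gene-body intervals for DMG assignment
#'
#' For a `+` strand gene with TSS t the promoter is
#' \[t - promoter_bp, t - 1\] and the body \[TSS, TES\]; for a `-`
#' strand gene the promoter mirrors to its TSS at the right end,
#' \[TES + 1, TES + promoter_bp\]. Promoters are clipped at position 1.
#' The gene body includes exons and introns.
#'
#' @param genes a [GeneModels-class].
#' @param promoter_bp promoter length in bp (default 2000).
#' @return a [GeneRegionIndex-class].
#' @export
buildRegionIndex <- function(genes, promoter_bp = 2000L) {
    stopifnot(is(genes, "GeneModels"), promoter_bp >= 1)
    g <- geneRanges(genes)
    minus <- as.character(GenomicRanges::strand(g)) == "-"
    s <- GenomicRanges::start(g); e <- GenomicRanges::end(g)
    pstart <- ifelse(minus, e + 1L, pmax(1L, s - as.integer(promoter_bp)))
    pend <- ifelse(minus, e + as.integer(promoter_bp), s - 1L)
    # a + strand gene starting at base 1 has no room upstream: keep a
    # zero-width placeholder so the index stays parallel to the genes
    degenerate <- pend < pstart
    pstart[degenerate] <- 1L
    pend[degenerate] <- 0L
    prom <- GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                                   IRanges::IRanges(start = pstart,
                                                    end = pend),
                                   strand = GenomicRanges::strand(g))
    names(prom) <- names(g)
    body <- GenomicRanges::granges(g)
    names(body) <- names(g)
    new("GeneRegionIndex", promoters = prom, geneBodies = body,
        promoterBp = as.numeric(promoter_bp))
}

#' Assign DMRs to genes as differentially methylated genes
#'
#' A DMR overlapping a promoter or gene body by at least 1 bp
#' contributes to that (gene, region class); a DMR straddling the TSS
#' contributes to both. Per (gene, region class, context) the direction
#' is the one with the larger summed overlap length; an exact tie is
#' reported as `ambiguous`.
#'
#' @param dmrs [GenomicRanges::GRanges] from [callDmrs()].
#' @param index a [GeneRegionIndex-class].
#' @return data.frame with columns `gene_id`, `region_class`,
#'   `context`, `direction`, `n_dmrs`, `best_p`, `total_overlap_bp`,
#'   sorted by (gene_id, region_class, context).
#' @export
assignDmgs <- function(dmrs, index) {
    stopifnot(is(index, "GeneRegionIndex"))
    one_class <- function(regions, class_name) {
        if (!length(dmrs) || !length(regions)) return(NULL)
        ov <- GenomicRanges::findOverlaps(dmrs, regions,
                                          ignore.strand = TRUE,
                                          minoverlap = 1L)
        if (!length(ov)) return(NULL)
        qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
        inter <- GenomicRanges::pintersect(
            GenomicRanges::granges(dmrs)[qi],
            GenomicRanges::granges(regions)[si], ignore.strand = TRUE)
        data.frame(gene_id = names(regions)[si],
                   region_class = class_name,
                   context = mcols(dmrs)$context[qi],
                   direction = mcols(dmrs)$direction[qi],
                   p_value = mcols(dmrs)$p_value[qi],
                   overlap_bp = GenomicRanges::width(inter),
                   stringsAsFactors = FALSE)
    }
    hits <- rbind(one_class(promoterRanges(index), "promoter"),
                  one_class(geneBodyRanges(index), "gene_body"))
    if (is.null(hits) || !nrow(hits))
        return(data.frame(gene_id = character(), region_class = character(),
                          context = character(), direction = character(),
                          n_dmrs = integer(), best_p = numeric(),
                          total_overlap_bp = integer(),
                          stringsAsFactors = FALSE))
    key <- interaction(hits$gene_id, hits$region_class, hits$context,
                       drop = TRUE)
    out <- do.call(rbind, lapply(split(hits, key), function(h) {
        bp <- tapply(h$overlap_bp, factor(h$direction,
                                          levels = c("hyper", "hypo")),
                     sum, default = 0L)
        dir <- if (bp["hyper"] > bp["hypo"]) "hyper"
               else if (bp["hypo"] > bp["hyper"]) "hypo"
               else "ambiguous"
        data.frame(gene_id = h$gene_id[1], region_class = h$region_class[1],
                   context = h$context[1], direction = dir,
                   n_dmrs = nrow(h), best_p = min(h$p_value),
                   total_overlap_bp = sum(h$overlap_bp),
                   stringsAsFactors = FALSE)
    }))
    out <- out[order(out$gene_id, out$region_class, out$context), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Cross-tabulate DMGs per region class, direction and context
#'
#' Each gene is counted once per (region class, context). A
#' context-deduplicated total per (region class, direction) is attached
#' as the `"dedup_total"` attribute.
#'
#' @param dmgs data.frame from [assignDmgs()].
#' @return data.frame with columns `region_class`, `direction`,
#'   `context`, `n_genes` covering all combinations (zero-filled).
#' @export
dmgCountTable <- function(dmgs) {
    grid <- expand.grid(region_class = c("promoter", "gene_body"),
                        direction = c("hyper", "hypo", "ambiguous"),
                        context = .CONTEXTS, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    if (nrow(dmgs)) {
        tab <- stats::aggregate(list(n_genes = dmgs$gene_id),
                                by = dmgs[c("region_class", "direction",
                                            "context")],
                                FUN = function(x) length(unique(x)))
        grid <- merge(grid, tab, all.x = TRUE,
                      by = c("region_class", "direction", "context"))
        grid$n_genes[is.na(grid$n_genes)] <- 0L
        dd <- stats::aggregate(
            list(n_genes = dmgs$gene_id),
            by = dmgs[c("region_class", "direction")],
            FUN = function(x) length(unique(x)))
    } else {
        grid$n_genes <- 0L
        dd <- data.frame(region_class = character(),
                         direction = character(), n_genes = integer())
    }
    grid <- grid[order(grid$region_class, grid$direction, grid$context), ]
    rownames(grid) <- NULL
    attr(grid, "dedup_total") <- dd
    grid
}

#' Ratio of hyper- to hypo-methylated DMG counts per region class
#'
#' Summarises the direction imbalance of a DMG count table: for each
#' region class, the number of hyper-methylated genes divided by the
#' number of hypo-methylated genes (contexts pooled by sum).
#'
#' @param counts data.frame from [dmgCountTable()], or any data.frame
#'   with columns `region_class`, `direction`, `n_genes`.
#' @return named numeric vector of hyper/hypo ratios per region class.
#' @examples
#' counts <- data.frame(
#'     region_class = c("gene_body", "gene_body"),
#'     direction = c("hyper", "hypo"),
#'     n_genes = c(10711, 6764))
#' hyperHypoRatio(counts)
#' @export
hyperHypoRatio <- function(counts) {
    stopifnot(all(c("region_class", "direction", "n_genes") %in%
                  colnames(counts)))
    classes <- unique(counts$region_class)
    vapply(stats::setNames(classes, classes), function(rc) {
        hyper <- sum(counts$n_genes[counts$region_class == rc &
                                    counts$direction == "hyper"])
        hypo <- sum(counts$n_genes[counts$region_class == rc &
                                   counts$direction == "hypo"])
        hyper / hypo
    }, numeric(1))
}
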