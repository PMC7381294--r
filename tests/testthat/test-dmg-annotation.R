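mkDmr <- function(chrom, start, end, direction = "hyper",
                  context = "CG", p = 1e-6) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        context = context, level_ref = 0.5, level_trt = 0.5,
        fold_change = 2.5, p_value = p, direction = direction,
        n_sites = 5L, merged_from = 1L)
    gr
}

test_that("region index is strand-aware and clipped at position 1", {
    g <- GenomicRanges::GRanges(c("chr1", "chr1", "chr1"),
                                IRanges::IRanges(c(5000L, 100L, 50L),
                                                 c(8000L, 900L, 400L)),
                                strand = c("+", "-", "+"))
    names(g) <- c("plus", "minus", "edge")
    gm <- geneModels(g, GenomicRanges::GRangesList(
        GenomicRanges::GRanges("chr1", IRanges::IRanges(5000L, 8000L), "+"),
        GenomicRanges::GRanges("chr1", IRanges::IRanges(100L, 900L), "-"),
        GenomicRanges::GRanges("chr1", IRanges::IRanges(50L, 400L), "+")))
    idx <- buildRegionIndex(gm, promoter_bp = 2000L)
    prom <- promoterRanges(idx)
    expect_identical(GenomicRanges::start(prom)[1], 3000L)  # [TSS-2000, TSS-1]
    expect_identical(GenomicRanges::end(prom)[1], 4999L)
    expect_identical(GenomicRanges::start(prom)[2], 901L)   # minus mirror
    expect_identical(GenomicRanges::end(prom)[2], 2900L)
    expect_identical(GenomicRanges::start(prom)[3], 1L)     # clipped
    expect_identical(GenomicRanges::end(prom)[3], 49L)
    body <- geneBodyRanges(idx)
    expect_identical(GenomicRanges::start(body), c(5000L, 100L, 50L))
})

test_that("DMRs map to genes with majority-by-length direction", {
    gm <- tinyGenes()  # gA + strand [1000,3000]; gB - strand [6000,9000]
    idx <- buildRegionIndex(gm, promoter_bp = 500L)

    # fully inside gA's body
    d1 <- assignDmgs(mkDmr("chr1", 1500, 1700), idx)
    expect_identical(nrow(d1), 1L)
    expect_identical(d1$region_class, "gene_body")
    expect_identical(d1$direction, "hyper")
    expect_identical(d1$n_dmrs, 1L)

    # straddling gA's TSS: contributes to promoter AND body
    d2 <- assignDmgs(mkDmr("chr1", 900, 1100), idx)
    expect_identical(sort(d2$region_class), c("gene_body", "promoter"))
    expect_identical(d2$total_overlap_bp,
                     c(101L, 100L)[order(c("gene_body", "promoter"))])

    # hyper 300 bp vs hypo 100 bp in the same body -> hyper wins
    d3 <- assignDmgs(c(mkDmr("chr1", 1500, 1799, "hyper"),
                       mkDmr("chr1", 2000, 2099, "hypo")), idx)
    expect_identical(d3$direction, "hyper")
    expect_identical(d3$n_dmrs, 2L)
    # exact tie -> ambiguous
    d4 <- assignDmgs(c(mkDmr("chr1", 1500, 1599, "hyper"),
                       mkDmr("chr1", 2000, 2099, "hypo")), idx)
    expect_identical(d4$direction, "ambiguous")

    # minus-strand promoter lies right of the gene
    d5 <- assignDmgs(mkDmr("chr1", 9100, 9200), idx)
    expect_identical(d5$gene_id, "gB")
    expect_identical(d5$region_class, "promoter")
})

test_that("count table cross-tabulates and is monotone in promoter size", {
    expect_true(all(dmgCountTable(assignDmgs(
        GenomicRanges::GRanges(), buildRegionIndex(tinyGenes())))$n_genes == 0L))

    dmgs <- data.frame(
        gene_id = c("g1", "g2", "g3", "g4", "g5"),
        region_class = c(rep("promoter", 3), rep("gene_body", 2)),
        context = "CG",
        direction = c(rep("hyper", 3), rep("hypo", 2)),
        n_dmrs = 1L, best_p = 0.01, total_overlap_bp = 100L)
    tab <- dmgCountTable(dmgs)
    expect_identical(tab$n_genes[tab$region_class == "promoter" &
                                 tab$direction == "hyper" &
                                 tab$context == "CG"], 3L)
    expect_identical(tab$n_genes[tab$region_class == "gene_body" &
                                 tab$direction == "hypo" &
                                 tab$context == "CG"], 2L)
    expect_identical(sum(tab$n_genes), 5L)

    # larger promoters can only gain overlaps
    gm <- tinyGenes()
    dmrs <- c(mkDmr("chr1", 700, 800), mkDmr("chr1", 9100, 9600, "hypo"))
    n_small <- sum(dmgCountTable(assignDmgs(dmrs,
        buildRegionIndex(gm, 100L)))$n_genes)
    n_big <- sum(dmgCountTable(assignDmgs(dmrs,
        buildRegionIndex(gm, 2000L)))$n_genes)
    expect_gte(n_big, n_small)
})

test_that("assignments agree with a brute-force interval scan on simulated calls", {
    cfg <- simulationConfig(seed = 42, nChroms = 1L,
                            chromLengthBp = 300000L, nGenes = 15L)
    cfg@plantedDmrs <- cfg@plantedDmrs[1:5, ]
    ann <- simulateAnnotation(cfg)
    sim <- simulateMethylomes(cfg, ann$genes)
    dmrs <- callDmrs(sim$reference, sim$treatment, contexts = "CG")
    idx <- buildRegionIndex(ann$genes, 2000L)
    dmgs <- assignDmgs(dmrs, idx)

    # quadratic oracle over all (DMR, gene, region) pairs
    overlap_len <- function(a1, a2, b1, b2)
        max(0L, min(a2, b2) - max(a1, b1) + 1L)
    expected_pairs <- 0L
    for (region in c("promoter", "gene_body")) {
        regs <- if (region == "promoter") promoterRanges(idx)
                else geneBodyRanges(idx)
        for (i in seq_along(dmrs)) for (j in seq_along(regs)) {
            same_chr <- as.character(GenomicRanges::seqnames(dmrs))[i] ==
                as.character(GenomicRanges::seqnames(regs))[j]
            ol <- overlap_len(GenomicRanges::start(dmrs)[i],
                              GenomicRanges::end(dmrs)[i],
                              GenomicRanges::start(regs)[j],
                              GenomicRanges::end(regs)[j])
            if (same_chr && ol >= 1L) {
                expected_pairs <- expected_pairs + 1L
                hit <- dmgs[dmgs$gene_id == names(regs)[j] &
                            dmgs$region_class == region, ]
                expect_identical(nrow(hit), 1L)
            }
        }
    }
    expect_identical(sum(dmgs$n_dmrs), as.integer(expected_pairs))
    # every DMG row is supported by at least one genuinely intersecting DMR
    expect_true(all(dmgs$n_dmrs >= 1L))
    expect_identical(sum(dmgCountTable(dmgs)$n_genes) > 0, length(dmrs) > 0)
})

test_that("the hyper/hypo ratio summarises direction imbalance per region class", {
    counts <- data.frame(
        region_class = c("gene_body", "gene_body", "promoter", "promoter"),
        direction = c("hyper", "hypo", "hyper", "hypo"),
        n_genes = c(200L, 100L, 30L, 60L))
    r <- hyperHypoRatio(counts)
    expect_equal(unname(r["gene_body"]), 2)
    expect_equal(unname(r["promoter"]), 0.5)
})
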