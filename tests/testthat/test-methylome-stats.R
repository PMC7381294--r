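test_that("site levels follow Nm/(Nm+Nnm) and are scale invariant", {
    expect_equal(siteLevel(8, 2), 0.8)
    expect_equal(siteLevel(0, 5), 0)
    expect_equal(siteLevel(3, 0), 1)
    expect_error(siteLevel(0, 0), "zero coverage")
    for (k in c(2L, 5L, 13L))
        expect_equal(siteLevel(k * 3L, k * 7L), siteLevel(3L, 7L))
})

test_that("global summary reports weighted level and binomial-called fraction", {
    s <- flatSample(pos = seq(100L, 1090L, by = 10L), n_meth = 4L,
                    n_unmeth = 1L)
    gs <- globalSummary(s, min_depth = 4L)
    expect_equal(gs$weighted_level[gs$context == "CG"], 0.8)
    # contexts with no covered site are missing, not zero
    expect_true(is.na(gs$weighted_level[gs$context == "CHH"]))
    expect_identical(gs$n_sites[gs$context == "CHH"], 0L)

    # error_rate = 0: any methylated read is a certain call
    one <- methylomeSample(chrom = "chr1", pos = c(1L, 2L), strand = "+",
                           context = "CG", n_meth = c(1L, 0L),
                           n_unmeth = c(9L, 10L))
    gs0 <- globalSummary(one, min_depth = 1L, error_rate = 0)
    expect_equal(gs0$site_fraction_methylated[gs0$context == "CG"], 0.5)

    # weighted level lies within [min, max] of contributing site levels
    set.seed(1)
    nm <- rpois(200, 6); nu <- rpois(200, 3)
    keep <- nm + nu >= 4
    r <- methylomeSample(chrom = "chr1", pos = seq_len(200), strand = "+",
                         context = "CG", n_meth = nm, n_unmeth = nu)
    gsr <- globalSummary(r, min_depth = 4L)
    lv <- nm[keep] / (nm + nu)[keep]
    w <- gsr$weighted_level[gsr$context == "CG"]
    expect_gte(w, min(lv)); expect_lte(w, max(lv))
})

test_that("simulated levels are recovered by the global summary", {
    cfg <- simulationConfig(seed = 7, nChroms = 1L,
                            chromLengthBp = 1000000L, nGenes = 0L,
                            plantedDmrs = data.frame())
    ann <- simulateAnnotation(cfg)
    sim <- simulateMethylomes(cfg, ann$genes)
    gs <- globalSummary(sim$reference[[1]])
    cg <- gs$weighted_level[gs$context == "CG"]
    chh <- gs$weighted_level[gs$context == "CHH"]
    expect_lt(abs(cg - 0.8), 0.02)
    expect_lt(abs(chh - 0.01), 0.005)
})

test_that("region profile is constant on constant methylomes and flags absent regions", {
    genes <- tinyGenes()
    pos <- seq(1L, 12000L, by = 37L)
    s <- flatSample(pos = pos, n_meth = 3L, n_unmeth = 3L)
    prof <- regionProfile(s, genes, flank_bp = 1000L, bins_per_region = 5L)
    cg <- prof[prof$context == "CG" & !is.na(prof$mean_level), ]
    expect_true(nrow(cg) > 0)
    expect_true(all(abs(cg$mean_level - 0.5) < 1e-12))

    # single-exon genes have no introns, no internal or last exon
    g1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2000L, 4000L),
                                 strand = "+")
    names(g1) <- "solo"
    single <- geneModels(g1, GenomicRanges::GRangesList(
        GenomicRanges::GRanges("chr1", IRanges::IRanges(2000L, 4000L),
                               strand = "+")))
    prof1 <- regionProfile(s, single, flank_bp = 1000L,
                           bins_per_region = 4L)
    absent <- c("first_intron", "internal_exon", "internal_intron",
                "last_exon")
    expect_true(all(is.na(prof1$mean_level[prof1$region %in% absent])))
    expect_true(all(prof1$n_genes[prof1$region %in% absent] == 0L))
    expect_error(regionProfile(s, geneModels(GenomicRanges::GRanges(),
                                             GenomicRanges::GRangesList())),
                 "empty gene list")
})

test_that("the planted TSS dip shows up in the bins flanking the TSS", {
    cfg <- simulationConfig(seed = 11, nChroms = 1L,
                            chromLengthBp = 500000L, nGenes = 25L,
                            tssDipHalfWidth = 200L, tssDipMultiplier = 0.5,
                            plantedDmrs = data.frame())
    ann <- simulateAnnotation(cfg)
    sim <- simulateMethylomes(cfg, ann$genes)
    prof <- regionProfile(sim$reference[[1]], ann$genes,
                          flank_bp = 2000L, bins_per_region = 10L)
    cg <- prof[prof$context == "CG", ]
    up <- cg[cg$region == "upstream", ]
    fe <- cg[cg$region == "first_exon", ]
    # the last upstream bin (abutting the TSS) is the upstream minimum
    expect_equal(which.min(up$mean_level), nrow(up))
    # bins near the TSS sit well below the 0.8 plateau
    expect_lt(up$mean_level[nrow(up)], 0.6)
    expect_lt(fe$mean_level[1], min(0.75, max(fe$mean_level, na.rm = TRUE)))
})

test_that("region profile is invariant under genome mirroring with strand flips", {
    set.seed(5)
    L <- 20000L
    pos <- sort(sample.int(L, 400L))
    nm <- rbinom(400, 10, 0.7)
    s <- methylomeSample(chrom = "chr1", pos = pos,
                         strand = sample(c("+", "-"), 400, TRUE),
                         context = "CG", n_meth = nm, n_unmeth = 10L - nm)
    genes <- tinyGenes()
    mirror_gr <- function(gr) {
        st <- L + 1L - GenomicRanges::end(gr)
        en <- L + 1L - GenomicRanges::start(gr)
        out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
            IRanges::IRanges(st, en),
            strand = chartr("+-", "-+",
                            as.character(GenomicRanges::strand(gr))))
        names(out) <- names(gr)
        out
    }
    genes_m <- geneModels(mirror_gr(geneRanges(genes)),
                          GenomicRanges::GRangesList(lapply(
                              exonRanges(genes),
                              function(e) sort(mirror_gr(e)))))
    mc <- S4Vectors::mcols(s)
    s_m <- methylomeSample(chrom = "chr1",
                           pos = L + 1L - GenomicRanges::start(s),
                           strand = chartr("+-", "-+",
                               as.character(GenomicRanges::strand(s))),
                           context = mc$context, n_meth = mc$n_meth,
                           n_unmeth = mc$n_unmeth)
    p1 <- regionProfile(s, genes, flank_bp = 1000L, bins_per_region = 5L)
    p2 <- regionProfile(s_m, genes_m, flank_bp = 1000L, bins_per_region = 5L)
    expect_equal(p1$mean_level, p2$mean_level)
    expect_identical(p1$n_genes, p2$n_genes)
})
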