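test_that("the two-sided Fisher p matches exact enumeration on hand tables", {
    expect_equal(fisherExactTwoSided(5, 5, 5, 5), 1)
    # enumeration over the 11 tables with margins (10,10)x(10,10)
    expect_equal(fisherExactTwoSided(2, 8, 8, 2), 0.0230141375652,
                 tolerance = 1e-10)
    expect_equal(fisherExactTwoSided(0, 0, 3, 7), 1)   # zero row margin
    expect_equal(fisherExactTwoSided(3, 0, 4, 0), 1)   # zero column margin
    expect_error(fisherExactTwoSided(0, 0, 0, 0), "at least one")
})

test_that("Fisher p agrees with independent oracles and is transposition symmetric", {
    set.seed(42)
    for (i in 1:200) {
        tab <- as.integer(rmultinom(1, sample(4:60, 1), rep(0.25, 4)))
        p <- fisherExactTwoSided(tab[1], tab[2], tab[3], tab[4])
        expect_equal(p, oracleFisher(tab[1], tab[2], tab[3], tab[4]),
                     tolerance = 1e-9)
        expect_equal(p, stats::fisher.test(matrix(tab, 2))$p.value,
                     tolerance = 1e-9)
        # row swap + column swap (transposition symmetry)
        expect_equal(p, fisherExactTwoSided(tab[4], tab[3], tab[2], tab[1]),
                     tolerance = 1e-12)
    }
})

test_that("windows partition eligible sites into disjoint five-site blocks", {
    params <- dmrParams()
    pos <- seq(100L, 100L + 11L * 50L, by = 50L)[1:12]
    ref <- flatSample(pos, n_meth = 8L, n_unmeth = 2L, group = "reference")
    trt <- flatSample(pos, n_meth = 2L, n_unmeth = 8L, group = "treatment",
                      id = "t")
    w <- buildWindows(list(ref), list(trt), "CG", params)
    expect_identical(nrow(w), 2L)          # 12 sites -> 2 windows, 2 dropped
    expect_identical(w$n_sites, c(5L, 5L))
    expect_identical(w$start, c(pos[1], pos[6]))
    expect_identical(w$end, c(pos[5], pos[10]))
    expect_identical(w$mr, c(40L, 40L))

    # 4 sites: below window size
    w4 <- buildWindows(flatSample(pos[1:4]), flatSample(pos[1:4], id = "t2",
                                                       group = "treatment"),
                       "CG", params)
    expect_identical(nrow(w4), 0L)

    # never spans a chromosome boundary
    ref2 <- methylomeSample(chrom = rep(c("chr1", "chr2"), each = 5),
                            pos = rep(pos[1:5], 2), strand = "+",
                            context = "CG", n_meth = 5L, n_unmeth = 5L)
    trt2 <- methylomeSample(chrom = rep(c("chr1", "chr2"), each = 5),
                            pos = rep(pos[1:5], 2), strand = "+",
                            context = "CG", n_meth = 5L, n_unmeth = 5L,
                            sampleId = "t3", group = "treatment")
    w2 <- buildWindows(ref2, trt2, "CG", params)
    expect_identical(nrow(w2), 2L)
    expect_identical(sort(unique(w2$chrom)), c("chr1", "chr2"))
    expect_error(buildWindows(list(), list(trt), "CG", params), "at least one")
})

test_that("window testing applies both the fold and the p gate inclusively", {
    params <- dmrParams()
    mk <- function(mr, ur, mt, ut)
        data.frame(chrom = "chr1", start = 1L, end = 100L, context = "CG",
                   n_sites = 5L, mr = mr, ur = ur, mt = mt, ut = ut)
    hit <- testWindow(mk(40L, 10L, 10L, 40L), params)
    expect_identical(hit$direction, "hypo")
    expect_gte(hit$fold_change, 2)
    expect_equal(hit$fold_change, 40.5 / 10.5, tolerance = 1e-12)
    expect_equal(hit$p_value, 2.22210081483e-09, tolerance = 1e-9)

    # identical counts: fold 1, no DMR
    expect_null(testWindow(mk(20L, 20L, 20L, 20L), params))
    # fold passes ((3.5/6)/(1.5/6) = 2.33) but p = 0.524 fails
    expect_equal(fisherExactTwoSided(3, 2, 1, 4), 0.523809523810,
                 tolerance = 1e-10)
    expect_null(testWindow(mk(3L, 2L, 1L, 4L), params))
})

test_that("neighboring same-direction DMRs merge iff the span keeps a twofold difference", {
    params <- dmrParams()
    # two hypo DMRs; the span pools to ref(80,20)/trt(20,80), fold 3.93
    sites_merge <- data.frame(
        chrom = "chr1", pos = seq(10L, 100L, by = 10L),
        mr = 8L, ur = 2L, mt = 2L, ut = 8L)
    dmr_a <- testWindow(data.frame(chrom = "chr1", start = 10L, end = 50L,
                                   context = "CG", n_sites = 5L, mr = 40L,
                                   ur = 10L, mt = 10L, ut = 40L), params)
    dmr_b <- testWindow(data.frame(chrom = "chr1", start = 60L, end = 100L,
                                   context = "CG", n_sites = 5L, mr = 40L,
                                   ur = 10L, mt = 10L, ut = 40L), params)
    merged <- mergeAdjacentDmrs(rbind(dmr_a, dmr_b), sites_merge, params)
    expect_identical(nrow(merged), 1L)
    expect_identical(merged$start, 10L)
    expect_identical(merged$end, 100L)
    expect_identical(merged$n_sites, 10L)
    expect_identical(merged$merged_from, 2L)
    expect_equal(merged$fold_change, 3.926829268, tolerance = 1e-8)

    # an intervening neutral stretch dilutes the span fold below 2
    sites_neutral <- rbind(
        data.frame(chrom = "chr1", pos = seq(10L, 50L, by = 10L),
                   mr = 8L, ur = 2L, mt = 2L, ut = 8L),
        data.frame(chrom = "chr1", pos = seq(110L, 490L, by = 10L),
                   mr = 5L, ur = 5L, mt = 5L, ut = 5L),
        data.frame(chrom = "chr1", pos = seq(510L, 550L, by = 10L),
                   mr = 8L, ur = 2L, mt = 2L, ut = 8L))
    dmr_c <- testWindow(data.frame(chrom = "chr1", start = 510L, end = 550L,
                                   context = "CG", n_sites = 5L, mr = 40L,
                                   ur = 10L, mt = 10L, ut = 40L), params)
    dmr_a2 <- dmr_a
    kept <- mergeAdjacentDmrs(rbind(dmr_a2, dmr_c), sites_neutral, params)
    expect_identical(nrow(kept), 2L)

    # opposite directions never merge
    dmr_hyper <- testWindow(data.frame(chrom = "chr1", start = 60L,
                                       end = 100L, context = "CG",
                                       n_sites = 5L, mr = 10L, ur = 40L,
                                       mt = 40L, ut = 10L), params)
    two <- mergeAdjacentDmrs(rbind(dmr_a, dmr_hyper), sites_merge, params)
    expect_identical(nrow(two), 2L)

    # unsorted input is rejected
    expect_error(mergeAdjacentDmrs(rbind(dmr_b, dmr_a), sites_merge, params),
                 "sorted")
    # the merge gap can be bounded
    far <- dmr_b; far$start <- 5000L; far$end <- 5040L
    sites_far <- rbind(sites_merge[1:5, ],
                       data.frame(chrom = "chr1",
                                  pos = seq(5000L, 5040L, by = 10L),
                                  mr = 8L, ur = 2L, mt = 2L, ut = 8L))
    gap_params <- dmrParams(maxMergeGap = 100)
    expect_identical(nrow(mergeAdjacentDmrs(rbind(dmr_a, far), sites_far,
                                            gap_params)), 2L)
    expect_identical(nrow(mergeAdjacentDmrs(rbind(dmr_a, far), sites_far,
                                            dmrParams())), 1L)
})

test_that("calling on identical groups yields nothing and output always satisfies both gates", {
    pos <- seq(100L, 3000L, by = 20L)
    a <- flatSample(pos, n_meth = 8L, n_unmeth = 2L)
    b <- flatSample(pos, n_meth = 8L, n_unmeth = 2L, id = "b",
                    group = "treatment")
    expect_length(callDmrs(a, b), 0L)

    cfg <- simulationConfig(seed = 42, nChroms = 1L,
                            chromLengthBp = 300000L, nGenes = 15L)
    cfg@plantedDmrs <- cfg@plantedDmrs[1:4, ]
    ann <- simulateAnnotation(cfg)
    sim <- simulateMethylomes(cfg, ann$genes)
    d <- callDmrs(sim$reference, sim$treatment)
    expect_gt(length(d), 0L)
    mc <- S4Vectors::mcols(d)
    expect_true(all(mc$fold_change >= 2))
    expect_true(all(mc$p_value <= 0.05))
    expect_true(all((mc$level_trt > mc$level_ref) == (mc$direction == "hyper")))
    # within a context, DMRs are sorted and non-overlapping
    for (cx in unique(mc$context)) {
        dc <- d[mc$context == cx]
        dc <- GenomicRanges::sort(dc)
        if (length(dc) > 1)
            expect_true(all(GenomicRanges::start(dc)[-1] >
                            GenomicRanges::end(dc)[-length(dc)] |
                            as.character(GenomicRanges::seqnames(dc))[-1] !=
                            as.character(GenomicRanges::seqnames(dc))[-length(dc)]))
    }
})

test_that("calls are invariant under replicate order and merging is idempotent", {
    cfg <- simulationConfig(seed = 9, nChroms = 1L,
                            chromLengthBp = 200000L, nGenes = 10L)
    cfg@plantedDmrs <- cfg@plantedDmrs[1:3, ]
    ann <- simulateAnnotation(cfg)
    sim <- simulateMethylomes(cfg, ann$genes)
    d1 <- callDmrs(sim$reference, sim$treatment, contexts = "CG")
    d2 <- callDmrs(rev(sim$reference), rev(sim$treatment), contexts = "CG")
    expect_identical(as.data.frame(d1), as.data.frame(d2))

    # merge fixpoint: re-merging the caller's output changes nothing
    params <- dmrParams()
    sites <- methylWindows:::.eligibleSites(sim$reference, sim$treatment,
                                            "CG", params@minDepth)
    df <- as.data.frame(d1)
    df <- data.frame(chrom = as.character(df$seqnames), start = df$start,
                     end = df$end, context = df$context,
                     level_ref = df$level_ref, level_trt = df$level_trt,
                     fold_change = df$fold_change, p_value = df$p_value,
                     direction = df$direction, n_sites = df$n_sites,
                     merged_from = df$merged_from,
                     stringsAsFactors = FALSE)
    again <- mergeAdjacentDmrs(df, sites, params)
    expect_equal(again, df)
})
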