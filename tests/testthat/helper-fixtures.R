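# Small in-code fixtures shared across test files.

# A hand-sized sample: positions and counts chosen so levels are easy
# to read off.
tinySample <- function(group = "reference", id = "tiny") {
    methylomeSample(
        chrom = c("chr1", "chr1", "chr1", "chr2"),
        pos = c(10L, 20L, 35L, 5L),
        strand = c("+", "-", "+", "+"),
        context = c("CG", "CG", "CHH", "CHG"),
        n_meth = c(8L, 0L, 1L, 3L),
        n_unmeth = c(2L, 5L, 9L, 0L),
        sampleId = id, group = group)
}

# One plus-strand and one minus-strand two-exon gene.
tinyGenes <- function() {
    g <- GenomicRanges::GRanges(
        c("chr1", "chr1"),
        IRanges::IRanges(c(1000L, 6000L), c(3000L, 9000L)),
        strand = c("+", "-"))
    names(g) <- c("gA", "gB")
    ex <- GenomicRanges::GRangesList(
        GenomicRanges::GRanges("chr1",
            IRanges::IRanges(c(1000L, 2500L), c(1400L, 3000L)),
            strand = "+"),
        GenomicRanges::GRanges("chr1",
            IRanges::IRanges(c(6000L, 8000L), c(7000L, 9000L)),
            strand = "-"))
    geneModels(g, ex)
}

# Build a MethylomeSample with constant counts at given positions.
flatSample <- function(pos, chrom = "chr1", context = "CG",
                       n_meth = 5L, n_unmeth = 5L,
                       group = "reference", id = "flat") {
    n <- length(pos)
    methylomeSample(chrom = chrom, pos = pos,
                    strand = rep("+", n), context = context,
                    n_meth = rep_len(n_meth, n),
                    n_unmeth = rep_len(n_unmeth, n),
                    sampleId = id, group = group)
}

# Independent two-sided Fisher oracle: enumerate the hypergeometric
# support with dhyper and sum probabilities <= the observed one (same
# relative tolerance as the published rule). Distinct code path from
# the implementation, which works in log space via lchoose.
oracleFisher <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c
    if (r1 == 0 || r2 == 0 || c1 == 0 || b + d == 0) return(1)
    x <- max(0, c1 - r2):min(r1, c1)
    p <- stats::dhyper(x, r1, r2, c1)
    p_obs <- stats::dhyper(a, r1, r2, c1)
    min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}
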