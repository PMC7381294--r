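.REGIONS <- c("upstream", "first_exon", "first_intron", "internal_exon",
              "internal_intron", "last_exon", "downstream")

#' Per-site methylation level
#'
#' The level of a cytosine site is the fraction of reads reporting
#' methylation, Nm / (Nm + Nnm). Undefined at zero coverage.
#'
#' @param n_meth,n_unmeth methylated / unmethylated read counts
#'   (vectorised).
#' @return numeric level(s) in \[0, 1\].
#' @examples
#' siteLevel(8, 2)   # 0.8
#' @export
siteLevel <- function(n_meth, n_unmeth) {
    tot <- n_meth + n_unmeth
    if (any(tot < 1L))
        stop("methylation level is undefined at zero coverage")
    n_meth / tot
}

#' Genome-wide methylation summary per context
#'
#' Two readings of "percent methylated" are reported side by side for
#' each context: the pooled weighted level (sum of methylated reads over
#' sum of all reads across covered sites) and the fraction of covered
#' sites *called* methylated by a one-sided binomial test of the
#' methylated count against the bisulfite non-conversion error rate.
#' A site is covered when its depth reaches `min_depth`.
#'
#' @param sample a [MethylomeSample-class].
#' @param min_depth minimum reads for a site to count as covered
#'   (default 4).
#' @param error_rate probability an unmethylated cytosine reads as
#'   methylated (default 0.005, i.e. ~99.5 percent conversion).
#' @param call_alpha significance level of the site call (default 0.05).
#' @return data.frame with one row per context plus an `overall` row:
#'   columns `context`, `weighted_level`, `site_fraction_methylated`,
#'   `n_sites`. Contexts with no covered site get `NA` (missing, not 0).
#' @export
globalSummary <- function(sample, min_depth = 4L, error_rate = 0.005,
                          call_alpha = 0.05) {
    stopifnot(is(sample, "MethylomeSample"), min_depth >= 1L,
              error_rate >= 0, error_rate < 1)
    mc <- mcols(sample)
    tot <- mc$n_meth + mc$n_unmeth
    keep <- tot >= min_depth
    nm <- mc$n_meth[keep]
    nt <- tot[keep]
    ctx <- mc$context[keep]
    # one-sided binomial: P(X >= n_meth | depth, error_rate) < call_alpha
    p_site <- stats::pbinom(nm - 1L, nt, error_rate, lower.tail = FALSE)
    called <- p_site < call_alpha
    rows <- lapply(.CONTEXTS, function(cx) {
        i <- ctx == cx
        if (!any(i))
            return(data.frame(context = cx, weighted_level = NA_real_,
                              site_fraction_methylated = NA_real_,
                              n_sites = 0L))
        data.frame(context = cx,
                   weighted_level = sum(nm[i]) / sum(nt[i]),
                   site_fraction_methylated = mean(called[i]),
                   n_sites = sum(i))
    })
    overall <- data.frame(
        context = "overall",
        weighted_level = if (length(nt)) sum(nm) / sum(nt) else NA_real_,
        site_fraction_methylated = if (length(nt)) mean(called) else NA_real_,
        n_sites = length(nt))
    out <- rbind(do.call(rbind, rows), overall)
    rownames(out) <- NULL
    out
}

# Seven-region intervals of one gene in transcription order.
# Returns a list of GRanges (possibly empty) named by region; each
# element's ranges are ordered 5'->3' in the transcription orientation.
.geneRegions <- function(gene, exons, flank_bp) {
    minus <- as.character(GenomicRanges::strand(gene)) == "-"
    chr <- as.character(GenomicRanges::seqnames(gene))
    s <- GenomicRanges::start(gene); e <- GenomicRanges::end(gene)
    mk <- function(st, en) {
        st <- pmax(st, 1L)
        if (any(en < st)) return(GenomicRanges::GRanges())
        GenomicRanges::GRanges(chr, IRanges::IRanges(st, en))
    }
    up <- if (minus) mk(e + 1L, e + flank_bp) else mk(s - flank_bp, s - 1L)
    dn <- if (minus) mk(s - flank_bp, s - 1L) else mk(e + 1L, e + flank_bp)
    ex <- exons  # position-sorted
    k <- length(ex)
    introns <- if (k >= 2L)
        GenomicRanges::GRanges(chr, IRanges::IRanges(
            GenomicRanges::end(ex)[-k] + 1L,
            GenomicRanges::start(ex)[-1] - 1L))
    else GenomicRanges::GRanges()
    introns <- introns[GenomicRanges::width(introns) > 0L]
    # transcription order: reverse genomic order on the minus strand
    tx_order <- function(gr) if (minus) rev(gr) else gr
    ex_tx <- tx_order(ex)
    in_tx <- tx_order(introns)
    ki <- length(in_tx)
    list(upstream = up,
         first_exon = ex_tx[1],
         first_intron = if (ki >= 1L) in_tx[1] else GenomicRanges::GRanges(),
         internal_exon = if (k >= 3L) ex_tx[2:(k - 1L)] else GenomicRanges::GRanges(),
         internal_intron = if (ki >= 2L) in_tx[2:ki] else GenomicRanges::GRanges(),
         last_exon = if (k >= 2L) ex_tx[k] else GenomicRanges::GRanges(),
         downstream = dn)
}

# Map absolute positions inside a multi-interval region (transcription
# order) to relative offsets in [0, 1) along the concatenated length.
.relativeOffset <- function(pos, region, minus) {
    w <- GenomicRanges::width(region)
    total <- sum(w)
    cum <- cumsum(c(0L, w[-length(w)]))
    st <- GenomicRanges::start(region); en <- GenomicRanges::end(region)
    off <- rep(NA_real_, length(pos))
    for (j in seq_along(w)) {
        i <- pos >= st[j] & pos <= en[j]
        within <- if (minus) en[j] - pos[i] else pos[i] - st[j]
        off[i] <- (cum[j] + within) / total
    }
    off
}

#' Seven-region metagene methylation profile
#'
#' Partitions each gene, strand-aware, into upstream flank, first exon,
#' first intron, internal exons, internal introns, last exon and
#' downstream flank ("first"/"last" in transcription order), divides
#' each region into equal-length bins by relative position 5'->3', pools
#' covered-site counts per (gene, region, bin, context) into a weighted
#' level and averages over genes. Genes lacking a region (e.g.
#' single-exon genes have no introns) contribute nothing to it.
#'
#' @param sample a [MethylomeSample-class].
#' @param genes a [GeneModels-class].
#' @param flank_bp upstream/downstream flank length (default 2000).
#' @param bins_per_region bins per region (default 20).
#' @param min_depth minimum site depth to contribute (default 1).
#' @return data.frame with columns `region` (ordered factor),
#'   `bin_index`, `context`, `mean_level`, `n_genes`; `mean_level` is
#'   `NA` where no gene contributed.
#' @export
regionProfile <- function(sample, genes, flank_bp = 2000L,
                          bins_per_region = 20L, min_depth = 1L) {
    stopifnot(is(sample, "MethylomeSample"), is(genes, "GeneModels"))
    if (!length(genes)) stop("empty gene list")
    if (flank_bp < bins_per_region)
        stop("'flank_bp' must be >= 'bins_per_region'")
    mc <- mcols(sample)
    tot <- mc$n_meth + mc$n_unmeth
    keep <- tot >= min_depth
    sites <- GenomicRanges::granges(sample)[keep]
    nm <- mc$n_meth[keep]; nt <- tot[keep]; ctx <- mc$context[keep]
    B <- as.integer(bins_per_region)
    # accumulators: per (region, bin, context) sum of gene-level levels
    acc_sum <- array(0, dim = c(7L, B, 3L),
                     dimnames = list(.REGIONS, NULL, .CONTEXTS))
    acc_n <- array(0L, dim = c(7L, B, 3L),
                   dimnames = list(.REGIONS, NULL, .CONTEXTS))
    region_genes <- stats::setNames(integer(7L), .REGIONS)
    gr_genes <- geneRanges(genes)
    ex_all <- exonRanges(genes)
    for (gi in seq_along(genes)) {
        gene <- gr_genes[gi]
        minus <- as.character(GenomicRanges::strand(gene)) == "-"
        regions <- .geneRegions(gene, ex_all[[gi]], as.integer(flank_bp))
        gene_contributed <- stats::setNames(logical(7L), .REGIONS)
        for (rg in .REGIONS) {
            reg <- regions[[rg]]
            if (!length(reg)) next
            ov <- GenomicRanges::findOverlaps(sites, reg, ignore.strand = TRUE)
            hit <- unique(S4Vectors::queryHits(ov))
            if (!length(hit)) next
            off <- .relativeOffset(GenomicRanges::start(sites)[hit], reg, minus)
            bin <- pmin(B, floor(off * B) + 1L)
            for (cx_i in seq_along(.CONTEXTS)) {
                i <- ctx[hit] == .CONTEXTS[cx_i]
                if (!any(i)) next
                gm <- rowsum(nm[hit][i], bin[i])
                gt <- rowsum(nt[hit][i], bin[i])
                bj <- as.integer(rownames(gm))
                acc_sum[rg, bj, cx_i] <- acc_sum[rg, bj, cx_i] +
                    as.numeric(gm / gt)
                acc_n[rg, bj, cx_i] <- acc_n[rg, bj, cx_i] + 1L
                gene_contributed[rg] <- TRUE
            }
        }
        region_genes <- region_genes + gene_contributed
    }
    out <- expand.grid(region = .REGIONS, bin_index = seq_len(B),
                       context = .CONTEXTS, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
    out$mean_level <- mapply(function(r, b, cx) {
        n <- acc_n[r, b, cx]
        if (n == 0L) NA_real_ else acc_sum[r, b, cx] / n
    }, out$region, out$bin_index, out$context)
    out$n_genes <- region_genes[out$region]
    out$region <- factor(out$region, levels = .REGIONS)
    out <- out[order(out$region, out$bin_index, out$context), ]
    rownames(out) <- NULL
    out
}

#' Write the global summary or region profile as TSV
#'
#' @param x data.frame from [globalSummary()] or [regionProfile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSummaryTable <- function(x, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    utils::write.table(x, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
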