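#' Configure the synthetic methylome generator
#'
#' Defaults emulate a replicated two-group vertebrate liver WGBS design:
#' CG sites methylated near 80 percent, CHG/CHH near 1 percent, a
#' methylation dip around transcription start sites, ~20x Poisson
#' depth, a 0.5 percent conversion/sequencing error (~99.5 percent
#' bisulfite conversion) and three methylomes per group. Planted
#' differential regions default to ten 10-site CG regions at level 0.8
#' (reference) vs 0.2 (treatment) inside gene bodies.
#'
#' @param seed integer seed.
#' @param nChroms,chromLengthBp,nGenes,exonsPerGene genome/annotation
#'   shape (defaults: 2 chromosomes of 1 Mbp, 50 genes, 2-8 exons).
#' @param siteDensity named sites per kbp per context.
#' @param baselineLevels named true levels per context.
#' @param tssDipHalfWidth,tssDipMultiplier the TSS dip (default: level
#'   halved within 200 bp of a TSS).
#' @param depthMean,conversionError,replicatesPerGroup read model.
#' @param plantedDmrs data.frame (`context`, `n_sites`, `level_ref`,
#'   `level_trt`, `placement`), or `NULL` for the default design, or a
#'   zero-row data.frame for none.
#' @return a validated [SimulationConfig-class].
#' @export
simulationConfig <- function(seed = 1L, nChroms = 2L,
                             chromLengthBp = 1000000L, nGenes = 50L,
                             exonsPerGene = c(2L, 8L),
                             siteDensity = c(CG = 8, CHG = 2, CHH = 4),
                             baselineLevels = c(CG = 0.80, CHG = 0.01,
                                                CHH = 0.01),
                             tssDipHalfWidth = 200L,
                             tssDipMultiplier = 0.5,
                             depthMean = 20, conversionError = 0.005,
                             replicatesPerGroup = 3L,
                             plantedDmrs = NULL) {
    if (is.null(plantedDmrs))
        plantedDmrs <- data.frame(
            context = "CG", n_sites = 10L, level_ref = 0.8,
            level_trt = 0.2, placement = "gene_body",
            stringsAsFactors = FALSE)[rep(1L, 10L), ]
    rownames(plantedDmrs) <- NULL
    new("SimulationConfig", seed = as.integer(seed),
        nChroms = as.integer(nChroms),
        chromLengthBp = as.integer(chromLengthBp),
        nGenes = as.integer(nGenes),
        exonsPerGene = as.integer(exonsPerGene),
        siteDensity = siteDensity, baselineLevels = baselineLevels,
        tssDipHalfWidth = as.integer(tssDipHalfWidth),
        tssDipMultiplier = as.numeric(tssDipMultiplier),
        depthMean = as.numeric(depthMean),
        conversionError = as.numeric(conversionError),
        replicatesPerGroup = as.integer(replicatesPerGroup),
        plantedDmrs = plantedDmrs)
}

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(paste0("SimulationConfig: seed %d; %d x %.2g Mbp ",
                       "chromosomes, %d genes; depth ~Pois(%.3g), ",
                       "error %.3g, %d replicates/group; %d planted DMR(s)\n"),
                object@seed, object@nChroms,
                object@chromLengthBp / 1e6, object@nGenes,
                object@depthMean, object@conversionError,
                object@replicatesPerGroup, nrow(object@plantedDmrs)))
    invisible(object)
})

#' Simulate a non-overlapping gene annotation
#'
#' Places `nGenes` genes by rejection sampling so that no two genes
#' overlap, draws an exon count per gene from `exonsPerGene` and
#' partitions each gene span into alternating exons and introns.
#' Deterministic for a fixed config; with `gff3_path` set, identical
#' configs produce byte-identical files parseable by
#' [readGeneAnnotation()].
#'
#' @param cfg a [SimulationConfig-class].
#' @param gff3_path optional path; when given the annotation is also
#'   written as GFF3.
#' @return list with `genes` (a [GeneModels-class]) and `gff3_path`
#'   (`NULL` if not written).
#' @export
simulateAnnotation <- function(cfg, gff3_path = NULL) {
    stopifnot(is(cfg, "SimulationConfig"))
    set.seed(cfg@seed)
    chroms <- sprintf("chr%d", seq_len(cfg@nChroms))
    placed <- data.frame(chrom = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)
    gene_len_range <- c(2000L, 10000L)
    tries <- 0L
    while (nrow(placed) < cfg@nGenes) {
        tries <- tries + 1L
        if (tries > cfg@nGenes * 200L)
            stop("cannot place non-overlapping genes at this density")
        chr <- sample(chroms, 1L)
        len <- sample(gene_len_range[1]:gene_len_range[2], 1L)
        if (cfg@chromLengthBp - len - 1L < 2L)
            stop("chromosome too short for a gene")
        start <- sample(2L:(cfg@chromLengthBp - len), 1L)
        end <- start + len - 1L
        same <- placed[placed$chrom == chr, , drop = FALSE]
        if (nrow(same) && any(start <= same$end & end >= same$start))
            next
        placed <- rbind(placed, data.frame(chrom = chr, start = start,
                                           end = end,
                                           stringsAsFactors = FALSE))
    }
    if (!cfg@nGenes) {
        genes <- geneModels(GenomicRanges::GRanges(),
                            GenomicRanges::GRangesList())
        if (!is.null(gff3_path)) .writeGff3(genes, gff3_path)
        return(list(genes = genes, gff3_path = gff3_path))
    }
    placed <- placed[order(placed$chrom, placed$start), , drop = FALSE]
    strand <- sample(c("+", "-"), cfg@nGenes, replace = TRUE)
    ids <- sprintf("gene%03d", seq_len(cfg@nGenes))
    exon_list <- vector("list", cfg@nGenes)
    for (i in seq_len(cfg@nGenes)) {
        len <- placed$end[i] - placed$start[i] + 1L
        k <- sample(cfg@exonsPerGene[1]:cfg@exonsPerGene[2], 1L)
        k <- min(k, len %/% 200L)  # keep every segment >= ~100 bp
        k <- max(k, 1L)
        n_seg <- 2L * k - 1L
        # random interior breakpoints defining alternating exon/intron widths
        cuts <- sort(sample(seq_len(len - 1L), n_seg - 1L))
        bounds <- c(0L, cuts, len)
        seg_start <- placed$start[i] + bounds[-length(bounds)]
        seg_end <- placed$start[i] + bounds[-1] - 1L
        is_exon <- seq_len(n_seg) %% 2L == 1L
        exon_list[[i]] <- GenomicRanges::GRanges(
            placed$chrom[i],
            IRanges::IRanges(seg_start[is_exon], seg_end[is_exon]),
            strand = strand[i])
    }
    genes_gr <- GenomicRanges::GRanges(placed$chrom,
        IRanges::IRanges(placed$start, placed$end), strand = strand)
    names(genes_gr) <- ids
    genes <- geneModels(genes_gr, GenomicRanges::GRangesList(exon_list))
    validObject(genes)
    if (!is.null(gff3_path)) .writeGff3(genes, gff3_path)
    list(genes = genes, gff3_path = gff3_path)
}

# Deterministic GFF3 emission of gene/mRNA/exon features.
.writeGff3 <- function(genes, path) {
    lines <- "##gff-version 3"
    g <- geneRanges(genes)
    ex <- exonRanges(genes)
    for (i in seq_along(g)) {
        id <- names(g)[i]
        chr <- as.character(GenomicRanges::seqnames(g))[i]
        st <- as.character(GenomicRanges::strand(g))[i]
        lines <- c(lines,
            sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s", chr,
                    GenomicRanges::start(g)[i], GenomicRanges::end(g)[i],
                    st, id),
            sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                    chr, GenomicRanges::start(g)[i],
                    GenomicRanges::end(g)[i], st, id, id))
        e <- ex[[i]]
        lines <- c(lines,
            sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.t1.e%d;Parent=%s.t1",
                    chr, GenomicRanges::start(e), GenomicRanges::end(e),
                    st, id, seq_along(e), id))
    }
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con)
    invisible(path)
}

#' Simulate paired-group methylomes with planted DMRs
#'
#' Site positions are drawn uniformly per context at the configured
#' density. Each site's true level is its context baseline, multiplied
#' by the TSS-dip factor within the dip half-width of any TSS, and
#' overridden (group-specifically) inside planted differential regions,
#' which occupy runs of consecutive same-context sites at the requested
#' placement. Per replicate, depth is Poisson and the methylated count
#' binomial with success probability
#' `level * (1 - e) + (1 - level) * e` where `e` is the conversion/
#' sequencing error. Identical configs give identical outputs.
#'
#' @param cfg a [SimulationConfig-class].
#' @param genes a [GeneModels-class] (as from [simulateAnnotation()]).
#' @param outdir optional directory; when given, each replicate is also
#'   written as a cytosine report (`<group>_rep<i>.tsv`).
#' @return list with `reference` and `treatment` (lists of
#'   [MethylomeSample-class]) and `truth` (list with `planted`
#'   data.frame of planted intervals incl. direction, and `site_levels`
#'   data.frame of every site's true level per group).
#' @export
simulateMethylomes <- function(cfg, genes, outdir = NULL) {
    stopifnot(is(cfg, "SimulationConfig"), is(genes, "GeneModels"))
    set.seed(cfg@seed + 1L)
    chroms <- sprintf("chr%d", seq_len(cfg@nChroms))
    # unique positions genome-wide, then contexts assigned by density share
    per_chrom <- lapply(chroms, function(chr) {
        n_by_ctx <- round(cfg@siteDensity[.CONTEXTS] * cfg@chromLengthBp / 1000)
        n_tot <- sum(n_by_ctx)
        pos <- sort(sample.int(cfg@chromLengthBp, n_tot))
        ctx <- sample(rep(.CONTEXTS, times = n_by_ctx))
        data.frame(chrom = chr, pos = pos, ctx = ctx,
                   strand = sample(c("+", "-"), n_tot, replace = TRUE),
                   stringsAsFactors = FALSE)
    })
    sites <- do.call(rbind, per_chrom)
    lvl <- cfg@baselineLevels[sites$ctx]
    # TSS dip
    g <- geneRanges(genes)
    if (length(g) && cfg@tssDipHalfWidth > 0L) {
        minus <- as.character(GenomicRanges::strand(g)) == "-"
        tss <- ifelse(minus, GenomicRanges::end(g),
                      GenomicRanges::start(g))
        tss_chr <- as.character(GenomicRanges::seqnames(g))
        near <- rep(FALSE, nrow(sites))
        for (i in seq_along(tss)) {
            near <- near | (sites$chrom == tss_chr[i] &
                            abs(sites$pos - tss[i]) <= cfg@tssDipHalfWidth)
        }
        lvl[near] <- lvl[near] * cfg@tssDipMultiplier
    }
    lvl_ref <- lvl
    lvl_trt <- lvl
    # plant differential regions on runs of consecutive same-context sites
    planted <- .plantDmrs(cfg, genes, sites)
    if (nrow(planted)) {
        for (i in seq_len(nrow(planted))) {
            j <- planted$first_idx[i]:planted$last_idx[i]
            j <- j[sites$ctx[j] == planted$context[i]]
            lvl_ref[j] <- planted$level_ref[i]
            lvl_trt[j] <- planted$level_trt[i]
        }
    }
    e <- cfg@conversionError
    draw_group <- function(true_lvl, group) {
        p_obs <- true_lvl * (1 - e) + (1 - true_lvl) * e
        lapply(seq_len(cfg@replicatesPerGroup), function(r) {
            depth <- stats::rpois(nrow(sites), cfg@depthMean)
            nm <- stats::rbinom(nrow(sites), depth, p_obs)
            methylomeSample(chrom = sites$chrom, pos = sites$pos,
                            strand = sites$strand, context = sites$ctx,
                            n_meth = nm, n_unmeth = depth - nm,
                            sampleId = sprintf("%s_rep%d", group, r),
                            group = group)
        })
    }
    ref <- draw_group(lvl_ref, "reference")
    trt <- draw_group(lvl_trt, "treatment")
    if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        for (s in c(ref, trt))
            writeCytosineReport(s, file.path(outdir,
                                             paste0(sampleId(s), ".tsv")))
    }
    truth <- list(
        planted = planted[, setdiff(colnames(planted),
                                    c("first_idx", "last_idx")),
                          drop = FALSE],
        site_levels = data.frame(chrom = sites$chrom, pos = sites$pos,
                                 strand = sites$strand,
                                 context = sites$ctx,
                                 level_ref = lvl_ref,
                                 level_trt = lvl_trt,
                                 stringsAsFactors = FALSE))
    list(reference = ref, treatment = trt, truth = truth)
}

# Choose non-overlapping runs of consecutive same-context sites at the
# requested placements. Returns the planted table with site-index
# bounds into `sites`.
.plantDmrs <- function(cfg, genes, sites) {
    empty <- data.frame(chrom = character(), start = integer(),
                        end = integer(), context = character(),
                        n_sites = integer(), level_ref = numeric(),
                        level_trt = numeric(), placement = character(),
                        direction = character(), first_idx = integer(),
                        last_idx = integer(), stringsAsFactors = FALSE)
    pd <- cfg@plantedDmrs
    if (!nrow(pd)) return(empty)
    idx_regions <- buildRegionIndex(genes, promoter_bp = 2000L)
    used <- rep(FALSE, nrow(sites))
    out <- empty
    for (i in seq_len(nrow(pd))) {
        cx <- pd$context[i]
        n_req <- pd$n_sites[i]
        cand <- which(sites$ctx == cx)
        n_runs <- length(cand) - n_req + 1L
        ok_run <- NULL
        if (n_runs >= 1L) {
            first <- cand[seq_len(n_runs)]
            last <- cand[seq_len(n_runs) + n_req - 1L]
            same_chrom <- sites$chrom[first] == sites$chrom[last]
            spans <- GenomicRanges::GRanges(sites$chrom[first],
                IRanges::IRanges(sites$pos[first],
                                 pmax(sites$pos[first], sites$pos[last])))
            inside <- switch(pd$placement[i],
                promoter = IRanges::overlapsAny(spans,
                    promoterRanges(idx_regions), type = "within",
                    ignore.strand = TRUE),
                gene_body = IRanges::overlapsAny(spans,
                    geneBodyRanges(idx_regions), type = "within",
                    ignore.strand = TRUE),
                intergenic = !IRanges::overlapsAny(spans,
                        c(GenomicRanges::granges(geneRanges(genes)),
                          GenomicRanges::granges(
                              promoterRanges(idx_regions))),
                        ignore.strand = TRUE))
            ok <- which(same_chrom & inside)
            # scatter plants across the genome rather than first-fit
            for (j in ok[sample.int(length(ok))]) {
                run <- cand[j:(j + n_req - 1L)]
                if (!any(used[run])) { ok_run <- run; break }
            }
        }
        if (is.null(ok_run))
            stop(sprintf("cannot place planted DMR %d (%s, %d sites, %s): not enough eligible sites",
                         i, cx, n_req, pd$placement[i]))
        used[ok_run] <- TRUE
        out <- rbind(out, data.frame(
            chrom = sites$chrom[ok_run[1]],
            start = sites$pos[ok_run[1]],
            end = sites$pos[ok_run[length(ok_run)]],
            context = cx, n_sites = n_req,
            level_ref = pd$level_ref[i], level_trt = pd$level_trt[i],
            placement = pd$placement[i],
            direction = if (pd$level_trt[i] > pd$level_ref[i]) "hyper"
                        else "hypo",
            first_idx = ok_run[1], last_idx = ok_run[length(ok_run)],
            stringsAsFactors = FALSE))
    }
    out
}

#' Simulate a gene-to-term annotation with one optionally enriched term
#'
#' Genes are assigned to terms uniformly at random; an optional
#' designated term additionally annotates each gene of a target set
#' with probability `excess_prob`, creating a planted enrichment
#' signal. Deterministic per seed.
#'
#' @param genes a [GeneModels-class] or character vector of gene ids.
#' @param n_terms number of background terms.
#' @param genes_per_term length-2 range of genes per background term.
#' @param enriched_term optional list with `term_id`, `target_genes`,
#'   `excess_prob`.
#' @param seed integer seed.
#' @param path optional TSV output path (gene_id, term_id).
#' @return data.frame (`gene_id`, `term_id`), invisibly also written to
#'   `path` when given.
#' @export
simulateTerms <- function(genes, n_terms = 20L,
                          genes_per_term = c(5L, 15L),
                          enriched_term = NULL, seed = 1L, path = NULL) {
    ids <- if (is(genes, "GeneModels")) geneIds(genes)
           else as.character(genes)
    set.seed(seed)
    out <- do.call(rbind, lapply(seq_len(n_terms), function(t) {
        k <- sample(genes_per_term[1]:genes_per_term[2], 1L)
        k <- min(k, length(ids))
        data.frame(gene_id = sort(sample(ids, k)),
                   term_id = sprintf("TERM%03d", t),
                   stringsAsFactors = FALSE)
    }))
    if (!is.null(enriched_term)) {
        hit <- enriched_term$target_genes[
            stats::runif(length(enriched_term$target_genes)) <
                enriched_term$excess_prob]
        if (length(hit))
            out <- rbind(out, data.frame(gene_id = hit,
                                         term_id = enriched_term$term_id,
                                         stringsAsFactors = FALSE))
    }
    out <- unique(out[order(out$term_id, out$gene_id), , drop = FALSE])
    rownames(out) <- NULL
    if (!is.null(path)) {
        con <- file(path, open = "wb")
        on.exit(close(con))
        utils::write.table(out, con, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    }
    out
}

#' Simulate a qPCR plate with a planted expression fold change
#'
#' Reference-gene Ct ~ Normal(20, sd); target Ct in the reference group
#' ~ Normal(25, sd); the treatment group's target Ct is shifted by
#' `-log2(true_fold)` (one fewer cycle per doubling of expression).
#'
#' @param n_per_group samples per group.
#' @param true_fold planted expression fold (treatment / reference).
#' @param ct_noise_sd Ct noise standard deviation.
#' @param seed integer seed.
#' @param path optional TSV output path.
#' @return plate data.frame (`sample_id`, `group`, `gene`, `ct`) with
#'   genes `target` and `ef1a`.
#' @export
simulateQpcrPlate <- function(n_per_group = 6L, true_fold = 1,
                              ct_noise_sd = 0.15, seed = 1L,
                              path = NULL) {
    set.seed(seed)
    mk <- function(group, shift) {
        sid <- sprintf("%s_%d", group, seq_len(n_per_group))
        rbind(data.frame(sample_id = sid, group = group, gene = "ef1a",
                         ct = stats::rnorm(n_per_group, 20, ct_noise_sd),
                         stringsAsFactors = FALSE),
              data.frame(sample_id = sid, group = group, gene = "target",
                         ct = stats::rnorm(n_per_group, 25 + shift,
                                           ct_noise_sd),
                         stringsAsFactors = FALSE))
    }
    plate <- rbind(mk("reference", 0), mk("treatment", -log2(true_fold)))
    if (!is.null(path)) {
        con <- file(path, open = "wb")
        on.exit(close(con))
        utils::write.table(plate, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    plate
}
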