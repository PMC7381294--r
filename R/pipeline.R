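#' Run the full simulated analysis pipeline
#'
#' Orchestrates simulate -> summarize -> DMR -> DMG -> enrichment ->
#' qPCR into one result directory. Every stage output is written as a
#' plain-text table re-loadable by its owning reader, and a JSON
#' manifest records the parameters, seed, package version and record
#' counts at each stage. Reruns with the same configuration are
#' byte-identical (the manifest carries no timestamp).
#'
#' @param outdir result directory (created if needed).
#' @param cfg a [SimulationConfig-class] (default
#'   `simulationConfig(seed = seed)`).
#' @param seed seed used when `cfg` is not supplied, and for the term /
#'   qPCR simulations.
#' @param params a [DmrParams-class].
#' @param promoter_bp promoter length for DMG assignment.
#' @param enrich_method `"bonferroni"` or `"bh"`.
#' @param enrich_alpha significance level on corrected p.
#' @param qpcr_true_fold,qpcr_noise_sd,qpcr_n_per_group qPCR stage
#'   design.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(outdir, cfg = NULL, seed = 42L,
                        params = dmrParams(), promoter_bp = 2000L,
                        enrich_method = "bonferroni",
                        enrich_alpha = 0.05, qpcr_true_fold = 3,
                        qpcr_noise_sd = 0.15, qpcr_n_per_group = 6L) {
    if (is.null(cfg)) cfg <- simulationConfig(seed = seed)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))
    }
    ann <- stage("simulate_annotation",
                 simulateAnnotation(cfg, file.path(outdir, "genes.gff3")))
    sim <- stage("simulate_methylomes",
                 simulateMethylomes(cfg, ann$genes,
                                    outdir = file.path(outdir, "methylomes")))
    gsum <- stage("global_summary", {
        s <- globalSummary(.pooledSample(sim$reference))
        writeSummaryTable(s, file.path(outdir, "global_summary.tsv"))
        s
    })
    prof <- stage("region_profile", {
        p <- regionProfile(.pooledSample(sim$reference), ann$genes)
        writeSummaryTable(p, file.path(outdir, "region_profile.tsv"))
        p
    })
    dmrs <- stage("dmr", {
        d <- callDmrs(sim$reference, sim$treatment, params)
        writeDmrBed(d, file.path(outdir, "dmrs.bed"))
        d
    })
    index <- buildRegionIndex(ann$genes, promoter_bp)
    dmgs <- stage("annotate", {
        a <- assignDmgs(dmrs, index)
        writeDmgTable(a, file.path(outdir, "dmgs.tsv"))
        counts <- dmgCountTable(a)
        writeSummaryTable(counts, file.path(outdir, "dmg_counts.tsv"))
        a
    })
    enr <- stage("enrich", {
        dmg_genes <- unique(dmgs$gene_id)
        terms <- simulateTerms(ann$genes, seed = cfg@seed + 2L,
                               enriched_term = if (length(dmg_genes))
                                   list(term_id = "TERM_PLANTED",
                                        target_genes = dmg_genes,
                                        excess_prob = 0.9) else NULL,
                               path = file.path(outdir, "terms.tsv"))
        e <- if (length(dmg_genes))
            enrich(dmg_genes, terms, method = enrich_method,
                   alpha = enrich_alpha)
        else
            data.frame()
        writeEnrichmentTable(e, file.path(outdir, "enrichment.tsv"))
        e
    })
    qp <- stage("qpcr", {
        plate <- simulateQpcrPlate(qpcr_n_per_group, qpcr_true_fold,
                                   qpcr_noise_sd, seed = cfg@seed + 3L,
                                   path = file.path(outdir, "qpcr_plate.tsv"))
        res <- ddctFoldChange(plate, "target")
        writeSummaryTable(res$per_sample,
                          file.path(outdir, "qpcr_per_sample.tsv"))
        writeSummaryTable(res$per_group,
                          file.path(outdir, "qpcr_per_group.tsv"))
        res
    })
    manifest <- list(
        package_version = as.character(utils::packageVersion("methylWindows")),
        seed = cfg@seed,
        simulation = list(n_chroms = cfg@nChroms,
                          chrom_length_bp = cfg@chromLengthBp,
                          n_genes = cfg@nGenes,
                          depth_mean = cfg@depthMean,
                          conversion_error = cfg@conversionError,
                          replicates_per_group = cfg@replicatesPerGroup,
                          n_planted_dmrs = nrow(cfg@plantedDmrs)),
        dmr_params = list(window_sites = params@windowSites,
                          min_fold = params@minFold,
                          alpha = params@alpha,
                          min_depth = params@minDepth,
                          pseudocount = params@pseudocount,
                          max_merge_gap = if (is.infinite(params@maxMergeGap))
                              "unlimited" else params@maxMergeGap,
                          fdr = params@fdr),
        promoter_bp = as.integer(promoter_bp),
        enrichment = list(method = enrich_method, alpha = enrich_alpha),
        counts = list(
            genes = length(ann$genes),
            sites_per_sample = length(sim$reference[[1]]),
            dmrs = length(dmrs),
            dmrs_per_context = as.list(table(
                factor(mcols(dmrs)$context, levels = .CONTEXTS))),
            dmg_rows = nrow(dmgs),
            dmg_genes = length(unique(dmgs$gene_id)),
            enriched_terms = if (nrow(enr)) sum(enr$significant) else 0L,
            qpcr_samples = nrow(qp$per_sample)))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
}

# Pool replicates of one group into a single sample (sums counts per
# site) for whole-group summaries.
.pooledSample <- function(samples) {
    if (is(samples, "MethylomeSample")) return(samples)
    if (length(samples) == 1L) return(samples[[1]])
    parts <- lapply(.CONTEXTS, function(cx) {
        df <- .poolGroup(samples, cx)
        df$ctx <- cx
        df
    })
    df <- do.call(rbind, parts)
    methylomeSample(chrom = df$chrom, pos = df$pos, strand = df$strand,
                    context = df$ctx, n_meth = df$n_meth,
                    n_unmeth = df$n_unmeth,
                    sampleId = paste0(sampleGroup(samples[[1]]), "_pooled"),
                    group = sampleGroup(samples[[1]]))
}
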