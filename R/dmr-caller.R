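#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p for the table \[\[a, b\], \[c, d\]\] by exhaustive
#' enumeration: all tables with the observed margins whose
#' hypergeometric probability is no larger than that of the observed
#' table (with a relative tolerance of 1e-7 on the comparison) are
#' summed. A zero row or column margin carries no evidence and returns
#' 1.
#'
#' @param a,b,c,d non-negative cell counts; rows are groups, columns
#'   methylated/unmethylated.
#' @return the two-sided p-value.
#' @examples
#' fisherExactTwoSided(5, 5, 5, 5)   # 1
#' fisherExactTwoSided(2, 8, 8, 2)   # ~0.023
#' @export
fisherExactTwoSided <- function(a, b, c, d) {
    stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
    n <- a + b + c + d
    if (n < 1) stop("table must contain at least one observation")
    r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
    if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
    # support of the (1,1) cell given the margins
    lo <- max(0, c1 - r2); hi <- min(r1, c1)
    x <- lo:hi
    # log P(table | margins), hypergeometric
    logp <- lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
    logp_obs <- logp[x == a]
    p <- sum(exp(logp[logp <= logp_obs + log(1 + 1e-7)]))
    min(1, p)
}

# Pool counts across replicates within one group for one context.
# Returns data.frame(chrom, pos, strand, n_meth, n_unmeth) keyed by
# site, sorted by (chrom, pos, strand).
.poolGroup <- function(samples, context) {
    parts <- lapply(samples, function(s) {
        mc <- mcols(s)
        i <- mc$context == context
        data.frame(chrom = as.character(GenomicRanges::seqnames(s))[i],
                   pos = GenomicRanges::start(s)[i],
                   strand = as.character(GenomicRanges::strand(s))[i],
                   n_meth = mc$n_meth[i], n_unmeth = mc$n_unmeth[i],
                   stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, parts)
    if (!nrow(df))
        return(df[, c("chrom", "pos", "strand", "n_meth", "n_unmeth")])
    key <- paste(df$chrom, df$pos, df$strand, sep = "\r")
    nm <- rowsum(df$n_meth, key)
    nu <- rowsum(df$n_unmeth, key)
    k <- strsplit(rownames(nm), "\r", fixed = TRUE)
    out <- data.frame(chrom = vapply(k, `[`, "", 1L),
                      pos = as.integer(vapply(k, `[`, "", 2L)),
                      strand = vapply(k, `[`, "", 3L),
                      n_meth = as.integer(nm[, 1]),
                      n_unmeth = as.integer(nu[, 1]),
                      stringsAsFactors = FALSE)
    out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
}

# Sites of one context eligible for windowing: pooled depth >= minDepth
# in BOTH groups. Columns: chrom, pos, strand, mr, ur, mt, ut.
.eligibleSites <- function(ref_samples, trt_samples, context, minDepth) {
    ref <- .poolGroup(ref_samples, context)
    trt <- .poolGroup(trt_samples, context)
    kr <- paste(ref$chrom, ref$pos, ref$strand, sep = "\r")
    kt <- paste(trt$chrom, trt$pos, trt$strand, sep = "\r")
    i <- match(kr, kt)
    hit <- !is.na(i)
    out <- data.frame(chrom = ref$chrom[hit], pos = ref$pos[hit],
                      strand = ref$strand[hit],
                      mr = ref$n_meth[hit], ur = ref$n_unmeth[hit],
                      mt = trt$n_meth[i[hit]], ut = trt$n_unmeth[i[hit]],
                      stringsAsFactors = FALSE)
    keep <- (out$mr + out$ur) >= minDepth & (out$mt + out$ut) >= minDepth
    out <- out[keep, , drop = FALSE]
    out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
}

#' Build non-overlapping windows of eligible same-context sites
#'
#' Within each chromosome, sites of the given context whose pooled depth
#' reaches `minDepth` in both groups (replicates pooled within group)
#' are taken in coordinate order and partitioned into consecutive,
#' non-overlapping blocks of `windowSites`; a trailing remainder shorter
#' than a full window is discarded. Counts are pooled across replicates
#' and across the window's sites.
#'
#' @param ref_samples,trt_samples lists of [MethylomeSample-class] (one
#'   or more replicates per group).
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param params a [DmrParams-class].
#' @return data.frame with one row per window: `chrom`, `start`, `end`
#'   (1-based inclusive span of the first/last site), `context`,
#'   `n_sites`, pooled counts `mr`, `ur` (reference methylated /
#'   unmethylated) and `mt`, `ut` (treatment), and a `positions` list
#'   column of site positions.
#' @export
buildWindows <- function(ref_samples, trt_samples, context, params = dmrParams()) {
    if (is(ref_samples, "MethylomeSample")) ref_samples <- list(ref_samples)
    if (is(trt_samples, "MethylomeSample")) trt_samples <- list(trt_samples)
    if (!length(ref_samples) || !length(trt_samples))
        stop("both groups need at least one sample")
    sites <- .eligibleSites(ref_samples, trt_samples, context,
                            params@minDepth)
    .windowsFromSites(sites, context, params@windowSites)
}

.windowsFromSites <- function(sites, context, windowSites) {
    empty <- data.frame(chrom = character(), start = integer(),
                        end = integer(), context = character(),
                        n_sites = integer(), mr = integer(),
                        ur = integer(), mt = integer(), ut = integer())
    empty$positions <- list()
    if (!nrow(sites)) return(empty)
    out <- list()
    for (chr in unique(sites$chrom)) {
        s <- sites[sites$chrom == chr, , drop = FALSE]
        n_win <- nrow(s) %/% windowSites
        if (n_win == 0L) next
        for (w in seq_len(n_win)) {
            i <- ((w - 1L) * windowSites + 1L):(w * windowSites)
            blk <- s[i, , drop = FALSE]
            row <- data.frame(chrom = chr, start = min(blk$pos),
                              end = max(blk$pos), context = context,
                              n_sites = windowSites,
                              mr = sum(blk$mr), ur = sum(blk$ur),
                              mt = sum(blk$mt), ut = sum(blk$ut),
                              stringsAsFactors = FALSE)
            row$positions <- list(blk$pos)
            out[[length(out) + 1L]] <- row
        }
    }
    if (!length(out)) return(empty)
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

# Pseudocounted level and symmetric fold change between two pooled
# count pairs; fold = max(r, 1/r) on pseudocounted levels.
.foldChange <- function(mr, ur, mt, ut, pseudocount) {
    lr <- (mr + pseudocount) / (mr + ur + 2 * pseudocount)
    lt <- (mt + pseudocount) / (mt + ut + 2 * pseudocount)
    r <- lt / lr
    pmax(r, 1 / r)
}

#' Test one window for differential methylation
#'
#' Computes pooled levels, the pseudocounted fold change and the
#' two-sided Fisher exact p on the 2x2 table of pooled group counts.
#' The window is a DMR iff fold >= `minFold` AND p <= `alpha` (both
#' inclusive, as published).
#'
#' @param w a one-row window as produced by [buildWindows()].
#' @param params a [DmrParams-class].
#' @return a one-row DMR data.frame, or `NULL` if the window fails
#'   either gate.
#' @export
testWindow <- function(w, params = dmrParams()) {
    p <- fisherExactTwoSided(w$mr, w$ur, w$mt, w$ut)
    fold <- .foldChange(w$mr, w$ur, w$mt, w$ut, params@pseudocount)
    if (!(fold >= params@minFold && p <= params@alpha)) return(NULL)
    lr <- w$mr / (w$mr + w$ur)
    lt <- w$mt / (w$mt + w$ut)
    data.frame(chrom = w$chrom, start = w$start, end = w$end,
               context = w$context,
               level_ref = lr, level_trt = lt, fold_change = fold,
               p_value = p,
               direction = if (lt > lr) "hyper" else "hypo",
               n_sites = w$n_sites, merged_from = 1L,
               stringsAsFactors = FALSE)
}

# Vectorised window testing; returns the DMR data.frame (0 rows if none).
.testWindows <- function(wins, params) {
    if (!nrow(wins)) return(.emptyDmrDf())
    p <- mapply(fisherExactTwoSided, wins$mr, wins$ur, wins$mt, wins$ut)
    p_gate <- if (params@fdr) stats::p.adjust(p, method = "BH") else p
    fold <- .foldChange(wins$mr, wins$ur, wins$mt, wins$ut,
                        params@pseudocount)
    keep <- fold >= params@minFold & p_gate <= params@alpha
    if (!any(keep)) return(.emptyDmrDf())
    w <- wins[keep, , drop = FALSE]
    lr <- w$mr / (w$mr + w$ur)
    lt <- w$mt / (w$mt + w$ut)
    data.frame(chrom = w$chrom, start = w$start, end = w$end,
               context = w$context, level_ref = lr, level_trt = lt,
               fold_change = fold[keep], p_value = p[keep],
               direction = ifelse(lt > lr, "hyper", "hypo"),
               n_sites = w$n_sites, merged_from = 1L,
               stringsAsFactors = FALSE)
}

.emptyDmrDf <- function() {
    data.frame(chrom = character(), start = integer(), end = integer(),
               context = character(), level_ref = numeric(),
               level_trt = numeric(), fold_change = numeric(),
               p_value = numeric(), direction = character(),
               n_sites = integer(), merged_from = integer(),
               stringsAsFactors = FALSE)
}

#' Join neighboring DMRs whose span keeps a twofold difference
#'
#' Left-to-right greedy scan over consecutive same-chromosome,
#' same-context, same-direction DMR pairs (gap at most `maxMergeGap`):
#' the span from the upstream DMR's start to the downstream DMR's end is
#' re-pooled over ALL eligible sites of that context in the span, in
#' both groups; if the span's pseudocounted fold change reaches
#' `minFold` the pair becomes one DMR with recomputed levels, fold,
#' Fisher p, site count and merge provenance. Otherwise the two DMRs
#' stay independent. Scanning repeats until a full pass makes no merge.
#'
#' @param dmrs DMR data.frame sorted by (chrom, start) within one
#'   context (as produced internally by [callDmrs()]).
#' @param sites eligible-site count table for the same context, as
#'   columns `chrom`, `pos`, `mr`, `ur`, `mt`, `ut`.
#' @param params a [DmrParams-class].
#' @return the merged DMR data.frame (idempotent: re-applying changes
#'   nothing).
#' @export
mergeAdjacentDmrs <- function(dmrs, sites, params = dmrParams()) {
    if (!nrow(dmrs)) return(dmrs)
    if (length(unique(dmrs$context)) > 1L)
        stop("'dmrs' must contain a single context")
    o <- order(dmrs$chrom, dmrs$start)
    if (!identical(o, seq_len(nrow(dmrs))))
        stop("'dmrs' must be sorted by (chrom, start)")
    repeat {
        merged_any <- FALSE
        i <- 1L
        out <- list()
        while (i <= nrow(dmrs)) {
            cur <- dmrs[i, , drop = FALSE]
            while (i < nrow(dmrs)) {
                nxt <- dmrs[i + 1L, , drop = FALSE]
                gap <- nxt$start - cur$end - 1L
                if (!(nxt$chrom == cur$chrom &&
                      nxt$direction == cur$direction &&
                      gap <= params@maxMergeGap)) break
                span <- .spanDmr(cur, nxt, sites, params)
                if (is.null(span)) break
                cur <- span
                merged_any <- TRUE
                i <- i + 1L
            }
            out[[length(out) + 1L]] <- cur
            i <- i + 1L
        }
        dmrs <- do.call(rbind, out)
        rownames(dmrs) <- NULL
        if (!merged_any) break
    }
    dmrs
}

# Re-pool the span of two DMRs over all eligible sites; returns the
# merged one-row DMR if the span fold passes, else NULL.
.spanDmr <- function(up, dn, sites, params) {
    s <- sites[sites$chrom == up$chrom & sites$pos >= up$start &
               sites$pos <= dn$end, , drop = FALSE]
    mr <- sum(s$mr); ur <- sum(s$ur); mt <- sum(s$mt); ut <- sum(s$ut)
    fold <- .foldChange(mr, ur, mt, ut, params@pseudocount)
    if (fold < params@minFold) return(NULL)
    lr <- mr / (mr + ur)
    lt <- mt / (mt + ut)
    data.frame(chrom = up$chrom, start = up$start, end = dn$end,
               context = up$context, level_ref = lr, level_trt = lt,
               fold_change = fold,
               p_value = fisherExactTwoSided(mr, ur, mt, ut),
               direction = up$direction, n_sites = nrow(s),
               merged_from = up$merged_from + dn$merged_from,
               stringsAsFactors = FALSE)
}

#' Call differentially methylated regions between two groups
#'
#' The full published rule, per context: pool replicate counts within
#' each group; partition eligible sites into non-overlapping
#' `windowSites`-site windows; keep windows with a pseudocounted fold
#' change of at least `minFold` and a two-sided Fisher exact p of at
#' most `alpha`; then join neighboring same-direction DMRs whenever the
#' whole span from the upstream DMR's start to the downstream DMR's end
#' still shows at least a `minFold` difference.
#'
#' @param ref_samples,trt_samples lists of [MethylomeSample-class].
#' @param params a [DmrParams-class].
#' @param contexts contexts to analyse (default all three).
#' @return a [GenomicRanges::GRanges] sorted by (chrom, start) with
#'   metadata columns `context`, `level_ref`, `level_trt`,
#'   `fold_change`, `p_value`, `direction`, `n_sites`, `merged_from`.
#' @examples
#' cfg <- simulationConfig(seed = 1, nGenes = 5L, chromLengthBp = 50000L)
#' ann <- simulateAnnotation(cfg)
#' sim <- simulateMethylomes(cfg, ann$genes)
#' callDmrs(sim$reference, sim$treatment)
#' @export
callDmrs <- function(ref_samples, trt_samples, params = dmrParams(),
                     contexts = c("CG", "CHG", "CHH")) {
    if (is(ref_samples, "MethylomeSample")) ref_samples <- list(ref_samples)
    if (is(trt_samples, "MethylomeSample")) trt_samples <- list(trt_samples)
    if (!length(ref_samples) || !length(trt_samples))
        stop("both groups need at least one sample")
    contexts <- match.arg(contexts, .CONTEXTS, several.ok = TRUE)
    res <- lapply(contexts, function(cx) {
        sites <- .eligibleSites(ref_samples, trt_samples, cx, params@minDepth)
        wins <- .windowsFromSites(sites, cx, params@windowSites)
        dmrs <- .testWindows(wins, params)
        if (nrow(dmrs))
            dmrs <- mergeAdjacentDmrs(dmrs, sites, params)
        dmrs
    })
    df <- do.call(rbind, res)
    if (!nrow(df)) {
        gr <- GenomicRanges::GRanges()
        mcols(gr) <- DataFrame(context = character(),
                               level_ref = numeric(), level_trt = numeric(),
                               fold_change = numeric(), p_value = numeric(),
                               direction = character(), n_sites = integer(),
                               merged_from = integer())
        return(gr)
    }
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end),
                                 strand = "*")
    mcols(gr) <- DataFrame(context = df$context, level_ref = df$level_ref,
                           level_trt = df$level_trt,
                           fold_change = df$fold_change,
                           p_value = df$p_value, direction = df$direction,
                           n_sites = df$n_sites,
                           merged_from = df$merged_from)
    gr
}
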