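#' Read a qPCR plate table
#'
#' TSV with header columns `sample_id`, `group`, `gene`, `ct` and
#' optionally `replicate`. Technical replicates are kept as separate
#' rows and averaged at the Ct level by [ddctFoldChange()].
#'
#' @param path TSV path.
#' @return the validated plate data.frame.
#' @export
readQpcrPlate <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    need <- c("sample_id", "group", "gene", "ct")
    if (!all(need %in% colnames(df)))
        stop(sprintf("plate file needs columns %s",
                     paste(need, collapse = ", ")))
    if (any(!df$group %in% .GROUPS))
        stop("plate 'group' must be 'reference' or 'treatment'")
    if (any(df$ct <= 0)) stop("Ct values must be positive")
    df
}

#' Relative expression by the comparative Ct method
#'
#' The Livak 2^-ddCt quantification: per sample,
#' dCt = mean Ct(target) - mean Ct(reference gene); ddCt = dCt -
#' mean dCt over reference-group samples; fold = 2^-ddCt. Note the
#' negative exponent: higher expression means fewer cycles to
#' threshold, so a lower Ct must map to a larger fold.
#'
#' @param plate data.frame as from [readQpcrPlate()] or
#'   [simulateQpcrPlate()].
#' @param target_gene the gene quantified.
#' @param reference_gene the endogenous reference (default `"ef1a"`).
#' @return list with `per_sample` (sample_id, group, dct, ddct, fold)
#'   and `per_group` (group, mean_fold, se_fold, n, plus
#'   `fold_from_mean_ddct`, the fold of the group-mean ddCt, which is
#'   exactly 1 for the reference group).
#' @examples
#' plate <- simulateQpcrPlate(n_per_group = 3, true_fold = 4,
#'                            ct_noise_sd = 0, seed = 1)
#' ddctFoldChange(plate, "target")$per_group
#' @export
ddctFoldChange <- function(plate, target_gene, reference_gene = "ef1a") {
    stopifnot(all(c("sample_id", "group", "gene", "ct") %in%
                  colnames(plate)))
    samples <- unique(plate[c("sample_id", "group")])
    dct <- vapply(seq_len(nrow(samples)), function(i) {
        rows <- plate$sample_id == samples$sample_id[i]
        tgt <- plate$ct[rows & plate$gene == target_gene]
        ref <- plate$ct[rows & plate$gene == reference_gene]
        if (!length(ref))
            stop(sprintf("sample '%s' has no reference-gene ('%s') measurement",
                         samples$sample_id[i], reference_gene))
        if (!length(tgt))
            stop(sprintf("sample '%s' has no '%s' measurement",
                         samples$sample_id[i], target_gene))
        mean(tgt) - mean(ref)
    }, numeric(1))
    is_ref <- samples$group == "reference"
    if (!any(is_ref)) stop("reference group is empty")
    anchor <- mean(dct[is_ref])
    ddct <- dct - anchor
    fold <- 2^(-ddct)
    per_sample <- data.frame(sample_id = samples$sample_id,
                             group = samples$group, dct = dct,
                             ddct = ddct, fold = fold,
                             stringsAsFactors = FALSE)
    per_group <- do.call(rbind, lapply(.GROUPS, function(g) {
        f <- fold[samples$group == g]
        if (!length(f)) return(NULL)
        data.frame(group = g, mean_fold = mean(f),
                   se_fold = if (length(f) > 1)
                       stats::sd(f) / sqrt(length(f)) else NA_real_,
                   n = length(f),
                   fold_from_mean_ddct =
                       2^(-(mean(dct[samples$group == g]) - anchor)),
                   stringsAsFactors = FALSE)
    }))
    list(per_sample = per_sample, per_group = per_group)
}
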