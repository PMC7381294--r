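#' Upper-tail hypergeometric probability
#'
#' The over-representation statistic
#' \deqn{p = 1 - \sum_{i=0}^{m-1} \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}}
#'        = P(X \ge m)}
#' for X hypergeometric with `N` annotated genes in the universe, `M` of
#' them annotated to the term, and `n` selected genes. Computed as a
#' direct log-gamma sum over the upper tail (numerically stable; no
#' cancellation against 1).
#'
#' @param N universe size (genes with any annotation).
#' @param M genes annotated to the term.
#' @param n selected genes.
#' @param m selected genes annotated to the term (vectorised over `m`).
#' @return `P(X >= m)`.
#' @examples
#' hypergeomUpperTail(4, 2, 2, 2)  # 1/6
#' hypergeomUpperTail(100, 10, 10, 0)  # 1
#' @export
hypergeomUpperTail <- function(N, M, n, m) {
    stopifnot(length(N) == 1L, length(M) == 1L, length(n) == 1L)
    if (M < 0 || M > N || n < 0 || n > N)
        stop("need 0 <= M <= N and 0 <= n <= N")
    if (any(m < 0) || any(m > pmin(n, M)))
        stop("need 0 <= m <= min(n, M)")
    hi <- min(n, M)
    lo_support <- max(0, n - (N - M))
    denom <- lchoose(N, n)
    vapply(m, function(mm) {
        if (mm <= lo_support) return(1)
        i <- mm:hi
        sum(exp(lchoose(M, i) + lchoose(N - M, n - i) - denom))
    }, numeric(1))
}

#' Gene-set over-representation of a selected gene list
#'
#' One hypergeometric upper-tail test per term with at least one
#' annotated gene in the universe, followed by Bonferroni correction
#' (`p_adj = min(1, p_raw * T)` with `T` the number of tested terms) or
#' optionally Benjamini-Hochberg. The universe defaults to all genes
#' carrying at least one annotation; selected genes outside the
#' universe are dropped with a warning. Results are sorted by raw p,
#' ties broken by term id, so repeated runs are byte-identical.
#'
#' @param selected_genes character vector of selected (e.g. DMG) gene
#'   ids.
#' @param terms data.frame with columns `gene_id`, `term_id` and
#'   optionally `term_name` (see [readTermAnnotation()]).
#' @param universe optional character vector restricting the annotated
#'   universe.
#' @param method `"bonferroni"` (default, as published) or `"bh"`.
#' @param alpha significance level on the corrected p (default 0.05).
#' @return data.frame with columns `term_id`, `term_name`, `N`, `n`,
#'   `M`, `m`, `rich_factor` (m/M), `p_raw`, `p_adj`, `significant`.
#' @export
enrich <- function(selected_genes, terms, universe = NULL,
                   method = c("bonferroni", "bh"), alpha = 0.05) {
    method <- match.arg(method)
    stopifnot(all(c("gene_id", "term_id") %in% colnames(terms)))
    annotated <- unique(terms$gene_id)
    uni <- if (is.null(universe)) annotated
           else intersect(unique(universe), annotated)
    if (!length(uni)) stop("empty annotation universe")
    terms <- terms[terms$gene_id %in% uni, , drop = FALSE]
    selected_genes <- unique(selected_genes)
    dropped <- setdiff(selected_genes, uni)
    if (length(dropped))
        warning(sprintf("%d selected gene(s) outside the annotated universe were dropped",
                        length(dropped)))
    sel <- intersect(selected_genes, uni)
    N <- length(uni)
    n <- length(sel)
    term_genes <- split(terms$gene_id, terms$term_id)
    term_ids <- names(term_genes)
    name_map <- if ("term_name" %in% colnames(terms))
        terms$term_name[match(term_ids, terms$term_id)]
    else term_ids
    M <- vapply(term_genes, function(g) length(unique(g)), integer(1))
    m <- vapply(term_genes, function(g) length(intersect(unique(g), sel)),
                integer(1))
    keep <- M >= 1L
    term_ids <- term_ids[keep]; name_map <- name_map[keep]
    M <- M[keep]; m <- m[keep]
    p_raw <- mapply(function(MM, mm) hypergeomUpperTail(N, MM, n, mm), M, m)
    T_tests <- length(term_ids)
    p_adj <- switch(method,
        bonferroni = pmin(1, p_raw * T_tests),
        bh = stats::p.adjust(p_raw, method = "BH"))
    out <- data.frame(term_id = term_ids, term_name = name_map,
                      N = N, n = n, M = as.integer(M), m = as.integer(m),
                      rich_factor = ifelse(M > 0, m / M, NA_real_),
                      p_raw = p_raw, p_adj = p_adj,
                      significant = p_adj <= alpha,
                      stringsAsFactors = FALSE)
    out <- out[order(out$p_raw, out$term_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write enrichment results as TSV
#'
#' @param results data.frame from [enrich()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEnrichmentTable <- function(results, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    utils::write.table(results, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
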