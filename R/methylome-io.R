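#' Read a per-cytosine methylation count report
#'
#' Parses the tab-separated per-cytosine report dialect (Bismark
#' coverage/CX-report family): columns chrom, 1-based position, strand,
#' methylated read count, unmethylated read count, context, with an
#' optional trailing trinucleotide column that is ignored. Zero-coverage
#' sites are retained; they carry position information but are excluded
#' from all downstream statistics.
#'
#' @param path path to the TSV file (no header).
#' @param sampleId label for the sample (default: file name sans
#'   extension).
#' @param group `"reference"` or `"treatment"`.
#' @return a [MethylomeSample-class] sorted by (chrom, pos, strand).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("chr1\t10\t+\t8\t2\tCG", "chr1\t25\t-\t0\t5\tCHH"), f)
#' readCytosineReport(f, sampleId = "demo")
#' @export
readCytosineReport <- function(path, sampleId = NULL, group = "reference") {
    if (is.null(sampleId))
        sampleId <- sub("\\.[^.]*$", "", basename(path))
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(methylomeSample(sampleId = sampleId, group = group))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf < 6L)
    if (length(bad))
        stop(sprintf("malformed cytosine report line %d in '%s': expected >= 6 tab-separated fields, got %d",
                     bad[1], path, nf[bad[1]]))
    m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6L, byrow = TRUE)
    pos <- suppressWarnings(as.integer(m[, 2]))
    n_meth <- suppressWarnings(as.integer(m[, 4]))
    n_unmeth <- suppressWarnings(as.integer(m[, 5]))
    bad <- which(is.na(pos) | is.na(n_meth) | is.na(n_unmeth) |
                 pos < 1L | n_meth < 0L | n_unmeth < 0L)
    if (length(bad))
        stop(sprintf("malformed cytosine report line %d in '%s': non-numeric or negative position/count",
                     bad[1], path))
    bad <- which(!m[, 3] %in% c("+", "-"))
    if (length(bad))
        stop(sprintf("malformed cytosine report line %d in '%s': strand must be + or -",
                     bad[1], path))
    bad <- which(!m[, 6] %in% .CONTEXTS)
    if (length(bad))
        stop(sprintf("unknown context token '%s' at line %d in '%s' (expected CG, CHG or CHH)",
                     m[bad[1], 6], bad[1], path))
    key <- paste(m[, 1], pos, m[, 3])
    if (anyDuplicated(key)) {
        d <- key[duplicated(key)][1]
        stop(sprintf("duplicate site key (%s) in '%s'", d, path))
    }
    methylomeSample(chrom = m[, 1], pos = pos, strand = m[, 3],
                    context = m[, 6], n_meth = n_meth,
                    n_unmeth = n_unmeth, sampleId = sampleId,
                    group = group)
}

#' Write a per-cytosine methylation count report
#'
#' Inverse of [readCytosineReport()]: `readCytosineReport(writeCytosineReport(s))`
#' reproduces `s` field for field.
#'
#' @param sample a [MethylomeSample-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCytosineReport <- function(sample, path) {
    stopifnot(is(sample, "MethylomeSample"))
    validObject(sample)
    mc <- mcols(sample)
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s",
                     as.character(GenomicRanges::seqnames(sample)),
                     GenomicRanges::start(sample),
                     as.character(GenomicRanges::strand(sample)),
                     mc$n_meth, mc$n_unmeth, mc$context)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con)
    invisible(path)
}

#' Classify the sequence context of a cytosine
#'
#' From the two nucleotides immediately 3' of the cytosine on its own
#' strand: CG if the next base is G; CHG if the next base is H (A, C or
#' T) and the one after is G; CHH otherwise. Ambiguity codes are
#' rejected.
#'
#' @param base_plus1,base_plus2 single bases in `A`, `C`, `G`, `T`
#'   (vectorised).
#' @return character vector of `"CG"`, `"CHG"` or `"CHH"`.
#' @examples
#' classifyContext("G", "A")  # CG
#' classifyContext("A", "G")  # CHG
#' classifyContext("T", "T")  # CHH
#' @export
classifyContext <- function(base_plus1, base_plus2) {
    b1 <- toupper(as.character(base_plus1))
    b2 <- toupper(as.character(base_plus2))
    ok <- c("A", "C", "G", "T")
    if (!all(b1 %in% ok) || !all(b2 %in% ok))
        stop("bases must be one of A, C, G, T (ambiguity codes rejected)")
    ifelse(b1 == "G", "CG", ifelse(b2 == "G", "CHG", "CHH"))
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3 input expects gene/mRNA/exon features; a gene with several
#' transcripts is represented by its longest one (by transcript span).
#' BED12 input is converted from 0-based half-open to the internal
#' 1-based inclusive convention; blocks become exons.
#'
#' @param path annotation file.
#' @param format `"gff3"` or `"bed12"`.
#' @return a [GeneModels-class].
#' @export
readGeneAnnotation <- function(path, format = c("gff3", "bed12")) {
    format <- match.arg(format)
    if (format == "gff3") .readGff3Genes(path) else .readBed12Genes(path)
}

.readGff3Genes <- function(path) {
    gr <- rtracklayer::import(path, format = "gff3")
    type <- as.character(gr$type)
    tx <- gr[type %in% c("mRNA", "transcript")]
    ex <- gr[type == "exon"]
    if (!length(tx)) stop(sprintf("no mRNA/transcript features in '%s'", path))
    parent_of <- function(x) vapply(x$Parent, function(p)
        if (length(p)) as.character(p[1]) else NA_character_, character(1))
    tx_parent <- parent_of(tx)
    tx_id <- as.character(tx$ID)
    ex_parent <- parent_of(ex)
    genes <- GenomicRanges::GRanges()
    exon_list <- list()
    ids <- character()
    for (g in unique(tx_parent)) {
        cand <- which(tx_parent == g)
        # longest transcript represents the gene
        pick <- cand[which.max(GenomicRanges::width(tx)[cand])]
        t_id <- tx_id[pick]
        t_ex <- ex[ex_parent == t_id]
        if (!length(t_ex))
            stop(sprintf("transcript '%s' has no exons in '%s'", t_id, path))
        span <- tx[pick]
        if (any(GenomicRanges::start(t_ex) < GenomicRanges::start(span)) ||
            any(GenomicRanges::end(t_ex) > GenomicRanges::end(span)))
            stop(sprintf("exon outside transcript bounds for '%s' in '%s'",
                         t_id, path))
        t_ex <- GenomicRanges::sort(t_ex, ignore.strand = TRUE)
        mcols(span) <- NULL
        mcols(t_ex) <- NULL
        gid <- sub("^gene:", "", g)
        genes <- c(genes, span)
        exon_list[[length(exon_list) + 1L]] <- t_ex
        ids <- c(ids, gid)
    }
    names(genes) <- ids
    geneModels(genes, GenomicRanges::GRangesList(exon_list))
}

.readBed12Genes <- function(path) {
    gr <- rtracklayer::import(path, format = "bed")
    if (is.null(gr$blocks))
        stop(sprintf("'%s' is not BED12 (no block definitions)", path))
    ids <- if (!is.null(gr$name)) as.character(gr$name)
           else sprintf("gene%04d", seq_along(gr))
    exon_list <- vector("list", length(gr))
    for (i in seq_along(gr)) {
        bl <- gr$blocks[[i]]  # block ranges relative to chromStart, already 1-based
        exon_list[[i]] <- GenomicRanges::GRanges(
            seqnames = GenomicRanges::seqnames(gr)[i],
            ranges = IRanges::shift(bl, GenomicRanges::start(gr)[i] - 1L),
            strand = GenomicRanges::strand(gr)[i])
    }
    genes <- GenomicRanges::granges(gr)
    names(genes) <- ids
    geneModels(genes, GenomicRanges::GRangesList(exon_list))
}

#' Write DMRs as BED6+5
#'
#' Standard BED columns (0-based half-open; name = context; score =
#' `round(-10 * log10(p))` capped at 1000; strand `.`) followed by
#' level_reference, level_treatment, fold_change, p_value and direction.
#'
#' @param dmrs a [GenomicRanges::GRanges] of DMRs as returned by
#'   [callDmrs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDmrBed <- function(dmrs, path) {
    mc <- mcols(dmrs)
    score <- ifelse(mc$p_value <= 0, 1000,
                    pmin(1000, round(-10 * log10(mc$p_value))))
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.\t%.6g\t%.6g\t%.6g\t%.6g\t%s",
                     as.character(GenomicRanges::seqnames(dmrs)),
                     GenomicRanges::start(dmrs) - 1L,
                     GenomicRanges::end(dmrs),
                     mc$context, as.integer(score),
                     mc$level_ref, mc$level_trt, mc$fold_change,
                     mc$p_value, mc$direction)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con)
    invisible(path)
}

#' Read a gene-to-term annotation table
#'
#' Two-column TSV (gene_id, term_id), optionally a third column with the
#' term name.
#'
#' @param path TSV path (no header).
#' @return data.frame with columns `gene_id`, `term_id` and, when
#'   present, `term_name`.
#' @export
readTermAnnotation <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "")
    if (ncol(df) < 2L)
        stop(sprintf("'%s' must have at least two tab-separated columns", path))
    names(df)[1:2] <- c("gene_id", "term_id")
    if (ncol(df) >= 3L) names(df)[3] <- "term_name"
    df[seq_len(min(3L, ncol(df)))]
}

#' Write the DMG table as TSV
#'
#' Columns: gene_id, region_class, context, direction, n_dmrs, best_p,
#' total_overlap_bp.
#'
#' @param dmgs data.frame from [assignDmgs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDmgTable <- function(dmgs, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    utils::write.table(dmgs, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
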