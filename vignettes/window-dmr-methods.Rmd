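---
title: "Window-based WGBS differential methylation: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based WGBS differential methylation: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylWindows)
```

# The data and the model

A whole-genome bisulfite experiment reduces, after alignment and
methylation extraction, to a per-cytosine count table: for every
cytosine site (chromosome, 1-based position, strand) the number of
reads reporting methylation (`Nm`) and non-methylation (`Nnm`), plus
the sequence context CG, CHG or CHH (H = A, C or T). The methylation
level of a site, or of any pooled set of sites, is `Nm / (Nm + Nnm)`.
The two cytosines of a CpG dyad are independent sites here; no
destranding is performed, so "all cytosines" accounting stays exact.
Zero-coverage sites are parsed and kept — their positions matter for
window construction bookkeeping — but excluded from every statistic,
because a level is undefined at zero depth.

`methylWindows` consumes this table (the Bismark CX-report family
dialect, the de-facto standard), compares two groups of replicated
samples, and carries the comparison through region calling, gene
annotation, term enrichment and qPCR validation. All central objects
are Bioconductor-native: a `MethylomeSample` is a `GRanges` of width-1
sites, DMRs come back as a `GRanges`, genes as `GRanges`/`GRangesList`
pairs.

# DMR calling

Per context, sites with pooled depth of at least `minDepth` reads in
*both* groups (default 4, a common WGBS floor) are taken in coordinate
order within each chromosome and tiled into consecutive,
non-overlapping windows of `windowSites` sites (default 5); a trailing
remainder is discarded. A window is a DMR when

* its pooled levels differ at least twofold, and
* the two-sided Fisher exact test on the 2×2 table
  (methylated/unmethylated × reference/treatment) of pooled counts
  gives p ≤ 0.05,

both thresholds inclusive. Two design points deserve explanation
because the underlying procedure leaves them open:

* **Disjoint, not sliding, windows.** Non-overlapping blocks avoid
  dependent overlapping tests and make "neighboring DMRs" well
  defined, which the merge rule needs. Sliding windows would multiply
  the number of tests roughly five-fold while testing nearly identical
  counts.
* **Replicates are pooled within group before testing.** One Fisher
  test per window needs one 2×2 table; with three animals per group
  the only table that uses all reads is the pooled one. The cost is
  that between-animal variance is not modeled — see Limitations.

The **fold change** is computed on pseudocounted levels,
`(Nm + 0.5) / (Nm + Nnm + 1)` (Jeffreys), as `max(r, 1/r)` of their
ratio. This keeps fully unmethylated windows (level 0) comparable
without dividing by zero, while leaving well-covered windows nearly
untouched; at a typical pooled window depth of ~300 reads the
pseudocount shifts a level by under 0.002. Reported `level_ref` /
`level_trt` are the raw pooled levels. `direction` is `hyper` when the
treatment level exceeds the reference level.

The **Fisher p** is computed by exhaustive enumeration of the
hypergeometric support in log space (`lchoose`), summing all tables
with the observed margins whose probability is at most that of the
observed table, with a relative tolerance of 1e-7 on the comparison —
the same convention `stats::fisher.test` uses, which serves as an
independent cross-check in the tests (agreement to < 1e-9 over every
table with total ≤ 40).

The **merge rule**: neighboring DMRs on the same chromosome, in the
same context and with the same direction are joined when the pooled
level of the whole span — from the upstream DMR's start to the
downstream DMR's end, re-pooled over *all* eligible sites of that
context in the span, not just the two DMRs' sites — still differs
twofold between groups. The span reading is deliberate: "the
methylation level of the region" is a property of the region, and it
makes the rule conservative (an intervening neutral stretch dilutes
the span and blocks the merge). The scan is greedy left-to-right and
repeats until a fixpoint; the tests verify idempotence on random
inputs. Merging is gated on the fold criterion only, exactly as the
rule is stated; the span's Fisher p is recomputed for reporting.
`maxMergeGap` defaults to unlimited (the rule states no distance
limit) but can be bounded. Opposite-direction neighbors never merge —
a "twofold difference" of a span mixing directions is not meaningful.

Raw p ≤ 0.05 is the default gate, as published; `dmrParams(fdr =
TRUE)` switches the window gate to Benjamini–Hochberg-adjusted
p-values for users who want multiplicity control. The practical
difference shows in near-zero-level contexts: at CHG/CHH baselines of
~1%, five-site windows reach twofold "changes" by sampling noise
alone, and the raw-p rule emits a scatter of such calls (visible in
any full-context run of the simulator). That is a property of the
published rule, not of this implementation.

# Genome-wide and metagene summaries

"Percent methylated" has two defensible readings, so `globalSummary()`
reports both per context: the **pooled weighted level**
(ΣNm / Σ(Nm+Nnm) over covered sites) and the **called-site fraction**,
where a site counts as methylated when a one-sided binomial test of
`Nm` successes in `Nm+Nnm` trials against the error rate gives
p < 0.05. The default error rate 0.005 is the complement of a ~99.5%
bisulfite conversion rate. In a CG context methylated near 80%, the
weighted level lands near 0.8 while the called fraction approaches 1 —
the two statistics bracket the two readings rather than guessing one.

`regionProfile()` partitions each gene, strand-aware, into seven
regions: upstream flank, first exon, first intron, internal exons,
internal introns, last exon, downstream flank, with "first"/"last" in
transcription order (the first exon of a minus-strand gene is the
rightmost). Each region is divided into `bins_per_region` (default 20)
equal-length bins by relative position 5'→3' — multi-interval regions
are concatenated in transcription order first — and a gene's covered
sites in a bin pool into one weighted level, then bins average over
genes. Genes lacking a region (single-exon genes have no introns)
contribute nothing to it; a region with no contributing gene is `NA`,
never 0. Flanks default to 2 kb. Multi-transcript genes are
represented by their longest transcript: the partition needs a single
model per gene.

# DMG annotation and enrichment

The promoter is the `promoter_bp` (default 2000, the common WGBS
convention) bases ending at the TSS, strand-aware and clipped at
position 1; the gene body is TSS..TES including introns. A DMR
overlapping a region by ≥ 1 bp contributes to that (gene, region
class); one straddling the TSS contributes to both promoter and body.
Direction per (gene, region class, context) is decided by summed
overlap length, with an explicit `ambiguous` state on exact ties
rather than a silent tie-break. The count table keeps contexts
separate and also attaches a context-deduplicated total, since a gene
can be hit in several contexts.

Enrichment is the upper-tail hypergeometric probability
P(X ≥ m) for m of n selected genes falling in a term annotating M of N
universe genes, computed as a direct log-gamma sum over the tail
(summing the tail directly avoids the cancellation a
`1 - cumulative` form would suffer at small p). The universe is the
set of genes with at least one annotation — unannotated genes can
never be drawn, so they belong in neither N nor n — and the correction
multiplier counts only terms with M ≥ 1 in that universe. Bonferroni
is the default, matching the published criterion "corrected p ≤ 0.05";
BH is available. Results order by raw p with term-id tie-break, so
runs are byte-reproducible. The selected set is gene-level (the DMG
gene list): the only internally consistent reading when the formula's
slots all count genes. The rich factor m/M is emitted as a column.

# qPCR

`ddctFoldChange()` implements the Livak comparative-Ct method with the
negative exponent, fold = 2^(−ΔΔCt): expression doubles per cycle
*saved*, so higher expression must map to lower Ct. Technical
replicates are averaged at the Ct level before ΔCt; ΔΔCt anchors at
the reference-group mean ΔCt, which makes the reference group's fold
from its group-mean ΔCt exactly 1 and the whole computation invariant
under a global Ct shift. Group summaries report mean ± SE of
per-sample folds.

# The simulator: what it emulates and what it does not

`simulationConfig()` defaults encode a replicated vertebrate-liver
WGBS design: CG sites methylated near 80% and CHG/CHH near 1% (the
animal pattern, where non-CG methylation is largely absent), a
methylation dip around TSSs (level halved within 200 bp), three
replicates per group, read depth Poisson with mean 20, and a
symmetric 0.005 conversion/sequencing error folded into the binomial
success probability, `p = level·(1−e) + (1−level)·e` — the minimal
error model under which Fisher testing of counts is well specified.
Planted differential regions default to ten 10-site CG regions at 0.8
(reference) vs 0.2 (treatment) placed inside gene bodies, scattered
across the genome. Site placement is uniform per context at 8/2/4
sites per kbp (CG/CHG/CHH); CpG-island clustering is irrelevant to the
statistics under test and is not modeled. The default genome (2
chromosomes × 1 Mbp, 50 genes) keeps a full pipeline run around ten
seconds; the test suite uses this scale or smaller throughout, and the
acceptance script uses ~2,000 windows for null calibration.

One seed fixes every draw: identical configs produce byte-identical
files, which the pipeline's manifest-and-rerun test exploits.

What passing tests on this generator do **not** show about real data:
there is no between-replicate biological variance beyond binomial
sampling (no overdispersion), no coverage biases, no
context-dependent conversion failure, no CpG islands, and genome
scale is three orders of magnitude down. Recovery and calibration
results are statements about the procedure's correctness, not about
its operating characteristics on an animal genome.

# Numerical and degenerate-input choices

* Fisher test: zero row/column margins return p = 1 (no evidence),
  not an error; the ≤ comparison on table probabilities carries a
  1e-7 relative tolerance.
* Hypergeometric tail: m = 0 returns exactly 1; m at the lower
  support bound returns exactly 1.
* Levels: zero-coverage sites error in `siteLevel` and are excluded
  from summaries; a context with no covered site is reported missing
  (`NA`), never 0.
* Coordinates: 1-based inclusive internally (the cytosine-report
  convention); BED output is 0-based half-open with score
  `round(−10·log10 p)` capped at 1000; BED12 input converts on read.
* Ties: p = α and fold = minFold are inclusive; enrichment ties order
  by term id; direction ties in DMG assignment are `ambiguous`.

# Known limitations

Pooling replicates ignores between-animal dispersion, so p-values are
anti-conservative relative to beta-binomial callers; the raw-p gate
performs no multiplicity control (BH is optional); smoothing-based
callers, paired designs, amplification-efficiency-corrected qPCR and
GO-DAG-aware enrichment are out of scope. Intergenic DMRs are
reported unassigned rather than attached to a nearest gene.
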