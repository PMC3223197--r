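---
title: "Methods: comparing histone-methylation landscapes between two cell lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing histone-methylation landscapes between two cell lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histmarkr)
```

## The analysis

histmarkr implements the standard comparative analysis of two histone marks
(H3K4me3, a proximal-promoter signature of active genes, and H3K4me1, an
enhancer signature at promoter-distal sites) profiled by ChIP-seq in two
related cell populations — the motivating setting is regulatory versus
activated conventional CD4+ T cells. The analysis answers four questions:

1. **Where do enrichment islands fall?** The genome is divided into four
   classes — proximal promoters (±1 kb of each transcription start site),
   exons, introns and intergenic sequence — and each island is assigned one
   class.
2. **How alike are the two lineages?** Islands are *common* when they
   overlap an island of the other lineage by at least 1 bp, and
   *lineage-specific* when they overlap none.
3. **How does enrichment co-vary?** For every marked proximal promoter, the
   per-lineage enrichment ratio (peak tag count over promoter length,
   tags/bp) is computed, and the two lineages' ratios are correlated
   (Pearson by default).
4. **What is the aggregate profile around genes?** A metagene tag-density
   curve over the upstream 5 kb, the length-scaled gene body and the
   downstream 5 kb, 40 windows per region, normalised as
   *density = reads in window / (total reads × window length)*.

All coordinates are 0-based half-open (BED convention) internally;
1-based inclusive region strings are converted exactly once at the parse
boundary (`parse_region()`).

## Genome partition

Promoters are `[TSS − h, TSS + h)` with `h = 1000` bp by default,
configurable. The TSS is strand-aware: `tx_start` for `+` transcripts and
`tx_end − 1` for `−` transcripts. Annotation tables name only "txStart",
which is strand-ignorant for minus-strand genes; because the biological
promoter sits at the 5' end, strand-aware is the default and a
`tss_mode = "literal"` switch reproduces the strand-ignorant reading.
Promoter windows of overlapping transcripts are merged into single promoter
units that retain every contributing transcript and gene symbol — one
proximal promoter is commonly associated with more than one gene.

The four classes overlap at the base level (a promoter window usually covers
the first exon), so classification of a query interval uses a fixed
precedence: **promoter > exon > intron > intergenic**, with ≥ 1 bp overlap —
the same overlap semantics used for peak comparison. No published rule
exists for multi-class islands; precedence toward the more informative,
rarer class is the default, and `mode = "max_overlap"` (majority base count,
ties broken by the same precedence) is available for sensitivity analysis.
Every base belongs to at least one class, which the test suite verifies
against an exhaustive per-base scan on a toy genome.

## Peak calling

The built-in caller is a deliberately simple local-Poisson sliding-window
detector so the pipeline is self-contained on tag BED files; externally
called peaks can be supplied instead (`skip_calling` in the pipeline
configuration). It is not a re-implementation of any published caller: there
is no fragment-shift model, no control library, no broad/narrow distinction
and no multiple-testing correction (a raw p-value threshold).

Tags are extended from their 5' end to a nominal fragment length (200 bp;
sonicated chromatin fragments are a few hundred bp) and the fragment
midpoints are counted in 200 bp windows stepped every 50 bp from position 0
of each chromosome. A window is significant when its count `k` satisfies
`P(X ≥ k) < 10⁻⁵` for `X ~ Poisson(λ_max)`, computed in log space
(`poisson_tail()`), where `λ_max` is the maximum of

* the chromosome-wide rate, `(tags on chromosome) × window / chromosome length`, and
* local rates over 5 kb and 10 kb spans centred on the window.

Two numerical choices deserve explanation:

* **The background is per chromosome, not genome-wide.** This makes peak
  calling exactly decomposable: calling on a merged library equals calling
  per chromosome and concatenating, and chromosomes with different coverage
  get appropriate baselines.
* **The smallest local span is 5 kb, not 1 kb.** A local span that fits
  inside an enrichment island estimates the enrichment itself, not its
  background: with ~1 kb islands, a 1 kb span centred on an in-island window
  raises λ to the island's own rate and suppresses every true peak (recall
  collapsed to 0.05 in simulation). Callers that operate without a control
  library omit the 1 kb span for exactly this reason; both spans remain
  configurable through `peak_caller_params()`.

Significant windows closer than 200 bp are merged; merged islands shorter
than 200 bp or containing fewer than 10 tags are discarded. Note that the
number of *islands* is not strictly monotone in the p-value threshold — a
newly significant window can bridge two islands into one — but the total
base-pair coverage of islands is, and the island count is antitone in
`min_length`; the test suite asserts these, the true invariants of a
merge-based caller.

## Peak comparison and enrichment correlation

Overlap is ≥ 1 bp under half-open semantics (`A.end > B.start` and
`B.end > A.start`); adjacent islands share no base and are specific.
Counting is **per side**: an island is common if it has ≥ 1 partner, so one
A-island spanning two B-islands yields one common-A and two common-B — the
only convention under which the two sides of a cross-mark comparison can
legitimately report different common counts. The implementation (interval
trees via GenomicRanges) is tested against an O(n²) all-pairs oracle on a
thousand random instances including 1 bp-overlap and adjacency boundaries.

A promoter is *marked* when ≥ 1 island of the mark overlaps it; no minimum
tag count is imposed. The promoter enrichment ratio in lineage X is the
number of X-library tags falling in the promoter-overlapping island(s)
divided by the promoter length (tags/bp); when several islands overlap one
promoter their tag counts are summed by default (`multi_peak = "max"`
selects the strongest island instead). Ratios are raw by default; `cpm`
rescales counts to per-million before the ratio, and the correlation can be
computed on raw ratios (Pearson, the default, matching a raw-ratio scatter),
ranks (Spearman) or log2 ratios over promoters positive in both lineages.
Gene-level Venn partitions compare the union of gene symbols over each
lineage's marked promoters; a gene counts once however many transcripts or
promoters carry it.

## Metagene profile

Flanks are cut into fixed 125 bp windows (5 kb / 40); the body of each gene
is cut into 40 equal windows with boundaries at `round(i·L/40)`, which tiles
any `L ≥ 40` bp without gaps or overlaps; genes shorter than 40 bp are
skipped with a warning. Profiles are oriented 5'→3' (minus-strand genes are
flipped; `orient = "literal"` disables this). A tag counts in every window
it overlaps, consistent with interval semantics elsewhere; a
single-assignment mode (`assign = "five_prime"`) counts each tag once at its
5' end. Counts are pooled over genes *before* normalising — the density is
one ratio, pooled reads over (library total × pooled window length) — which
matches the single-ratio definition above; per-gene averaging is available
behind `average = "per_gene"`. Pooling means overlapping genes count shared
tags toward each gene they overlap.

## The synthetic-data generator

The generator produces the study conditions under which the package is
validated end to end; it emulates the statistical structure the analysis
assumes, not raw sequencing reality. Defaults, chosen once:

| parameter | default | why |
|---|---|---|
| genome | 2 chromosomes, 20 Mb | large enough for ~10⁵-window calling, small enough for minutes-scale runs |
| `n_genes` | 200 | enough promoters for stable class and Venn statistics |
| `n_peaks` | 300 per mark | ~1.5 islands per gene, Fig-scale class counts |
| `peak_length` | 1 kb | typical H3K4 island size |
| `enrichment_fold` | 20 | strongly detectable but not degenerate |
| `library_size` | 200 000 | ≈150 tags per planted island (≥ 50 everywhere) |
| `fragment_length` | 200 bp | sonicated-fragment scale |
| H3K4me3 mixture | 0.45/0.12/0.25/0.18 (prom/exon/intron/inter) | promoter-heavy, as observed for this mark |
| H3K4me1 mixture | 0.05/0.08/0.55/0.32 | intron/distal-heavy enhancer signature |
| `share_fraction` | 0.7 (me3) / 0.2 (me1) | promoter landscapes are largely shared between related lineages; enhancer landscapes are largely lineage-specific |

Peak placement is rejection-sampled so the planted interval — padded by one
fragment length, since called islands extend about that far beyond the
enrichment — classifies to its drawn class under precedence, and planted
peaks of one mark keep ≥ 2 kb mutual spacing so called islands never merge
across loci. Each peak is common to both cell types with probability
`share_fraction`, else assigned to one cell type uniformly. Tags are
`fragment_length` intervals whose starts are drawn uniformly outside the
planted peaks (background) and uniformly inside them at `enrichment_fold`
times the background rate, so the fold is the exact in/out rate contrast.
All randomness flows from one integer seed; identical seeds give identical
libraries byte for byte.

What the generator does **not** model: mappability and GC bias, duplicate
reads, fragment-size variation, chromatin-state autocorrelation, and
variation of enrichment strength across loci (every planted peak has the
same expected density). Passing end-to-end tests therefore demonstrates
that the pipeline's logic is correct under its own assumptions — not that
real libraries at real depths would yield the published island counts.

The constant enrichment fold has one visible consequence: in the synthetic
promoter enrichment table, common promoters cluster around a single
(ratio_A, ratio_B) point while lineage-specific promoters sit on the axes,
so the cross-lineage correlation is near zero or negative regardless of the
share fraction. The strongly positive correlations seen in real promoter
landscapes arise from locus-to-locus variation in enrichment strength that
is shared between lineages — a feature the generator deliberately omits to
keep planted truth exact. The correlation machinery itself is validated
separately on records with a planted correlation coefficient.

When validating parameter recovery, the recovered class percentages are
compared to the *realised* class distribution of the planted peaks rather
than the mixture parameter: a finite draw of 300 peaks differs from its
parameter by multinomial noise (~3 points per class), which is the
generator's sampling variation, not pipeline error. The share fraction is
estimated as `C / (n_A + n_B − C)` with `C` the mean of the two per-side
common counts, which equals the planted share exactly under clean one-to-one
island matching.

## Problem sizes used in validation

The shipped test-and-acceptance runs use: 1 000 random instances (≤ 50
peaks per side) for the overlap oracle; a 100 kb, 10-gene toy genome for
the per-base partition scan; a 8 Mb, 150-peak study for caller
recall/precision; and the full default study (20 Mb, 200 genes, four
200 000-tag libraries) for end-to-end share and class-mixture recovery.
These sizes keep a complete run in the minutes range on a single CPU while
leaving every statistical check well-powered.

## Known limitations

* The caller requires tags, not BAM alignments; upstream alignment and
  filtering are out of scope (use any aligner plus `bedtools bamtobed`).
* Duplicate tags are kept; collapse them upstream if desired.
* Chromosome names are matched exactly ("chr1" ≠ "1").
* Enrichment correlation on promoters marked in only one lineage produces
  zero-inflated axes; with very few marked promoters the correlation is
  reported as `NA` rather than a misleading number.
* Flank windows of genes within 5 kb of a chromosome start are clipped, and
  their reduced width enters the normalisation denominator.
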