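# histmarkr

Comparative ChIP-seq analysis of histone methylation marks between two cell
lineages, in tidy R.

Active regulatory chromatin carries characteristic histone H3 lysine-4
methylation: **H3K4me3** concentrates at the proximal promoters of active
genes, while **H3K4me1** away from promoters marks enhancers. Comparing the
genome-wide landscapes of these two marks between two related cell
populations — the motivating case is CD4+CD25+FOXP3+ regulatory T cells
(Treg) versus activated conventional T cells (aTconv) — shows which parts
of the regulatory landscape are shared and which are lineage-specific.
histmarkr packages that whole comparison:

* **Genome partition** into proximal promoters (±1 kb of each TSS), exons,
  introns and intergenic sequence, with precedence-based classification of
  any interval and per-class distribution reports.
* **Peak calling**: a simplified local-Poisson sliding-window caller —
  windows are tested against `P(X ≥ k)` for `X ~ Poisson(λ_max)`,
  `λ_max = max(chromosome-wide rate, 5 kb / 10 kb local rates)` — so the
  pipeline runs end-to-end from tag BED files; externally called peaks can
  be supplied instead.
* **Peak comparison**: common vs lineage-specific islands by ≥ 1 bp overlap
  (half-open coordinates), counted per side.
* **Promoter and gene association**: per-promoter enrichment ratios
  (peak tags / promoter length, tags/bp) in each lineage, their Pearson (or
  Spearman / log2) correlation, and gene-level Venn partitions.
* **Metagene profiles**: tag density over upstream 5 kb, length-scaled gene
  body and downstream 5 kb, 40 windows per region, with
  `density = reads in window / (total reads × window length)`.
* **Synthetic data**: a seeded generator that builds toy genomes, plants
  common and lineage-specific peak architectures with mark-specific genomic
  class mixtures, and draws tag libraries — with ground truth attached, so
  every stage is validated end to end.

Every user-facing function takes a data frame and returns a tibble; results
have `tidy()` / `glance()` methods and `autoplot()` / `plot_*()` views.

## Worked example

Simulate a two-lineage H3K4me3 study, call peaks, and compare:

```r
library(histmarkr)

params <- sim_params(
  n_genes = 40, chrom_lengths = tibble::tibble(chrom = "chr1", length = 4e6),
  n_peaks = 40, library_size = 40000, seed = 7
)
study <- simulate_study(params)

peaks <- lapply(params$cell_types, function(cell)
  call_peaks(study$tags$H3K4me3[[cell]], study$sizes))

compare_peak_sets(peaks[[1]], peaks[[2]], labels = params$cell_types)
#> <peak_comparison> Treg vs aTconv
#>   Treg: 38 peaks (31 common, 7 specific)
#>   aTconv: 33 peaks (31 common, 2 specific)
#>   overlapping pairs: 31

distribution_report(study$partition, peaks[[1]])
#> # A tibble: 4 × 3
#>   region_class          n percent
#>   <fct>             <int>   <dbl>
#> 1 proximal_promoter    17    44.7
#> 2 exon                  6    15.8
#> 3 intron               10    26.3
#> 4 intergenic            5    13.2

metagene_profile(study$genes, study$tags$H3K4me3$Treg)
#> <metagene_profile> 40 genes, 40000 reads, 40 bins/region
#>   max density 2.96e-06 at upstream bin 36

gene_venn(marked_promoters(study$partition, peaks[[1]]),
          marked_promoters(study$partition, peaks[[2]]),
          labels = params$cell_types)
#> <gene_venn> Treg vs aTconv
#>   common: 12  Treg-specific: 5  aTconv-specific: 1
```

Reading the numbers: of 38 Treg and 33 aTconv islands, 31 on each side
overlap the other lineage by at least 1 bp (the generator planted a 70%
share); 44.7% of Treg islands sit in proximal promoters, matching the
promoter-heavy placement used for an H3K4me3-like mark; the metagene
maximum falls in the upstream windows adjacent to the TSS; and most marked
genes are shared between the lineages.

The same analysis runs end-to-end from a config:

```r
run_pipeline(pipeline_config(out_dir = "histmark_out", seed = 1))
```

which writes, per mark and cell type: peak BED/TSV, genomic-distribution
TSV, metagene TSV, common/specific BEDs with a JSON comparison summary,
promoter-enrichment TSV with cross-lineage correlations, gene-Venn JSON,
cross-mark comparison JSON, and a manifest. A thin CLI wraps the same
stages (`inst/scripts/histmark simulate|call|classify|compare|profile|venn|run`).

On real data, point the config at your own refFlat/BED12 annotation,
chrom.sizes and tag BED files (`simulate = FALSE`), or pass MACS peaks with
`skip_calling = TRUE`.

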