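# Common vs lineage-specific peak classification, promoter-level enrichment
# ratios, gene-level Venn partitions, and cross-lineage / cross-mark
# correlation of enrichment.

#' Compare two peak sets by 1-bp overlap
#'
#' A peak is *common* if it overlaps at least one peak of the other set by a
#' minimal distance of 1 bp (half-open semantics: `A.end > B.start` and
#' `B.end > A.start`), and *specific* otherwise. Counting is per side: one
#' peak of A overlapping two peaks of B contributes one common-A peak and two
#' common-B peaks, which is why the two sides of a comparison can report
#' different common counts.
#'
#' @param peaks_a,peaks_b Peak tibbles (`chrom`, `start`, `end`, ...).
#' @param labels Length-2 character vector naming the two sides.
#' @return A `peak_comparison` object: `common_pairs` (row indices and
#'   coordinates of every overlapping pair), per-side peak tibbles with a
#'   `status` column, and a `counts` list. Use [tidy()] / [glance()] to get
#'   tibble views and [common_peaks()] / [specific_peaks()] to extract sets.
#' @export
compare_peak_sets <- function(peaks_a, peaks_b, labels = c("A", "B")) {
  peaks_a <- validate_intervals(peaks_a, "peaks_a")
  peaks_b <- validate_intervals(peaks_b, "peaks_b")
  if (nrow(peaks_a) > 0 && nrow(peaks_b) > 0) {
    hits <- find_overlaps_iv(peaks_a, peaks_b)
    ia <- S4Vectors::queryHits(hits)
    ib <- S4Vectors::subjectHits(hits)
  } else {
    ia <- ib <- integer()
  }
  pairs <- tibble(
    index_a = ia, index_b = ib,
    chrom = peaks_a$chrom[ia],
    start_a = peaks_a$start[ia], end_a = peaks_a$end[ia],
    start_b = peaks_b$start[ib], end_b = peaks_b$end[ib]
  ) |> arrange(.data$chrom, .data$start_a, .data$start_b)
  peaks_a$status <- ifelse(seq_len(nrow(peaks_a)) %in% ia, "common", "specific")
  peaks_b$status <- ifelse(seq_len(nrow(peaks_b)) %in% ib, "common", "specific")
  counts <- list(
    n_a = nrow(peaks_a), n_b = nrow(peaks_b),
    n_common_a = sum(peaks_a$status == "common"),
    n_common_b = sum(peaks_b$status == "common"),
    n_specific_a = sum(peaks_a$status == "specific"),
    n_specific_b = sum(peaks_b$status == "specific"),
    n_pairs = nrow(pairs)
  )
  structure(
    list(common_pairs = pairs, peaks_a = peaks_a, peaks_b = peaks_b,
         counts = counts, labels = labels),
    class = "peak_comparison"
  )
}

#' Cross-mark overlap within one sample
#'
#' Same contract as [compare_peak_sets()], applied to two marks of the same
#' cell type (e.g. H3K4me1 vs H3K4me3 in one lineage). Per-side counting
#' means the two marks can report different numbers of overlapping regions.
#'
#' @param peaks_me1,peaks_me3 Peak tibbles for the two marks.
#' @inheritParams compare_peak_sets
#' @export
cross_mark_comparison <- function(peaks_me1, peaks_me3,
                                  labels = c("H3K4me1", "H3K4me3")) {
  compare_peak_sets(peaks_me1, peaks_me3, labels = labels)
}

#' @export
print.peak_comparison <- function(x, ...) {
  cat(sprintf("<peak_comparison> %s vs %s\n", x$labels[1], x$labels[2]))
  cat(sprintf("  %s: %d peaks (%d common, %d specific)\n", x$labels[1],
              x$counts$n_a, x$counts$n_common_a, x$counts$n_specific_a))
  cat(sprintf("  %s: %d peaks (%d common, %d specific)\n", x$labels[2],
              x$counts$n_b, x$counts$n_common_b, x$counts$n_specific_b))
  cat(sprintf("  overlapping pairs: %d\n", x$counts$n_pairs))
  invisible(x)
}

#' @rdname compare_peak_sets
#' @param x A `peak_comparison`.
#' @param side `"a"` or `"b"`.
#' @export
common_peaks <- function(x, side = c("a", "b")) {
  side <- match.arg(side)
  p <- if (side == "a") x$peaks_a else x$peaks_b
  p[p$status == "common", , drop = FALSE]
}

#' @rdname compare_peak_sets
#' @export
specific_peaks <- function(x, side = c("a", "b")) {
  side <- match.arg(side)
  p <- if (side == "a") x$peaks_a else x$peaks_b
  p[p$status == "specific", , drop = FALSE]
}

#' @export
tidy.peak_comparison <- function(x, ...) {
  bind_rows(
    mutate(x$peaks_a, side = x$labels[1], .before = 1),
    mutate(x$peaks_b, side = x$labels[2], .before = 1)
  ) |>
    arrange(.data$side, .data$chrom, .data$start, .data$end) |>
    as_tibble()
}

#' @export
glance.peak_comparison <- function(x, ...) {
  as_tibble(x$counts) |>
    mutate(label_a = x$labels[1], label_b = x$labels[2])
}

#' Promoter enrichment table across two lineages
#'
#' For every proximal promoter overlapped by at least one peak in either
#' lineage, computes the per-lineage enrichment ratio: total tags of that
#' lineage's library falling in the promoter-overlapping peak(s), divided by
#' the promoter length in bp (tags/bp). A promoter whose lineage has no
#' overlapping peak gets ratio 0 for that lineage; promoters with no peak in
#' either lineage are excluded.
#'
#' @param partition A `genome_partition` (supplies the promoter registry).
#' @param peaks_a,peaks_b Peak tibbles per lineage.
#' @param tags_a,tags_b Tag tibbles per lineage.
#' @param multi_peak When several peaks overlap one promoter: `"sum"`
#'   (default) their tag counts or take the `"max"` single peak.
#' @param cpm Normalise tag counts to counts-per-million library tags before
#'   forming ratios.
#' @return A tibble of enrichment records: `unit_id`, `chrom`, `start`,
#'   `end`, `gene_symbols` (list), `n_peaks_a`, `n_peaks_b`, `ratio_a`,
#'   `ratio_b`.
#' @export
promoter_mark_table <- function(partition, peaks_a, peaks_b, tags_a, tags_b,
                                multi_peak = c("sum", "max"), cpm = FALSE) {
  multi_peak <- match.arg(multi_peak)
  reg <- partition$promoters
  if (nrow(reg) == 0) abort("partition has no promoters")
  side <- function(peaks, tags) {
    peaks <- validate_intervals(peaks, "peaks")
    n_tags <- nrow(tags)
    if (nrow(peaks) == 0) {
      return(list(n = integer(nrow(reg)), count = numeric(nrow(reg))))
    }
    per_peak <- count_overlaps_iv(peaks, tags)
    if (cpm) per_peak <- per_peak * 1e6 / n_tags
    hits <- find_overlaps_iv(reg, peaks)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    n <- integer(nrow(reg))
    cnt <- numeric(nrow(reg))
    if (length(qh) > 0) {
      tn <- table(factor(qh, levels = seq_len(nrow(reg))))
      n <- as.integer(tn)
      agg_fun <- if (multi_peak == "sum") sum else max
      agg <- tapply(per_peak[sh], qh, agg_fun)
      cnt[as.integer(names(agg))] <- agg
    }
    list(n = n, count = cnt)
  }
  a <- side(peaks_a, tags_a)
  b <- side(peaks_b, tags_b)
  keep <- a$n > 0 | b$n > 0
  out <- tibble(
    unit_id = reg$promoter_id[keep],
    chrom = reg$chrom[keep],
    start = reg$start[keep],
    end = reg$end[keep],
    gene_symbols = reg$gene_symbols[keep],
    n_peaks_a = a$n[keep],
    n_peaks_b = b$n[keep],
    ratio_a = a$count[keep] / (reg$end[keep] - reg$start[keep]),
    ratio_b = b$count[keep] / (reg$end[keep] - reg$start[keep])
  )
  sort_intervals(out)
}

#' Promoters marked by a peak set
#'
#' A promoter is *marked* when at least one peak overlaps it by >= 1 bp; no
#' minimum tag count is applied.
#'
#' @param partition A `genome_partition`.
#' @param peaks Peak tibble.
#' @return The promoter-registry rows (with gene symbols) of marked
#'   promoters.
#' @export
marked_promoters <- function(partition, peaks) {
  reg <- partition$promoters
  peaks <- validate_intervals(peaks, "peaks")
  if (nrow(reg) == 0 || nrow(peaks) == 0) return(reg[integer(), ])
  hit <- overlaps_any_iv(reg, peaks)
  reg[hit, , drop = FALSE]
}

#' Gene-level Venn partition of two marked-promoter sets
#'
#' Compares the genes associated with each lineage's marked promoters: a
#' gene is counted once regardless of how many transcripts or promoters
#' carry it, `common` is the intersection and the specific sets are the set
#' differences.
#'
#' @param marked_a,marked_b Marked-promoter tibbles from
#'   [marked_promoters()] (or plain character vectors of gene symbols).
#' @param labels Length-2 character vector naming the two sides.
#' @return A `gene_venn` object with `common`, `specific_a`, `specific_b`
#'   (sorted character vectors) and `counts`.
#' @export
gene_venn <- function(marked_a, marked_b, labels = c("A", "B")) {
  genes_of <- function(x) {
    if (is.character(x)) return(sort(unique(x)))
    if (is.data.frame(x) && "gene_symbols" %in% names(x)) {
      return(sort(unique(unlist(x$gene_symbols))))
    }
    abort("expected a marked-promoter tibble or a character vector of genes")
  }
  ga <- genes_of(marked_a)
  gb <- genes_of(marked_b)
  structure(
    list(
      common = intersect(ga, gb),
      specific_a = setdiff(ga, gb),
      specific_b = setdiff(gb, ga),
      counts = list(n_common = length(intersect(ga, gb)),
                    n_specific_a = length(setdiff(ga, gb)),
                    n_specific_b = length(setdiff(gb, ga))),
      labels = labels
    ),
    class = "gene_venn"
  )
}

#' @export
print.gene_venn <- function(x, ...) {
  cat(sprintf("<gene_venn> %s vs %s\n", x$labels[1], x$labels[2]))
  cat(sprintf("  common: %d  %s-specific: %d  %s-specific: %d\n",
              x$counts$n_common, x$labels[1], x$counts$n_specific_a,
              x$labels[2], x$counts$n_specific_b))
  invisible(x)
}

#' @export
tidy.gene_venn <- function(x, ...) {
  tibble(
    gene = c(x$common, x$specific_a, x$specific_b),
    set = rep(c("common", "specific_a", "specific_b"),
              c(length(x$common), length(x$specific_a), length(x$specific_b)))
  ) |> arrange(.data$set, .data$gene)
}

#' @export
glance.gene_venn <- function(x, ...) {
  as_tibble(x$counts) |> mutate(label_a = x$labels[1], label_b = x$labels[2])
}

#' Correlate enrichment ratios between two lineages
#'
#' Correlation of the paired per-unit enrichment ratios (`ratio_a`,
#' `ratio_b`) of an enrichment table, as plotted in cross-lineage scatter
#' comparisons. Pearson on the raw ratios is the default; Spearman and
#' log-scale Pearson (log2 of ratios, restricted to units with both ratios
#' positive) are available.
#'
#' @param records Enrichment tibble with `ratio_a` and `ratio_b` columns
#'   (see [promoter_mark_table()]).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param log2_transform Correlate `log2(ratio)` over units positive in both
#'   lineages.
#' @return A one-row tibble: `method`, `estimate`, `n`.
#' @export
enrichment_correlation <- function(records, method = c("pearson", "spearman"),
                                   log2_transform = FALSE) {
  method <- match.arg(method)
  if (!all(c("ratio_a", "ratio_b") %in% names(records))) {
    abort("records must have ratio_a and ratio_b columns")
  }
  x <- records$ratio_a
  y <- records$ratio_b
  if (log2_transform) {
    keep <- x > 0 & y > 0
    x <- log2(x[keep])
    y <- log2(y[keep])
  }
  if (length(x) < 3) abort("need >= 3 records to correlate")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("zero variance on one axis; correlation undefined")
  }
  est <- stats::cor(x, y, method = method)
  tibble(
    method = if (log2_transform) paste0("log2-", method) else method,
    estimate = est,
    n = length(x)
  )
}
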