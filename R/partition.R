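# Partition a genome into the four region classes used to summarise where
# histone-mark islands fall: proximal promoters (+/- 1 kb of the TSS by
# default), exons, introns and intergenic sequence. Classes may overlap on
# the base level (a promoter window typically covers the first exon); a
# fixed precedence resolves multi-class queries.

REGION_CLASSES <- c("proximal_promoter", "exon", "intron", "intergenic")

#' Build a four-class genome partition
#'
#' Divides the genome into proximal promoters, exons, introns and intergenic
#' sequence from a set of transcript models. Promoters are
#' `[TSS - halfwidth, TSS + halfwidth)` around each transcript's
#' strand-aware TSS (`tx_start` for `+` transcripts, `tx_end - 1` for `-`),
#' clipped to chromosome bounds; exons are the union of exon blocks; introns
#' are gene bodies minus exons; intergenic is the complement of promoters and
#' gene bodies. Overlapping intervals of the same class are merged.
#' Overlapping promoter windows are merged into a single promoter unit that
#' keeps every contributing transcript and gene symbol, mirroring the fact
#' that one proximal promoter is often associated with several genes.
#'
#' @param genes Gene model tibble from [read_gene_annotation()] or
#'   [generate_genome()].
#' @param sizes Chromosome sizes tibble (`chrom`, `length`).
#' @param promoter_halfwidth Half-width of the promoter window in bp
#'   (default 1000, i.e. a 2 kb window centred on the TSS).
#' @param tss_mode `"strand_aware"` (default: the biological 5' start) or
#'   `"literal"` (always `tx_start`, reproducing strand-ignorant use of
#'   annotation tables).
#' @return A `genome_partition` object: per-class interval tibbles, a
#'   promoter registry mapping each merged promoter to its transcripts and
#'   gene symbols, and the parameters used.
#' @export
build_partition <- function(genes, sizes, promoter_halfwidth = 1000,
                            tss_mode = c("strand_aware", "literal")) {
  tss_mode <- match.arg(tss_mode)
  if (promoter_halfwidth < 0) abort("promoter_halfwidth must be >= 0")
  sv <- sizes_vec(sizes)
  if (any(sv <= 0)) abort("chromosome lengths must be positive")
  if (nrow(genes) > 0) {
    bodies_raw <- tibble(chrom = genes$chrom, start = genes$tx_start, end = genes$tx_end)
    validate_intervals(bodies_raw, "gene bodies")
    unknown <- setdiff(unique(genes$chrom), names(sv))
    if (length(unknown) > 0) {
      abort(sprintf("gene(s) on unknown chromosome(s): %s", paste(unknown, collapse = ", ")))
    }
    over <- which(genes$tx_end > sv[genes$chrom] | genes$tx_start < 0)
    if (length(over) > 0) {
      abort(sprintf("transcript '%s' lies outside chromosome bounds", genes$tx_id[over[1]]))
    }
  }

  empty_iv <- tibble(chrom = character(), start = integer(), end = integer())

  if (nrow(genes) == 0) {
    promoters <- exons <- introns <- empty_iv
    registry <- tibble(promoter_id = character(), chrom = character(),
                       start = integer(), end = integer(),
                       tx_ids = list(), gene_symbols = list())
    bodies <- empty_iv
  } else {
    tss <- ifelse(genes$strand == "+" | tss_mode == "literal",
                  genes$tx_start, genes$tx_end - 1L)
    prom_raw <- tibble(
      chrom = genes$chrom,
      start = pmax(0L, as.integer(tss - promoter_halfwidth)),
      end = pmin(sv[genes$chrom], as.integer(tss + promoter_halfwidth))
    )
    keep <- prom_raw$end > prom_raw$start
    prom_raw <- prom_raw[keep, ]
    prom_genes <- genes[keep, ]
    if (nrow(prom_raw) > 0) {
      prom_gr <- iv_to_gr(prom_raw)
      merged_gr <- GenomicRanges::reduce(prom_gr)
      promoters <- sort_intervals(gr_to_iv(merged_gr))
      hits <- GenomicRanges::findOverlaps(iv_to_gr(promoters), prom_gr)
      tx_by_prom <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
      idx <- as.character(seq_len(nrow(promoters)))
      registry <- tibble(
        promoter_id = sprintf("%s:%d-%d", promoters$chrom, promoters$start, promoters$end),
        chrom = promoters$chrom,
        start = promoters$start,
        end = promoters$end,
        tx_ids = map(idx, function(i) sort(unique(prom_genes$tx_id[tx_by_prom[[i]]]))),
        gene_symbols = map(idx, function(i) {
          sort(unique(unlist(prom_genes$gene_symbols[tx_by_prom[[i]]])))
        })
      )
    } else {
      promoters <- empty_iv
      registry <- tibble(promoter_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         tx_ids = list(), gene_symbols = list())
    }
    exon_tbl <- tibble(
      chrom = rep(genes$chrom, lengths(genes$exon_starts)),
      start = as.integer(unlist(genes$exon_starts)),
      end = as.integer(unlist(genes$exon_ends))
    )
    exons <- sort_intervals(merge_intervals(exon_tbl))
    bodies <- merge_intervals(bodies_raw)
    introns <- if (nrow(exons) == 0) bodies else {
      sort_intervals(gr_to_iv(GenomicRanges::setdiff(iv_to_gr(bodies), iv_to_gr(exons))))
    }
  }

  genic <- merge_intervals(bind_rows(promoters, bodies))
  whole <- tibble(chrom = names(sv), start = 0L, end = as.integer(sv))
  intergenic <- if (nrow(genic) == 0) whole else {
    sort_intervals(gr_to_iv(GenomicRanges::setdiff(iv_to_gr(whole), iv_to_gr(genic))))
  }

  structure(
    list(
      classes = list(
        proximal_promoter = promoters,
        exon = exons,
        intron = introns,
        intergenic = intergenic
      ),
      promoters = registry,
      sizes = arrange(as_tibble(sizes), .data$chrom),
      params = list(promoter_halfwidth = promoter_halfwidth, tss_mode = tss_mode)
    ),
    class = "genome_partition"
  )
}

#' @export
print.genome_partition <- function(x, ...) {
  cat("<genome_partition>\n")
  cat(sprintf("  chromosomes: %d (%.1f Mb)\n", nrow(x$sizes), sum(x$sizes$length) / 1e6))
  cat(sprintf("  promoter halfwidth: %d bp (%s TSS)\n",
              x$params$promoter_halfwidth, x$params$tss_mode))
  for (cl in REGION_CLASSES) {
    cat(sprintf("  %-18s %6d intervals, %.2f Mb\n", cl,
                nrow(x$classes[[cl]]), interval_bp(x$classes[[cl]]) / 1e6))
  }
  invisible(x)
}

#' Classify intervals against a genome partition
#'
#' Assigns each query interval the highest-precedence region class it
#' overlaps by at least 1 bp, with precedence
#' `proximal_promoter > exon > intron > intergenic` (the same overlap
#' semantics used for peak comparison). An alternative `"max_overlap"` mode
#' assigns the class covering the most query bases, ties broken by the same
#' precedence.
#'
#' @param partition A `genome_partition`.
#' @param intervals Interval tibble (`chrom`, `start`, `end`).
#' @param mode `"precedence"` (default) or `"max_overlap"`.
#' @return `intervals` with an added `region_class` factor column.
#' @export
classify_intervals <- function(partition, intervals,
                               mode = c("precedence", "max_overlap")) {
  mode <- match.arg(mode)
  stopifnot(inherits(partition, "genome_partition"))
  intervals <- validate_intervals(intervals, "query intervals")
  unknown <- setdiff(unique(intervals$chrom), partition$sizes$chrom)
  if (length(unknown) > 0) {
    abort(sprintf("unknown chromosome(s): %s", paste(unknown, collapse = ", ")))
  }
  if (nrow(intervals) == 0) {
    intervals$region_class <- factor(character(), levels = REGION_CLASSES)
    return(intervals)
  }
  cls <- rep(NA_character_, nrow(intervals))
  if (mode == "precedence") {
    for (cl in REGION_CLASSES) {
      ctab <- partition$classes[[cl]]
      if (nrow(ctab) == 0) next
      hit <- overlaps_any_iv(intervals, ctab)
      cls[is.na(cls) & hit] <- cl
    }
  } else {
    ov <- matrix(0, nrow(intervals), length(REGION_CLASSES),
                 dimnames = list(NULL, REGION_CLASSES))
    for (cl in REGION_CLASSES) {
      ctab <- partition$classes[[cl]]
      if (nrow(ctab) == 0) next
      hits <- find_overlaps_iv(intervals, ctab)
      if (length(hits) == 0) next
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      w <- pmin(intervals$end[qh], ctab$end[sh]) - pmax(intervals$start[qh], ctab$start[sh])
      agg <- tapply(w, qh, sum)
      ov[as.integer(names(agg)), cl] <- agg
    }
    cls <- REGION_CLASSES[apply(ov, 1, which.max)] # which.max: first max wins = precedence
    cls[rowSums(ov) == 0] <- NA_character_
  }
  # every base belongs to >= 1 class, so NA is impossible for in-bounds queries;
  # out-of-bounds queries (beyond the chromosome end) fall back to intergenic
  cls[is.na(cls)] <- "intergenic"
  intervals$region_class <- factor(cls, levels = REGION_CLASSES)
  intervals
}

#' Genomic distribution of a peak set
#'
#' Classifies every peak once (see [classify_intervals()]) and tabulates
#' island counts and percentages per region class.
#'
#' @param partition A `genome_partition`.
#' @param peaks Peak tibble.
#' @inheritParams classify_intervals
#' @return A `distribution_report` tibble with columns `region_class`, `n`,
#'   `percent` (one row per class, fixed order) and a `total` attribute.
#' @export
distribution_report <- function(partition, peaks, mode = c("precedence", "max_overlap")) {
  if (nrow(peaks) == 0) abort("cannot summarise an empty peak set")
  cls <- classify_intervals(partition, peaks, mode = mode)$region_class
  counts <- table(cls)
  out <- tibble(
    region_class = factor(REGION_CLASSES, levels = REGION_CLASSES),
    n = as.integer(counts[REGION_CLASSES]),
    percent = 100 * as.integer(counts[REGION_CLASSES]) / length(cls)
  )
  attr(out, "total") <- length(cls)
  class(out) <- c("distribution_report", class(out))
  out
}

#' Export a partition as per-class BED files
#'
#' @param partition A `genome_partition`.
#' @param dir Output directory (created if needed); one
#'   `partition_<class>.bed` per class.
#' @return The written paths, invisibly.
#' @export
write_partition <- function(partition, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- map_chr(REGION_CLASSES, function(cl) {
    p <- file.path(dir, sprintf("partition_%s.bed", cl))
    x <- sort_intervals(partition$classes[[cl]])
    writeLines(sprintf("%s\t%d\t%d", x$chrom, x$start, x$end), p)
    p
  })
  invisible(paths)
}
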