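# Independent oracles used across the suite. These deliberately avoid the
# package's interval machinery (no GenomicRanges): plain arithmetic only.

# O(n^2) all-pairs overlap partition of two peak tables (half-open).
brute_force_compare <- function(a, b) {
  pairs_a <- logical(nrow(a))
  pairs_b <- logical(nrow(b))
  pair_list <- list()
  k <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] && a$end[i] > b$start[j] && b$end[j] > a$start[i]) {
        pairs_a[i] <- TRUE
        pairs_b[j] <- TRUE
        k <- k + 1L
        pair_list[[k]] <- c(i, j)
      }
    }
  }
  list(
    common_a = which(pairs_a), common_b = which(pairs_b),
    specific_a = which(!pairs_a), specific_b = which(!pairs_b),
    n_pairs = k,
    pairs = if (k > 0) do.call(rbind, pair_list) else matrix(0L, 0, 2)
  )
}

# Per-base region class by direct scan over gene models, precedence
# promoter > exon > intron > intergenic. `pos` is a vector of 0-based bases.
brute_force_class <- function(genes, pos, chrom, halfwidth) {
  is_prom <- rep(FALSE, length(pos))
  is_exon <- rep(FALSE, length(pos))
  is_body <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != chrom) next
    tss <- if (genes$strand[i] == "+") genes$tx_start[i] else genes$tx_end[i] - 1L
    is_prom <- is_prom | (pos >= tss - halfwidth & pos < tss + halfwidth)
    is_body <- is_body | (pos >= genes$tx_start[i] & pos < genes$tx_end[i])
    for (j in seq_along(genes$exon_starts[[i]])) {
      is_exon <- is_exon |
        (pos >= genes$exon_starts[[i]][j] & pos < genes$exon_ends[[i]][j])
    }
  }
  ifelse(is_prom, "proximal_promoter",
         ifelse(is_exon, "exon",
                ifelse(is_body, "intron", "intergenic")))
}

# Upper Poisson tail by direct series summation: 1 - sum_{k<count} P(X = k).
series_poisson_tail <- function(count, lam) {
  if (count == 0) return(1)
  k <- 0:(count - 1)
  1 - sum(exp(-lam) * lam^k / factorial(k))
}

# Random peak table on a couple of chromosomes, adjacency-prone coordinates.
random_peaks <- function(n, max_pos = 1000, max_len = 60) {
  starts <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = starts,
    end = starts + sample.int(max_len, n, replace = TRUE)
  )
}

# A tiny deterministic gene set for metagene and partition fixtures.
toy_genes <- function() {
  tibble::tibble(
    tx_id = c("tx_a", "tx_b"),
    gene_symbols = list("GA", "GB"),
    chrom = "chr1",
    strand = c("+", "-"),
    tx_start = c(10000L, 40000L),
    tx_end = c(18000L, 52000L),
    exon_starts = list(c(10000L, 14000L), c(40000L, 47000L)),
    exon_ends = list(c(11000L, 15000L), c(42000L, 52000L))
  )
}

toy_sizes <- function(len = 100000L) {
  tibble::tibble(chrom = "chr1", length = len)
}

# Recall/precision of called islands against planted intervals (>=1 bp).
overlap_stats <- function(called, planted) {
  hit_planted <- vapply(seq_len(nrow(planted)), function(i) {
    any(called$chrom == planted$chrom[i] &
          called$start < planted$end[i] & called$end > planted$start[i])
  }, TRUE)
  hit_called <- vapply(seq_len(nrow(called)), function(i) {
    any(planted$chrom == called$chrom[i] &
          planted$start < called$end[i] & planted$end > called$start[i])
  }, TRUE)
  list(recall = mean(hit_planted), precision = mean(hit_called))
}

# Share-fraction estimate from a peak_comparison (per-side common counts).
estimate_share <- function(cmp) {
  cts <- cmp$counts
  c_mean <- (cts$n_common_a + cts$n_common_b) / 2
  c_mean / (cts$n_a + cts$n_b - c_mean)
}
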