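test_that("1 bp overlap is common, adjacency is specific", {
  a <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L)
  b1 <- tibble::tibble(chrom = "chr1", start = 199L, end = 300L)
  cmp <- compare_peak_sets(a, b1)
  expect_equal(cmp$counts$n_common_a, 1)
  expect_equal(cmp$counts$n_common_b, 1)

  b2 <- tibble::tibble(chrom = "chr1", start = 200L, end = 300L)
  cmp <- compare_peak_sets(a, b2)
  expect_equal(cmp$counts$n_common_a, 0)
  expect_equal(cmp$counts$n_specific_a, 1)
  expect_equal(cmp$counts$n_specific_b, 1)
})

test_that("interval comparison equals the quadratic brute-force oracle", {
  set.seed(101)
  for (i in 1:200) {
    a <- random_peaks(sample.int(50, 1))
    b <- random_peaks(sample.int(50, 1))
    cmp <- compare_peak_sets(a, b)
    oracle <- brute_force_compare(a, b)
    expect_equal(which(cmp$peaks_a$status == "common"), oracle$common_a)
    expect_equal(which(cmp$peaks_b$status == "common"), oracle$common_b)
    expect_equal(cmp$counts$n_pairs, oracle$n_pairs)
  }
})

test_that("comparison is symmetric and conserves peak counts", {
  set.seed(202)
  for (i in 1:25) {
    a <- random_peaks(30)
    b <- random_peaks(30)
    ab <- compare_peak_sets(a, b)
    ba <- compare_peak_sets(b, a)
    expect_equal(ab$counts$n_common_a + ab$counts$n_specific_a, nrow(a))
    expect_equal(ab$counts$n_common_b + ab$counts$n_specific_b, nrow(b))
    transposed <- ba$common_pairs[, c("index_b", "index_a")]
    names(transposed) <- c("index_a", "index_b")
    expect_equal(
      dplyr::arrange(ab$common_pairs[, c("index_a", "index_b")], index_a, index_b),
      dplyr::arrange(transposed, index_a, index_b)
    )
  }
})

test_that("cross-mark overlap counts are per-side and can differ", {
  me1 <- tibble::tibble(chrom = "chr1", start = 100L, end = 500L)
  me3 <- tibble::tibble(chrom = "chr1", start = c(150L, 400L), end = c(250L, 600L))
  cmp <- cross_mark_comparison(me1, me3)
  expect_equal(cmp$counts$n_common_a, 1) # one me1 region overlaps
  expect_equal(cmp$counts$n_common_b, 2) # both me3 regions overlap
  expect_equal(cmp$counts$n_pairs, 2)
  expect_equal(cmp$labels, c("H3K4me1", "H3K4me3"))

  none <- compare_peak_sets(me1, tibble::tibble(chrom = "chr2", start = 1L, end = 5L))
  expect_equal(none$counts$n_common_a + none$counts$n_common_b, 0)
})

test_that("promoter enrichment ratios match hand computation", {
  sizes <- toy_sizes()
  genes <- toy_genes() # promoters: [9000,11000) for tx_a(+), [50999,52999) for tx_b(-)
  part <- build_partition(genes, sizes, 1000)
  peaks_a <- tibble::tibble(chrom = "chr1", start = c(9400L, 30000L), end = c(9800L, 30500L))
  peaks_b <- tibble::tibble(chrom = "chr1", start = 51000L, end = 51600L)
  mk_tags <- function(starts) {
    tibble::tibble(chrom = "chr1", start = starts, end = starts + 36L, strand = "+")
  }
  # 400 A-tags inside A's promoter peak, 50 elsewhere; 80 B-tags in B's peak
  tags_a <- mk_tags(c(rep(9500L, 400), rep(70000L, 50)))
  tags_b <- mk_tags(rep(51200L, 80))
  rec <- promoter_mark_table(part, peaks_a, peaks_b, tags_a, tags_b)
  expect_equal(nrow(rec), 2) # both promoters marked in at least one lineage
  rec_a <- rec[rec$start == 9000, ]
  expect_equal(rec_a$ratio_a, 400 / 2000)
  expect_equal(rec_a$ratio_b, 0) # no B peak on tx_a's promoter
  rec_b <- rec[rec$start == 50999, ]
  expect_equal(rec_b$ratio_a, 0)
  expect_equal(rec_b$ratio_b, 80 / 2000)
  expect_equal(rec_b$gene_symbols[[1]], "GB")

  # a promoter with no peak in either lineage is excluded
  expect_false(any(rec$ratio_a == 0 & rec$ratio_b == 0))

  # multiple peaks on one promoter: sum vs max
  peaks_a2 <- tibble::tibble(chrom = "chr1", start = c(9100L, 10500L), end = c(9600L, 10900L))
  tags_a2 <- mk_tags(c(rep(9200L, 100), rep(10600L, 40)))
  rec_sum <- promoter_mark_table(part, peaks_a2, peaks_b, tags_a2, tags_b)
  rec_max <- promoter_mark_table(part, peaks_a2, peaks_b, tags_a2, tags_b,
                                 multi_peak = "max")
  expect_equal(rec_sum$ratio_a[rec_sum$start == 9000], 140 / 2000)
  expect_equal(rec_max$ratio_a[rec_max$start == 9000], 100 / 2000)

  # cpm rescales by library size
  rec_cpm <- promoter_mark_table(part, peaks_a, peaks_b, tags_a, tags_b, cpm = TRUE)
  expect_equal(rec_cpm$ratio_a[rec_cpm$start == 9000],
               (400 * 1e6 / 450) / 2000)
})

test_that("gene Venn is plain set algebra on associated genes", {
  v <- gene_venn(c("FOXP3", "CCR7", "STAT1"), c("STAT1"))
  expect_equal(v$common, "STAT1")
  expect_equal(sort(v$specific_a), c("CCR7", "FOXP3"))
  expect_equal(v$specific_b, character())
  expect_equal(v$counts$n_common, 1)

  same <- gene_venn(c("A", "B"), c("B", "A"))
  expect_equal(same$counts$n_specific_a + same$counts$n_specific_b, 0)
  disjoint <- gene_venn(c("A"), c("B"))
  expect_equal(disjoint$counts$n_common, 0)

  td <- tidy(v)
  expect_equal(nrow(td), 3)
  expect_true(all(c("gene", "set") %in% names(td)))
})

test_that("gene Venn deduplicates transcript multiplicity via promoter tables", {
  part <- build_partition(toy_genes(), toy_sizes(), 1000)
  marked_a <- marked_promoters(part, tibble::tibble(chrom = "chr1", start = 9500L, end = 9700L))
  marked_b <- marked_promoters(part, tibble::tibble(chrom = "chr1", start = c(9500L, 51500L),
                                                    end = c(9700L, 51800L)))
  expect_equal(nrow(marked_a), 1)
  v <- gene_venn(marked_a, marked_b)
  expect_equal(v$common, "GA")
  expect_equal(v$specific_b, "GB")
})

test_that("correlation is exact on linear fixtures and errors on degenerate input", {
  rec <- tibble::tibble(ratio_a = c(0.1, 0.2, 0.5, 0.9), ratio_b = c(0.2, 0.4, 1.0, 1.8))
  expect_equal(enrichment_correlation(rec)$estimate, 1.0)
  rec$ratio_b <- -rec$ratio_a + 2
  expect_equal(enrichment_correlation(rec)$estimate, -1.0)
  expect_equal(enrichment_correlation(rec)$n, 4)

  expect_error(enrichment_correlation(rec[1:2, ]), ">= 3")
  rec$ratio_b <- 1
  expect_error(enrichment_correlation(rec), "zero variance")
  expect_error(enrichment_correlation(tibble::tibble(x = 1)), "ratio_a")
})

test_that("correlation recovers a planted rho within sampling error", {
  set.seed(77)
  rho <- 0.8
  x <- stats::rnorm(100)
  y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(100)
  rec <- tibble::tibble(ratio_a = x + 5, ratio_b = y + 5) # shift into ratio range
  est <- enrichment_correlation(rec)$estimate
  expect_lt(abs(est - rho), 0.1)
  # spearman flag
  expect_equal(enrichment_correlation(rec, method = "spearman")$method, "spearman")
  # log2 restricts to positive pairs
  rec$ratio_a[1] <- 0
  lg <- enrichment_correlation(rec, log2_transform = TRUE)
  expect_equal(lg$n, 99)
})
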