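# One plus-strand gene with a 10 kb body on a large chromosome; flank 5 kb,
# 40 bins -> 125 bp flank windows, 250 bp body windows.
metagene_fixture_gene <- function(strand = "+") {
  tibble::tibble(
    tx_id = "tx1", gene_symbols = list("G1"), chrom = "chr1", strand = strand,
    tx_start = 20000L, tx_end = 30000L,
    exon_starts = list(20000L), exon_ends = list(30000L)
  )
}

test_that("tag density follows reads / (total reads x window length)", {
  gene <- metagene_fixture_gene()
  # 10 tags wholly inside the 5'-most upstream window [15000, 15125)
  tags <- tibble::tibble(chrom = "chr1", start = rep(15010L, 10), end = rep(15040L, 10),
                         strand = "+")
  prof <- tidy(metagene_profile(gene, tags, total_reads = 1000))
  up1 <- prof[prof$region == "upstream" & prof$bin == 1, ]
  expect_equal(up1$density, 10 / (1000 * 125))
  expect_equal(up1$n_tags, 10L)
  expect_equal(sum(prof$n_tags), 10L)
  expect_equal(sum(prof$density > 0), 1)
})

test_that("a tag-free library gives 120 zero densities", {
  gene <- metagene_fixture_gene()
  tags <- tibble::tibble(chrom = character(), start = integer(), end = integer(),
                         strand = character())
  prof <- tidy(metagene_profile(gene, tags, total_reads = 100))
  expect_equal(nrow(prof), 120)
  expect_true(all(prof$density == 0))
})

test_that("pooled profile equals per-tag brute-force assignment across many genes", {
  params <- sim_params(
    n_genes = 20, chrom_lengths = tibble::tibble(chrom = "chr1", length = 2e6),
    gene_length_range = c(4000L, 12000L), seed = 13,
    promoter_halfwidth = 5000L # spacing scales with halfwidth: keeps gene windows disjoint
  )
  genome <- generate_genome(params)
  genes <- genome$genes
  # plant 3 point-like tags in the 5'-most upstream window of every gene
  tag_pos <- unlist(lapply(seq_len(nrow(genes)), function(i) {
    if (genes$strand[i] == "+") genes$tx_start[i] - 5000L + 10L + 0:2
    else genes$tx_end[i] + 5000L - 13L + 0:2
  }))
  tags <- tibble::tibble(chrom = "chr1", start = tag_pos, end = tag_pos + 1L, strand = "+")
  prof <- tidy(metagene_profile(genes, tags))
  up1 <- prof[prof$region == "upstream" & prof$bin == 1, ]
  expect_equal(up1$n_tags, 3L * nrow(genes))
  expect_equal(up1$window_bp, 125L * nrow(genes))
  expect_equal(up1$density, (3 * nrow(genes)) / (nrow(tags) * 125 * nrow(genes)))
  expect_equal(sum(prof$n_tags), nrow(tags))
})

test_that("duplicating every tag leaves densities unchanged", {
  gene <- metagene_fixture_gene()
  set.seed(4)
  pos <- sample(14000:31000, 200, replace = TRUE)
  tags <- tibble::tibble(chrom = "chr1", start = pos, end = pos + 36L, strand = "+")
  p1 <- tidy(metagene_profile(gene, tags))
  p2 <- tidy(metagene_profile(gene, dplyr::bind_rows(tags, tags)))
  expect_equal(p1$density, p2$density)
})

test_that("density x window length x library total recovers assigned tag counts", {
  params <- sim_params(
    n_genes = 10, chrom_lengths = tibble::tibble(chrom = "chr1", length = 1e6),
    gene_length_range = c(4000L, 9000L), seed = 21
  )
  genome <- generate_genome(params)
  set.seed(5)
  pos <- sample.int(1e6 - 40L, 5000)
  tags <- tibble::tibble(chrom = "chr1", start = pos, end = pos + 36L, strand = "+")
  prof <- tidy(metagene_profile(genome$genes, tags))
  expect_equal(prof$density * prof$window_bp * nrow(tags), as.numeric(prof$n_tags))
})

test_that("minus-strand genes are flipped so bin 1 is 5'-most", {
  gene <- metagene_fixture_gene(strand = "-")
  # 5' of a minus gene is tx_end; farthest upstream window is [tx_end+4875, tx_end+5000)
  tags <- tibble::tibble(chrom = "chr1", start = 34900L, end = 34920L, strand = "-")
  prof <- tidy(metagene_profile(gene, tags))
  expect_equal(prof$n_tags[prof$region == "upstream" & prof$bin == 1], 1L)
  # literal mode keeps genomic orientation: that tag is in the last downstream window
  prof_lit <- tidy(metagene_profile(gene, tags, orient = "literal"))
  expect_equal(prof_lit$n_tags[prof_lit$region == "downstream" & prof_lit$bin == 40], 1L)
})

test_that("five-prime assignment counts each tag exactly once", {
  gene <- metagene_fixture_gene()
  # a long fragment straddling two body windows
  tags <- tibble::tibble(chrom = "chr1", start = 20200L, end = 20400L, strand = "+")
  prof_ov <- tidy(metagene_profile(gene, tags))
  prof_5p <- tidy(metagene_profile(gene, tags, assign = "five_prime"))
  expect_equal(sum(prof_ov$n_tags), 2L) # body windows are 250 bp: [20000,20250), [20250,20500)
  expect_equal(sum(prof_5p$n_tags), 1L)
  expect_equal(prof_5p$n_tags[prof_5p$region == "body" & prof_5p$bin == 1], 1L)
})

test_that("TSS-centred and body-distributed enrichment give the expected shapes", {
  params <- sim_params(
    n_genes = 30, chrom_lengths = tibble::tibble(chrom = "chr1", length = 3e6),
    gene_length_range = c(8000L, 16000L), seed = 31,
    promoter_halfwidth = 5000L # keep gene flank windows disjoint between genes
  )
  genome <- generate_genome(params)
  genes <- genome$genes
  tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1L)
  set.seed(8)
  # TSS-centred: tags uniform within +/-250 bp of the TSS
  pos3 <- rep(tss, each = 60) + sample(-250:213, 60 * nrow(genes), replace = TRUE)
  me3ish <- tibble::tibble(chrom = "chr1", start = pos3, end = pos3 + 36L, strand = "+")
  prof3 <- tidy(metagene_profile(genes, me3ish))
  peak_bin <- which.max(prof3$density)
  boundary_bins <- which(
    (prof3$region == "upstream" & prof3$bin >= 39) |
      (prof3$region == "body" & prof3$bin <= 2)
  )
  expect_true(peak_bin %in% boundary_bins)

  # body-distributed: tags uniform within gene bodies
  pos1 <- unlist(lapply(seq_len(nrow(genes)), function(i) {
    genes$tx_start[i] + sample.int(genes$tx_end[i] - genes$tx_start[i] - 36L, 60)
  }))
  me1ish <- tibble::tibble(chrom = "chr1", start = pos1, end = pos1 + 36L, strand = "+")
  prof1 <- tidy(metagene_profile(genes, me1ish))
  body_mean <- mean(prof1$density[prof1$region == "body"])
  distal_flank <- mean(prof1$density[
    (prof1$region == "upstream" & prof1$bin <= 20) |
      (prof1$region == "downstream" & prof1$bin > 20)
  ])
  expect_gt(body_mean, 5 * distal_flank)
})

test_that("short genes are skipped with a warning and empty inputs error", {
  genes <- dplyr::bind_rows(
    metagene_fixture_gene(),
    tibble::tibble(tx_id = "tiny", gene_symbols = list("T"), chrom = "chr1",
                   strand = "+", tx_start = 50000L, tx_end = 50030L,
                   exon_starts = list(50000L), exon_ends = list(50030L))
  )
  tags <- tibble::tibble(chrom = "chr1", start = 1L, end = 37L, strand = "+")
  expect_warning(metagene_profile(genes, tags), "skipping 1 gene")
  expect_error(metagene_profile(genes[0, ], tags), "empty gene list")
  expect_error(metagene_profile(genes, tags, flank = 5000, n_bins = 37), "divisible")
  expect_error(metagene_profile(genes[1, ], tags[0, ]), "total_reads")
})
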