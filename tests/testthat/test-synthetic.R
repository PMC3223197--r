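small_params <- function(...) {
  defaults <- list(
    n_genes = 30, chrom_lengths = tibble::tibble(chrom = "chr1", length = 3e6),
    n_peaks = 30, library_size = 30000L, seed = 17
  )
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}

test_that("generation is deterministic under the seed", {
  p <- small_params()
  g1 <- generate_genome(p)
  g2 <- generate_genome(p)
  expect_identical(g1, g2)
  t1 <- plant_architecture(g1, p)
  t2 <- plant_architecture(g2, p)
  expect_identical(t1$peaks, t2$peaks)
  l1 <- generate_tags(t1, "H3K4me3", "Treg", p)
  l2 <- generate_tags(t1, "H3K4me3", "Treg", p)
  expect_identical(as.data.frame(l1), as.data.frame(l2))
  # different seed, different draw
  p2 <- small_params(seed = 18)
  expect_false(identical(as.data.frame(l1),
                         as.data.frame(generate_tags(plant_architecture(generate_genome(p2), p2),
                                                     "H3K4me3", "Treg", p2))))
})

test_that("generated genomes respect their invariants", {
  p <- small_params()
  g <- generate_genome(p)
  expect_equal(nrow(g$genes), p$n_genes)
  expect_true(all(g$genes$tx_end <= sum(g$sizes$length)))
  # non-overlapping, sorted placement
  expect_true(all(diff(g$genes$tx_start) > 0))
  expect_true(all(utils::head(g$genes$tx_end, -1) < utils::tail(g$genes$tx_start, -1)))
  # exon structure valid (validate_gene_models aborts otherwise)
  expect_true(all(purrr::map_int(g$genes$exon_starts, length) >= 2))
  expect_true(all(purrr::map_int(g$genes$exon_starts, length) <= 10))
  expect_equal(nrow(generate_genome(small_params(n_genes = 0))$genes), 0)
  expect_error(generate_genome(small_params(n_genes = 10000)), "pack")
})

test_that("generated annotation survives a refFlat round trip", {
  g <- generate_genome(small_params())
  path <- withr::local_tempfile()
  expect_no_warning(write_gene_annotation(g$genes, path))
  expect_no_warning(back <- read_gene_annotation(path))
  expect_equal(back$tx_start, g$genes$tx_start)
  expect_equal(back$exon_ends, g$genes$exon_ends)
})

test_that("share_fraction 1 and 0 give all-common and no-common truths", {
  p1 <- small_params(share_fraction = c(H3K4me3 = 1, H3K4me1 = 1))
  t1 <- plant_architecture(generate_genome(p1), p1)
  expect_true(all(t1$peaks$label == "common"))
  p0 <- small_params(share_fraction = c(H3K4me3 = 0, H3K4me1 = 0))
  t0 <- plant_architecture(generate_genome(p0), p0)
  expect_true(all(t0$peaks$label == "specific"))
  expect_true(all(t0$peaks$cell %in% p0$cell_types))
})

test_that("a pure-promoter mixture plants only promoter-class peaks", {
  mix <- c(proximal_promoter = 1, exon = 0, intron = 0, intergenic = 0)
  p <- small_params(class_mixture = list(H3K4me3 = mix, H3K4me1 = mix), n_peaks = 15)
  g <- generate_genome(p)
  truth <- plant_architecture(g, p)
  got <- classify_intervals(truth$partition,
                            truth$peaks[, c("chrom", "start", "end")])
  expect_true(all(got$region_class == "proximal_promoter"))
  # and planted intervals stay within chromosome bounds
  sv <- setNames(g$sizes$length, g$sizes$chrom)
  expect_true(all(truth$peaks$start >= 0))
  expect_true(all(truth$peaks$end <= sv[truth$peaks$chrom]))
})

test_that("background-only libraries look Poisson-uniform", {
  p <- small_params(n_peaks = 0, library_size = 20000L)
  truth <- plant_architecture(generate_genome(p), p)
  expect_equal(nrow(truth$peaks), 0)
  tags <- generate_tags(truth, "H3K4me3", "Treg", p)
  expect_equal(nrow(tags), 20000)
  # chi-squared goodness of fit of start positions against uniform 10 kb bins
  bins <- table(cut(tags$start, breaks = seq(0, 3e6, by = 1e4), include.lowest = TRUE))
  gof <- suppressWarnings(stats::chisq.test(as.integer(bins)))
  expect_gt(gof$p.value, 0.001)
})

test_that("tag libraries concentrate in planted peaks at high enrichment", {
  p <- small_params(enrichment_fold = 1e6)
  truth <- plant_architecture(generate_genome(p), p)
  tags <- generate_tags(truth, "H3K4me1", "aTconv", p)
  planted <- truth_peaks(truth, "H3K4me1", "aTconv")
  in_peak <- vapply(seq_len(nrow(tags)), function(i) {
    any(planted$chrom == tags$chrom[i] & tags$start[i] >= planted$start &
          tags$start[i] < planted$end)
  }, TRUE)
  expect_gt(mean(in_peak), 0.999)
  expect_error(generate_tags(truth, "H3K4me1", "aTconv",
                             small_params(library_size = 0)),
               "library_size")
})

test_that("generated BED files parse back without warnings", {
  p <- small_params()
  study <- simulate_study(p)
  path <- withr::local_tempfile(fileext = ".bed")
  expect_no_warning(write_tags(study$tags$H3K4me3$Treg, path))
  expect_no_warning(back <- read_tags(path))
  expect_equal(nrow(back), nrow(study$tags$H3K4me3$Treg))
  sizes_path <- withr::local_tempfile()
  write_chrom_sizes(study$sizes, sizes_path)
  expect_equal(read_chrom_sizes(sizes_path), study$sizes)
})

test_that("end-to-end gene Venn from called peaks agrees with planted truth", {
  p <- sim_params(
    n_genes = 40, chrom_lengths = tibble::tibble(chrom = "chr1", length = 4e6),
    n_peaks = 40, library_size = 40000L, seed = 7
  )
  study <- simulate_study(p)
  cells <- p$cell_types
  truth_marked <- lapply(cells, function(cc) {
    marked_promoters(study$partition,
                     truth_peaks(study$truth, "H3K4me3", cc))
  })
  venn_truth <- gene_venn(truth_marked[[1]], truth_marked[[2]])
  called <- lapply(cells, function(cc) call_peaks(study$tags$H3K4me3[[cc]], study$sizes))
  venn_called <- gene_venn(
    marked_promoters(study$partition, called[[1]]),
    marked_promoters(study$partition, called[[2]])
  )
  sets_of <- function(v) {
    stats::setNames(
      rep(c("common", "a", "b"),
          c(length(v$common), length(v$specific_a), length(v$specific_b))),
      c(v$common, v$specific_a, v$specific_b)
    )
  }
  st <- sets_of(venn_truth)
  sc <- sets_of(venn_called)
  genes_union <- union(names(st), names(sc))
  same <- !is.na(st[genes_union]) & !is.na(sc[genes_union]) &
    st[genes_union] == sc[genes_union]
  agreement <- mean(same)
  expect_gte(agreement, 0.95)
})
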