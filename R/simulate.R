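# Seeded synthetic-data generator: toy genomes with non-overlapping gene
# models, planted peak architectures whose genomic-class mixture mimics the
# two marks (H3K4me3 promoter-heavy, H3K4me1 intron-heavy), shared vs
# lineage-specific peak labels, and tag libraries drawn from a
# uniform-background / uniform-within-peak mixture. Every generated object
# carries ground truth so downstream stages can be validated end to end.

#' Synthetic study parameters
#'
#' Defaults describe the study conditions used throughout the package's
#' validation: a 20 Mb two-chromosome toy genome with 200 genes, 300 planted
#' 1 kb peaks per mark at 20x background enrichment, libraries of 200 000
#' 200 bp tags, a promoter-heavy class mixture with high cross-lineage
#' sharing for the H3K4me3-like mark and an intron-heavy mixture with low
#' sharing for the H3K4me1-like mark.
#'
#' @param n_genes Number of gene models to place.
#' @param chrom_lengths Chromosome sizes tibble.
#' @param promoter_halfwidth Promoter half-width used for planting (bp).
#' @param n_peaks Planted peaks per mark.
#' @param peak_length Planted peak width (bp).
#' @param class_mixture Named list per mark of probabilities over the four
#'   region classes for planted peak placement.
#' @param share_fraction Named per-mark probability that a planted peak is
#'   common to both cell types.
#' @param enrichment_fold In-peak over background tag-rate ratio.
#' @param background_rate Background tag density (tags/bp); used when
#'   `library_size` is `NULL`.
#' @param library_size Tags per library; overrides `background_rate`.
#' @param fragment_length Tag fragment width (bp).
#' @param gene_length_range Min/max gene body length (bp).
#' @param min_peak_spacing Minimum gap between planted peaks of one mark
#'   (bp), so called islands never merge across planted loci.
#' @param cell_types Length-2 labels for the two lineages.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A named parameter list for the `generate_*` functions.
#' @export
sim_params <- function(n_genes = 200L,
                       chrom_lengths = tibble(chrom = c("chr1", "chr2"),
                                              length = c(12e6, 8e6)),
                       promoter_halfwidth = 1000L,
                       n_peaks = 300L,
                       peak_length = 1000L,
                       class_mixture = list(
                         H3K4me3 = c(proximal_promoter = 0.45, exon = 0.12,
                                     intron = 0.25, intergenic = 0.18),
                         H3K4me1 = c(proximal_promoter = 0.05, exon = 0.08,
                                     intron = 0.55, intergenic = 0.32)
                       ),
                       share_fraction = c(H3K4me3 = 0.7, H3K4me1 = 0.2),
                       enrichment_fold = 20,
                       background_rate = 0.0075,
                       library_size = 200000L,
                       fragment_length = 200L,
                       gene_length_range = c(5000L, 20000L),
                       min_peak_spacing = 2000L,
                       cell_types = c("Treg", "aTconv"),
                       seed = 1L) {
  for (m in names(class_mixture)) {
    mix <- class_mixture[[m]]
    if (!setequal(names(mix), REGION_CLASSES)) {
      abort(sprintf("class_mixture for %s must name all four region classes", m))
    }
    if (abs(sum(mix) - 1) > 1e-8) abort("class mixture probabilities must sum to 1")
  }
  if (any(share_fraction < 0 | share_fraction > 1)) abort("share_fraction must be in [0, 1]")
  if (enrichment_fold <= 1) abort("enrichment_fold must be > 1")
  list(
    n_genes = as.integer(n_genes), chrom_lengths = chrom_lengths,
    promoter_halfwidth = as.integer(promoter_halfwidth),
    n_peaks = as.integer(n_peaks), peak_length = as.integer(peak_length),
    class_mixture = class_mixture, share_fraction = share_fraction,
    enrichment_fold = enrichment_fold, background_rate = background_rate,
    library_size = if (is.null(library_size)) NULL else as.integer(library_size),
    fragment_length = as.integer(fragment_length),
    gene_length_range = as.integer(gene_length_range),
    min_peak_spacing = as.integer(min_peak_spacing),
    cell_types = cell_types, seed = as.integer(seed)
  )
}

#' Generate a toy genome with non-overlapping gene models
#'
#' Genes (2-10 exons each, random strand, body lengths uniform in
#' `gene_length_range`) are packed onto the chromosomes proportionally to
#' chromosome length, separated by at least twice the promoter half-width
#' plus 1 kb so adjacent promoter windows never merge across genes. Output
#' is deterministic under `params$seed`.
#'
#' @param params Parameter list from [sim_params()].
#' @return A list with `sizes` (chromosome sizes tibble) and `genes` (gene
#'   model tibble, same shape as [read_gene_annotation()]).
#' @export
generate_genome <- function(params = sim_params()) {
  withr::with_seed(params$seed, generate_genome_impl(params))
}

generate_genome_impl <- function(params) {
  sizes <- arrange(as_tibble(params$chrom_lengths), .data$chrom)
  sizes$length <- as.integer(sizes$length)
  n <- params$n_genes
  empty <- tibble(
    tx_id = character(), gene_symbols = list(), chrom = character(),
    strand = character(), tx_start = integer(), tx_end = integer(),
    exon_starts = list(), exon_ends = list()
  )
  if (n == 0) return(list(sizes = sizes, genes = empty))
  min_gap <- 2L * params$promoter_halfwidth + 1000L
  # allocate genes to chromosomes proportionally to length
  alloc <- floor(n * as.numeric(sizes$length) / sum(as.numeric(sizes$length)))
  rem <- n - sum(alloc)
  if (rem > 0) alloc[order(-sizes$length)[seq_len(rem)]] <- alloc[order(-sizes$length)[seq_len(rem)]] + 1
  gene_rows <- list()
  gi <- 0L
  for (ci in seq_len(nrow(sizes))) {
    k <- alloc[ci]
    if (k == 0) next
    len <- runif(k, params$gene_length_range[1], params$gene_length_range[2])
    len <- as.integer(round(len))
    slack <- sizes$length[ci] - sum(len) - (k + 1) * min_gap
    if (slack < 0) {
      abort(sprintf("cannot pack %d genes onto %s without violating spacing",
                    k, sizes$chrom[ci]))
    }
    # split the slack into k+1 gaps with a uniform stick-breaking draw
    cuts <- sort(runif(k))
    gaps <- diff(c(0, cuts, 1)) * slack
    starts <- as.integer(round(min_gap + cumsum(gaps[seq_len(k)]) +
                                 c(0, cumsum(len[-k]))[seq_len(k)] +
                                 (seq_len(k) - 1) * min_gap))
    for (j in seq_len(k)) {
      gi <- gi + 1L
      L <- len[j]
      n_ex <- sample(2:10, 1)
      cutpts <- sort(sample(seq_len(L - 1L), 2L * n_ex - 2L))
      bounds <- c(0L, cutpts, L)
      ex_s <- starts[j] + bounds[seq(1, length(bounds), by = 2)]
      ex_e <- starts[j] + bounds[seq(2, length(bounds), by = 2)]
      gene_rows[[gi]] <- tibble(
        tx_id = sprintf("tx_%04d", gi),
        gene_symbols = list(sprintf("GENE%04d", gi)),
        chrom = sizes$chrom[ci],
        strand = sample(c("+", "-"), 1),
        tx_start = starts[j],
        tx_end = starts[j] + L,
        exon_starts = list(as.integer(ex_s)),
        exon_ends = list(as.integer(ex_e))
      )
    }
  }
  genes <- bind_rows(gene_rows)
  validate_gene_models(genes)
  list(sizes = sizes, genes = genes)
}

#' Plant a two-lineage peak architecture
#'
#' For each mark, draws each planted peak's region class from the mark's
#' class mixture and places a `peak_length` interval, by rejection sampling
#' a position inside the target class until the planted interval classifies
#' to that class under precedence and keeps `min_peak_spacing` from every
#' other planted peak of the mark. Each peak is then labelled `common`
#' (present in both cell types at the same locus) with probability
#' `share_fraction[mark]`, otherwise assigned to one cell type uniformly.
#'
#' @param genome Output of [generate_genome()].
#' @param params Parameter list from [sim_params()].
#' @param partition Optional pre-built `genome_partition` (rebuilt from the
#'   genome otherwise).
#' @return A `planted_truth` list: `peaks` (tibble with `mark`, `peak_id`,
#'   `chrom`, `start`, `end`, `region_class`, `label`, `cell`), the
#'   `partition` used, and `params`.
#' @export
plant_architecture <- function(genome, params = sim_params(), partition = NULL) {
  partition <- partition %||%
    build_partition(genome$genes, genome$sizes, params$promoter_halfwidth)
  withr::with_seed(params$seed + 1L, plant_architecture_impl(genome, params, partition))
}

plant_architecture_impl <- function(genome, params, partition) {
  half <- params$peak_length %/% 2L
  sv <- sizes_vec(genome$sizes)
  all_peaks <- list()
  for (mark in names(params$class_mixture)) {
    mix <- params$class_mixture[[mark]][REGION_CLASSES]
    target <- sample(REGION_CLASSES, params$n_peaks, replace = TRUE, prob = mix)
    placed <- tibble(chrom = character(), start = integer(), end = integer())
    placed_gr_list <- list()
    classes <- character(params$n_peaks)
    for (i in seq_len(params$n_peaks)) {
      cl <- target[i]
      pool <- partition$classes[[cl]]
      w <- as.numeric(pool$end - pool$start)
      ok <- FALSE
      for (try in seq_len(500)) {
        row <- sample.int(nrow(pool), 1, prob = w)
        pos <- pool$start[row] + floor(runif(1) * (pool$end[row] - pool$start[row]))
        s <- as.integer(pos - half)
        e <- s + params$peak_length
        if (s < 0 || e > sv[[pool$chrom[row]]]) next
        cand <- tibble(chrom = pool$chrom[row], start = s, end = e)
        # classify with a fragment-length margin so islands called from the
        # planted locus (which extend ~1 fragment beyond it) keep the class
        pad <- tibble(chrom = cand$chrom,
                      start = max(0L, s - params$fragment_length),
                      end = min(sv[[cand$chrom]], e + params$fragment_length))
        if (classify_intervals(partition, pad)$region_class != cl) next
        if (nrow(placed) > 0) {
          near <- placed$chrom == cand$chrom &
            placed$start < e + params$min_peak_spacing &
            placed$end > s - params$min_peak_spacing
          if (any(near)) next
        }
        ok <- TRUE
        break
      }
      if (!ok) {
        abort(sprintf("could not place a %s peak for %s after 500 tries", cl, mark))
      }
      placed <- bind_rows(placed, cand)
      classes[i] <- cl
    }
    common <- runif(params$n_peaks) < params$share_fraction[[mark]]
    cell <- ifelse(common, NA_character_,
                   sample(params$cell_types, params$n_peaks, replace = TRUE))
    all_peaks[[mark]] <- tibble(
      mark = mark,
      peak_id = sprintf("%s_planted_%03d", mark, seq_len(params$n_peaks)),
      chrom = placed$chrom, start = placed$start, end = placed$end,
      region_class = factor(classes, levels = REGION_CLASSES),
      label = ifelse(common, "common", "specific"),
      cell = cell
    )
  }
  structure(
    list(peaks = bind_rows(all_peaks) |> arrange(.data$mark, .data$chrom, .data$start),
         partition = partition, params = params),
    class = "planted_truth"
  )
}

#' Planted peaks present in one cell type
#'
#' @param truth A `planted_truth`.
#' @param mark Mark name.
#' @param cell Cell-type label.
#' @return The planted-peak rows for that library (common peaks plus the
#'   cell's specific peaks).
#' @export
truth_peaks <- function(truth, mark, cell) {
  filter(truth$peaks, .data$mark == !!mark,
         .data$label == "common" | .data$cell == !!cell)
}

#' Generate a tag library for one cell type and mark
#'
#' Tags are `fragment_length` intervals with random strand whose start
#' positions are drawn from a two-component mixture: uniform over the genome
#' outside the cell's planted peaks (background) and uniform within the
#' planted peaks at `enrichment_fold` times the background rate, until
#' `library_size` tags are drawn. Deterministic under the seed (each
#' library's seed is derived from `params$seed` and its mark/cell label).
#'
#' @param truth A `planted_truth` from [plant_architecture()].
#' @param mark,cell Library identity.
#' @param params Parameter list from [sim_params()].
#' @return A tag tibble (see [tag_library()]).
#' @export
generate_tags <- function(truth, mark, cell, params = sim_params()) {
  idx <- which(names(params$class_mixture) == mark) - 1L
  cidx <- which(params$cell_types == cell) - 1L
  if (length(idx) == 0 || length(cidx) == 0) abort("unknown mark or cell type")
  seed <- params$seed + 1000L + 10L * idx + cidx
  withr::with_seed(seed, generate_tags_impl(truth, mark, cell, params))
}

generate_tags_impl <- function(truth, mark, cell, params) {
  sizes <- truth$partition$sizes
  sv <- sizes_vec(sizes)
  genome_bp <- sum(as.numeric(sv))
  peaks <- truth_peaks(truth, mark, cell)
  peak_bp <- interval_bp(peaks)
  n <- params$library_size %||%
    as.integer(round(params$background_rate *
                       (genome_bp - peak_bp + params$enrichment_fold * peak_bp)))
  if (n <= 0) abort("library_size must be > 0")
  w_in <- params$enrichment_fold * peak_bp
  w_out <- genome_bp - peak_bp
  n_in <- rbinom(1, n, w_in / (w_in + w_out))
  # background: uniform over the complement of the planted peaks
  bg <- if (nrow(peaks) == 0) {
    tibble(chrom = sizes$chrom, start = 0L, end = as.integer(sizes$length))
  } else {
    whole <- tibble(chrom = sizes$chrom, start = 0L, end = as.integer(sizes$length))
    gr_to_iv(GenomicRanges::setdiff(iv_to_gr(whole), iv_to_gr(peaks)))
  }
  sample_positions <- function(intervals, k) {
    if (k == 0) {
      return(tibble(chrom = character(), pos = integer()))
    }
    w <- as.numeric(intervals$end - intervals$start)
    rows <- sample.int(nrow(intervals), k, replace = TRUE, prob = w)
    tibble(
      chrom = intervals$chrom[rows],
      pos = intervals$start[rows] +
        as.integer(floor(runif(k) * (intervals$end[rows] - intervals$start[rows])))
    )
  }
  pos <- bind_rows(
    sample_positions(peaks, n_in),
    sample_positions(bg, n - n_in)
  )
  tags <- tibble(
    chrom = pos$chrom,
    start = pos$pos,
    end = pmin(as.integer(sv[pos$chrom]), pos$pos + params$fragment_length),
    strand = sample(c("+", "-"), nrow(pos), replace = TRUE)
  )
  tags <- sort_intervals(tags)
  tag_library(tags, mark = mark, cell_type = cell)
}

#' Simulate a complete two-lineage, two-mark study
#'
#' Convenience wrapper running [generate_genome()], [plant_architecture()]
#' and [generate_tags()] for every (cell type, mark) library.
#'
#' @param params Parameter list from [sim_params()].
#' @return A list: `sizes`, `genes`, `partition`, `truth`, and `tags` — a
#'   nested list `tags[[mark]][[cell]]` of tag tibbles.
#' @export
simulate_study <- function(params = sim_params()) {
  genome <- generate_genome(params)
  truth <- plant_architecture(genome, params)
  marks <- names(params$class_mixture)
  tags <- map(setNames(marks, marks), function(m) {
    map(setNames(params$cell_types, params$cell_types), function(cc) {
      generate_tags(truth, m, cc, params)
    })
  })
  list(sizes = genome$sizes, genes = genome$genes,
       partition = truth$partition, truth = truth, tags = tags,
       params = params)
}
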