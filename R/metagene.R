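# Aggregate tag-density profile over an upstream flank, a length-scaled gene
# body and a downstream flank. Flanks are cut into fixed-width windows
# (125 bp at the defaults: 5 kb / 40), the body into 40 equal-width windows
# per gene, and the per-window density is
#   tags in window (summed over genes) /
#     (library total reads x summed window length over genes),
# i.e. a single pooled ratio per window position.

#' Metagene tag-density profile
#'
#' For each gene, tags are summed in `n_bins` fixed-width windows over
#' `[TSS - flank, TSS)`, `n_bins` equal-width windows over the gene body and
#' `n_bins` windows over `(TES, TES + flank]`; profiles are oriented 5' to 3'
#' (windows of `-` strand genes are reversed) and pooled over genes before
#' normalising, so window position 1 is always the 5'-most upstream window.
#' Density = pooled tag count / (library total reads x pooled window length).
#'
#' Genes shorter than `n_bins` bp are skipped with a warning (their body
#' windows would be under 1 bp). Body window boundaries for lengths not
#' divisible by `n_bins` fall at `round(i * L / n_bins)`, which tiles the
#' body without gaps or overlaps.
#'
#' @param genes Gene model tibble.
#' @param tags Tag tibble; `total_reads` defaults to `nrow(tags)`.
#' @param flank Flank width in bp (default 5000); must be divisible by
#'   `n_bins`.
#' @param n_bins Windows per region (default 40).
#' @param total_reads Library size used for normalisation.
#' @param assign `"overlap"` (default: a tag counts in every window it
#'   overlaps) or `"five_prime"` (a tag counts once, in the window holding
#'   its strand-aware 5' end).
#' @param orient `"stranded"` (default: flip `-` strand genes) or
#'   `"literal"` (genomic left-to-right for all genes).
#' @param average `"pooled"` (default: one ratio from pooled counts and
#'   lengths) or `"per_gene"` (mean of per-gene densities).
#' @return A `metagene_profile` object whose [tidy()] view is a
#'   `3 x n_bins`-row tibble with `region` (upstream/body/downstream), `bin`
#'   (1-based, 5' to 3'), `n_tags`, `window_bp` and `density`.
#' @export
metagene_profile <- function(genes, tags, flank = 5000L, n_bins = 40L,
                             total_reads = NULL,
                             assign = c("overlap", "five_prime"),
                             orient = c("stranded", "literal"),
                             average = c("pooled", "per_gene")) {
  assign <- match.arg(assign)
  orient <- match.arg(orient)
  average <- match.arg(average)
  if (nrow(genes) == 0) abort("empty gene list")
  if (flank %% n_bins != 0) abort("flank must be divisible by n_bins")
  total_reads <- total_reads %||% attr(tags, "total_reads") %||% nrow(tags)
  if (total_reads <= 0) abort("total_reads must be > 0 for normalisation")

  short <- (genes$tx_end - genes$tx_start) < n_bins
  if (any(short)) {
    warn(sprintf("skipping %d gene(s) shorter than %d bp", sum(short), n_bins))
    genes <- genes[!short, , drop = FALSE]
  }
  if (nrow(genes) == 0) abort("no gene is long enough to profile")

  fw <- flank %/% n_bins
  windows <- bind_rows(pmap(
    list(genes$chrom, genes$strand, genes$tx_start, genes$tx_end, seq_len(nrow(genes))),
    function(chrom, strand, s, e, gi) {
      up_b <- s - flank + fw * (0:n_bins) # genomic-left flank boundaries
      body_b <- s + as.integer(round((0:n_bins) * (e - s) / n_bins))
      down_b <- e + fw * (0:n_bins)
      mk <- function(b, region, rev_bins) {
        bins <- seq_len(n_bins)
        if (rev_bins) bins <- rev(bins)
        tibble(chrom = chrom, start = b[-length(b)], end = b[-1],
               region = region, bin = bins, gene_index = gi)
      }
      flip <- strand == "-" && orient == "stranded"
      bind_rows(
        mk(up_b, if (flip) "downstream" else "upstream", flip),
        mk(body_b, "body", flip),
        mk(down_b, if (flip) "upstream" else "downstream", flip)
      )
    }
  ))
  # clip flank windows that run off the chromosome start
  windows <- windows |>
    mutate(start = pmax(.data$start, 0L)) |>
    filter(.data$end > .data$start)

  if (nrow(tags) > 0) {
    if (assign == "overlap") {
      tag_iv <- tags
    } else {
      strand <- if ("strand" %in% names(tags)) tags$strand else rep("+", nrow(tags))
      p5 <- ifelse(strand == "-", tags$end - 1L, tags$start)
      tag_iv <- tibble(chrom = tags$chrom, start = p5, end = p5 + 1L)
    }
    windows$n_tags <- count_overlaps_iv(windows, tag_iv)
  } else {
    windows$n_tags <- 0L
  }
  windows$window_bp <- windows$end - windows$start

  prof <- windows |>
    group_by(.data$region, .data$bin)
  if (average == "pooled") {
    prof <- prof |>
      summarise(n_tags = sum(.data$n_tags), window_bp = sum(.data$window_bp),
                .groups = "drop") |>
      mutate(density = .data$n_tags /
               (as.numeric(total_reads) * as.numeric(.data$window_bp)))
  } else {
    prof <- prof |>
      summarise(
        density = mean(.data$n_tags /
                         (as.numeric(total_reads) * as.numeric(.data$window_bp))),
        n_tags = sum(.data$n_tags), window_bp = sum(.data$window_bp),
        .groups = "drop"
      )
  }
  prof <- prof |>
    mutate(region = factor(.data$region, levels = c("upstream", "body", "downstream"))) |>
    arrange(.data$region, .data$bin) |>
    select("region", "bin", "n_tags", "window_bp", "density")

  structure(
    list(profile = prof, n_genes = nrow(genes), total_reads = total_reads,
         params = list(flank = flank, n_bins = n_bins, assign = assign,
                       orient = orient, average = average)),
    class = "metagene_profile"
  )
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("<metagene_profile> %d genes, %d reads, %d bins/region\n",
              x$n_genes, x$total_reads, x$params$n_bins))
  m <- x$profile[which.max(x$profile$density), ]
  if (nrow(m) == 1) {
    cat(sprintf("  max density %.3g at %s bin %d\n", m$density, m$region, m$bin))
  }
  invisible(x)
}

#' @export
tidy.metagene_profile <- function(x, ...) {
  x$profile
}

#' @export
glance.metagene_profile <- function(x, ...) {
  tibble(
    n_genes = x$n_genes, total_reads = x$total_reads,
    n_bins = x$params$n_bins, flank = x$params$flank,
    max_density = max(x$profile$density),
    max_region = as.character(x$profile$region[which.max(x$profile$density)]),
    max_bin = x$profile$bin[which.max(x$profile$density)]
  )
}
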