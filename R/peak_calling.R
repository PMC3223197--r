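# Simplified local-Poisson enrichment-island caller. Tags are extended to an
# expected fragment length, counted (by fragment midpoint) in step-aligned
# sliding windows, and each window is tested against an upper-tail Poisson
# threshold whose rate is the most conservative of the chromosome-wide rate
# and several local background spans. Significant windows are merged into
# islands. This is deliberately a sound detector, not a re-implementation of
# any published caller: no fragment-shift model, no control library, no
# multiple-testing correction (a raw p-value threshold, as in classic
# sliding-window callers).

#' Upper-tail Poisson probability
#'
#' `P(X >= count)` for `X ~ Poisson(lam)`, computed in log space for
#' numerical stability at extreme counts.
#'
#' @param count Non-negative integer observed count (vectorised).
#' @param lam Positive expected count (vectorised).
#' @param log.p Return the natural log of the tail probability.
#' @return Tail probability (or its log).
#' @examples
#' poisson_tail(3, 1) # 1 - exp(-1) * (1 + 1 + 1/2)
#' @export
poisson_tail <- function(count, lam, log.p = FALSE) {
  if (any(lam <= 0)) abort("lam must be > 0")
  if (any(count < 0)) abort("count must be >= 0")
  stats::ppois(count - 1, lam, lower.tail = FALSE, log.p = log.p)
}

#' Default peak-caller parameters
#'
#' @param window Sliding-window width in bp.
#' @param step Window step in bp (must be <= `window`).
#' @param p_threshold Raw upper-tail Poisson p-value below which a window is
#'   significant.
#' @param merge_gap Significant windows closer than this many bp are merged
#'   into one island.
#' @param min_length Islands shorter than this are discarded.
#' @param min_count Islands with fewer overlapping tags than this are
#'   discarded.
#' @param fragment_length Tags are extended from their 5' end to this length
#'   before counting (sonicated chromatin fragments are a few hundred bp,
#'   so a sequenced tag evidences enrichment over ~200 bp).
#' @param local_lambda_windows Spans (bp) over which local background rates
#'   are estimated; each must exceed `window`, and the smallest span should
#'   comfortably exceed the expected island size — a span that fits inside
#'   an enriched island measures the enrichment itself rather than its
#'   background, which is why callers that lack a control library skip the
#'   1 kb span.
#' @return A named list of parameters for [call_peaks()].
#' @export
peak_caller_params <- function(window = 200L, step = 50L, p_threshold = 1e-5,
                               merge_gap = 200L, min_length = 200L,
                               min_count = 10L, fragment_length = 200L,
                               local_lambda_windows = c(5000L, 10000L)) {
  if (step > window) abort("step must be <= window")
  if (any(local_lambda_windows <= window)) {
    abort("every local background span must exceed the window width")
  }
  list(
    window = as.integer(window), step = as.integer(step),
    p_threshold = p_threshold, merge_gap = as.integer(merge_gap),
    min_length = as.integer(min_length), min_count = as.integer(min_count),
    fragment_length = as.integer(fragment_length),
    local_lambda_windows = as.integer(local_lambda_windows)
  )
}

# Strand-aware 5' extension of tags to fragment_length, clipped to the
# chromosome. Returns chrom/start/end tibble.
extend_tags <- function(tags, sizes, fragment_length) {
  sv <- sizes_vec(sizes)
  strand <- if ("strand" %in% names(tags)) tags$strand else rep("+", nrow(tags))
  fs <- ifelse(strand == "-", tags$end - fragment_length, tags$start)
  fe <- ifelse(strand == "-", tags$end, tags$start + fragment_length)
  tibble(
    chrom = tags$chrom,
    start = pmax(0L, as.integer(fs)),
    end = pmin(as.integer(sv[tags$chrom]), as.integer(fe))
  )
}

# number of sorted values v with w_lo <= v < w_hi, vectorised over windows
count_in <- function(v_sorted, w_lo, w_hi) {
  findInterval(w_hi - 0.5, v_sorted) - findInterval(w_lo - 0.5, v_sorted)
}

#' Call enrichment islands from a tag library
#'
#' Slides half-open, step-aligned windows (anchored at position 0 of each
#' chromosome) across the genome, counts extended-tag fragment midpoints per
#' window, and keeps windows whose count clears the Poisson upper-tail test
#' at `p_threshold` against `lambda_max` — the maximum of the
#' chromosome-wide expected count and local expected counts over the
#' `local_lambda_windows` spans centred on the window. Significant windows
#' within `merge_gap` of each other are merged; islands shorter than
#' `min_length` or holding fewer than `min_count` tags are dropped.
#'
#' Because the background rate is estimated per chromosome, calling on a
#' merged library equals calling per chromosome and concatenating.
#'
#' @param tags Tag tibble (see [read_tags()]).
#' @param sizes Chromosome sizes tibble.
#' @param params Parameter list from [peak_caller_params()].
#' @return A peak tibble: `chrom`, `start`, `end`, `name`, `tag_count`
#'   (tags overlapping the island), `score` (`-log10` of the best window
#'   p-value) and `summit` (midpoint of the densest window).
#' @export
call_peaks <- function(tags, sizes, params = peak_caller_params()) {
  if (nrow(tags) == 0) abort("tag library is empty")
  tags <- validate_intervals(tags, "tags")
  sv <- sizes_vec(sizes)
  unknown <- setdiff(unique(tags$chrom), names(sv))
  if (length(unknown) > 0) {
    abort(sprintf("tags on chromosome(s) absent from sizes: %s",
                  paste(unknown, collapse = ", ")))
  }
  frags <- extend_tags(tags, sizes, params$fragment_length)
  per_chrom <- map(
    sort(unique(frags$chrom)),
    function(ch) call_peaks_chrom(frags[frags$chrom == ch, ], ch, sv[[ch]], params)
  )
  islands <- bind_rows(per_chrom)
  if (nrow(islands) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), tag_count = integer(),
                  score = double(), summit = integer()))
  }
  islands <- sort_intervals(islands)
  # tag_count over the original (un-extended) tags, >=1 bp overlap
  islands$tag_count <- count_overlaps_iv(islands, tags)
  islands <- islands[islands$tag_count >= params$min_count, , drop = FALSE]
  islands$name <- sprintf("peak_%d", seq_len(nrow(islands)))
  islands[, c("chrom", "start", "end", "name", "tag_count", "score", "summit")]
}

call_peaks_chrom <- function(frags, chrom, chrom_len, params) {
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  score = double(), summit = integer())
  if (nrow(frags) == 0) return(empty)
  mids <- sort((frags$start + frags$end) %/% 2L)
  n <- length(mids)
  w <- params$window
  starts <- seq.int(0L, max(0L, chrom_len - 1L), by = params$step)
  ends <- pmin(starts + w, chrom_len)
  counts <- count_in(mids, starts, ends)

  lam <- rep(n * w / chrom_len, length(starts)) # chromosome-wide background
  centers <- (starts + ends) / 2
  for (span in params$local_lambda_windows) {
    lo <- pmax(0, centers - span / 2)
    hi <- pmin(chrom_len, centers + span / 2)
    local_counts <- count_in(mids, lo, hi)
    lam <- pmax(lam, local_counts * w / (hi - lo))
  }
  logp <- poisson_tail(counts, lam, log.p = TRUE)
  sig <- which(logp < log(params$p_threshold) & counts > 0)
  if (length(sig) == 0) return(empty)

  win_gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts[sig] + 1L, ends[sig]))
  isl_gr <- GenomicRanges::reduce(win_gr, min.gapwidth = params$merge_gap + 1L)
  isl <- gr_to_iv(isl_gr)
  keep <- (isl$end - isl$start) >= params$min_length
  isl <- isl[keep, , drop = FALSE]
  if (nrow(isl) == 0) return(empty)

  hits <- GenomicRanges::findOverlaps(GenomicRanges::reduce(win_gr, min.gapwidth = params$merge_gap + 1L)[keep], win_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  best <- vapply(split(sh, qh), function(i) i[which.min(logp[sig][i])], 1L)
  dens <- vapply(split(sh, qh), function(i) i[which.max(counts[sig][i])], 1L)
  isl$score <- -logp[sig][best] / log(10)
  isl$summit <- as.integer((starts[sig][dens] + ends[sig][dens]) %/% 2L)
  isl$chrom <- chrom
  isl[, c("chrom", "start", "end", "score", "summit")]
}
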