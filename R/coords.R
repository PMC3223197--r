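# Coordinate conventions and interval plumbing.
#
# All coordinates inside the package are 0-based half-open [start, end), the
# BED convention. Human-readable "chr:start-end" region strings are 1-based
# inclusive and converted exactly once, at the parse boundary.

#' Validate a tibble of genomic intervals
#'
#' Checks that `x` has `chrom`, `start`, `end` columns with non-empty
#' chromosome names, `start >= 0` and `end > start` (0-based half-open).
#'
#' @param x A data frame of intervals.
#' @param what Label used in error messages.
#' @return `x` as a tibble, invisibly unchanged apart from tibble coercion.
#' @export
validate_intervals <- function(x, what = "intervals") {
  if (!is.data.frame(x)) {
    abort(sprintf("%s must be a data frame", what))
  }
  x <- as_tibble(x)
  missing_cols <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s lacks column(s): %s", what, paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) {
    return(x)
  }
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    abort(sprintf("%s has empty chromosome names", what))
  }
  if (any(is.na(x$start)) || any(is.na(x$end))) {
    abort(sprintf("%s has missing coordinates", what))
  }
  if (any(x$start < 0)) {
    abort(sprintf("%s: negative start at row %d", what, which(x$start < 0)[1]))
  }
  bad <- which(x$end <= x$start)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: end <= start at row %d (%s:%d-%d); coordinates are 0-based half-open",
      what, bad[1], x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]
    ))
  }
  x
}

#' Parse a 1-based inclusive region string
#'
#' Region strings such as `"chrX:49001620-49002192"` (1-based inclusive, the
#' convention of genome browsers and publications) are converted to the
#' package's 0-based half-open representation: `[A-1, B)`. Commas and en
#' dashes are tolerated.
#'
#' @param x Character vector of region strings.
#' @return A tibble with `chrom`, `start`, `end` (0-based half-open).
#' @examples
#' parse_region("chrX:49001620-49002192")
#' @export
parse_region <- function(x) {
  x <- gsub(",", "", x)
  x <- gsub("–", "-", x) # en dash
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))
  bad <- which(vapply(m, length, 1L) != 4L)
  if (length(bad) > 0) {
    abort(sprintf("cannot parse region string: '%s'", x[bad[1]]))
  }
  out <- tibble(
    chrom = map_chr(m, 2),
    start = as.integer(map_chr(m, 3)) - 1L,
    end = as.integer(map_chr(m, 4))
  )
  validate_intervals(out, "region")
}

# Convert an interval tibble to GRanges (half-open 0-based -> 1-based closed).
iv_to_gr <- function(x, sizes = NULL) {
  sl <- NULL
  if (!is.null(sizes)) sl <- sizes_vec(sizes)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    seqlengths = sl
  )
}

# Convert GRanges back to a half-open interval tibble.
gr_to_iv <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

# Pairwise overlap operations on interval tibbles. Both sides are lifted
# onto the union of their chromosome sets so disjoint chromosome names are a
# plain "no overlap", not a Seqinfo mismatch.
iv_pair_gr <- function(x, y) {
  lev <- union(unique(x$chrom), unique(y$chrom))
  mk <- function(z) {
    GenomicRanges::GRanges(
      seqnames = factor(z$chrom, levels = lev),
      ranges = IRanges::IRanges(start = z$start + 1L, end = z$end)
    )
  }
  list(x = mk(x), y = mk(y))
}

find_overlaps_iv <- function(x, y) {
  g <- iv_pair_gr(x, y)
  GenomicRanges::findOverlaps(g$x, g$y)
}

overlaps_any_iv <- function(x, y) {
  g <- iv_pair_gr(x, y)
  IRanges::overlapsAny(g$x, g$y)
}

count_overlaps_iv <- function(x, y) {
  g <- iv_pair_gr(x, y)
  GenomicRanges::countOverlaps(g$x, g$y)
}

# Named integer vector chrom -> length from a chrom-sizes tibble.
sizes_vec <- function(sizes) {
  stats::setNames(as.integer(sizes$length), sizes$chrom)
}

# Merge overlapping/bookended intervals within a tibble; sorted output.
merge_intervals <- function(x) {
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end")])
  gr_to_iv(GenomicRanges::reduce(iv_to_gr(x)))
}

# Deterministic sort by chromosome then start then end.
sort_intervals <- function(x) {
  arrange(x, .data$chrom, .data$start, .data$end)
}

# Total bp covered (intervals assumed disjoint).
interval_bp <- function(x) {
  if (nrow(x) == 0) return(0)
  sum(as.numeric(x$end - x$start))
}

# Check that every interval lies within chromosome bounds.
check_in_bounds <- function(x, sizes, what = "interval") {
  sv <- sizes_vec(sizes)
  unknown <- setdiff(unique(x$chrom), names(sv))
  if (length(unknown) > 0) {
    abort(sprintf("%s on unknown chromosome(s): %s", what, paste(unknown, collapse = ", ")))
  }
  over <- which(x$end > sv[x$chrom])
  if (length(over) > 0) {
    abort(sprintf(
      "%s exceeds chromosome bounds at row %d (%s:%d-%d)",
      what, over[1], x$chrom[over[1]], x$start[over[1]], x$end[over[1]]
    ))
  }
  invisible(x)
}
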