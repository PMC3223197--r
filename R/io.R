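# Readers and writers for the plain-text genomic formats the pipeline touches:
# refFlat / BED12 gene annotation, BED3-6 tag libraries, BED5 peak sets,
# two-column chrom.sizes, and TSV/JSON reports.

read_lines_nocomment <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  list(lines = lines[keep], lineno = which(keep))
}

split_fields <- function(lines) {
  strsplit(lines, "[ \t]+")
}

parse_int_field <- function(x, lineno, field) {
  suppressWarnings(v <- as.integer(x))
  bad <- which(is.na(v))
  if (length(bad) > 0) {
    abort(sprintf("line %d: field '%s' is not an integer ('%s')", lineno[bad[1]], field, x[bad[1]]))
  }
  v
}

parse_num_list <- function(x, lineno, field) {
  map2(x, lineno, function(s, ln) {
    parts <- strsplit(sub(",$", "", s), ",")[[1]]
    suppressWarnings(v <- as.integer(parts))
    if (any(is.na(v))) abort(sprintf("line %d: cannot parse '%s' list", ln, field))
    v
  })
}

#' Read a gene annotation table
#'
#' Parses transcript models from either a UCSC refFlat table (columns
#' geneName, name, chrom, strand, txStart, txEnd, cdsStart, cdsEnd,
#' exonCount, exonStarts, exonEnds) or a BED12 file. refFlat is the primary
#' dialect because it carries txStart/txEnd/exon blocks directly; BED12 block
#' arithmetic (`chromStart + blockStarts`) is applied for the alternative.
#' Several comma-separated symbols in the refFlat geneName column are kept as
#' a list of symbols for the transcript.
#'
#' @param path Path to the annotation file.
#' @param dialect `"refflat"` (default) or `"bed12"`.
#' @return A tibble of gene models, one row per transcript: `tx_id`,
#'   `gene_symbols` (list column), `chrom`, `strand`, `tx_start`, `tx_end`
#'   (0-based half-open), `exon_starts`, `exon_ends` (list columns).
#' @export
read_gene_annotation <- function(path, dialect = c("refflat", "bed12")) {
  dialect <- match.arg(dialect)
  lc <- read_lines_nocomment(path)
  empty <- tibble(
    tx_id = character(), gene_symbols = list(), chrom = character(),
    strand = character(), tx_start = integer(), tx_end = integer(),
    exon_starts = list(), exon_ends = list()
  )
  if (length(lc$lines) == 0) return(empty)
  f <- split_fields(lc$lines)
  n_min <- if (dialect == "refflat") 11L else 12L
  short <- which(vapply(f, length, 1L) < n_min)
  if (length(short) > 0) {
    abort(sprintf("line %d: expected >= %d fields for %s", lc$lineno[short[1]], n_min, dialect))
  }
  col <- function(i) vapply(f, `[[`, "", i)
  if (dialect == "refflat") {
    genes <- tibble(
      tx_id = col(2),
      gene_symbols = map(strsplit(col(1), ","), unique),
      chrom = col(3),
      strand = col(4),
      tx_start = parse_int_field(col(5), lc$lineno, "txStart"),
      tx_end = parse_int_field(col(6), lc$lineno, "txEnd"),
      exon_starts = parse_num_list(col(10), lc$lineno, "exonStarts"),
      exon_ends = parse_num_list(col(11), lc$lineno, "exonEnds")
    )
    n_exons <- parse_int_field(col(9), lc$lineno, "exonCount")
  } else {
    chrom_start <- parse_int_field(col(2), lc$lineno, "chromStart")
    sizes_l <- parse_num_list(col(11), lc$lineno, "blockSizes")
    starts_l <- parse_num_list(col(12), lc$lineno, "blockStarts")
    genes <- tibble(
      tx_id = col(4),
      gene_symbols = map(col(4), identity),
      chrom = col(1),
      strand = col(6),
      tx_start = chrom_start,
      tx_end = parse_int_field(col(3), lc$lineno, "chromEnd"),
      exon_starts = map2(starts_l, chrom_start, `+`),
      exon_ends = pmap(list(starts_l, sizes_l, chrom_start), function(s, w, c0) c0 + s + w)
    )
    n_exons <- parse_int_field(col(10), lc$lineno, "blockCount")
  }
  mismatch <- which(
    lengths(genes$exon_starts) != n_exons | lengths(genes$exon_ends) != n_exons
  )
  if (length(mismatch) > 0) {
    abort(sprintf("line %d: exon count does not match exon block lists", lc$lineno[mismatch[1]]))
  }
  validate_gene_models(genes, lc$lineno)
  genes
}

validate_gene_models <- function(genes, lineno = seq_len(nrow(genes))) {
  for (i in seq_len(nrow(genes))) {
    s <- genes$exon_starts[[i]]
    e <- genes$exon_ends[[i]]
    ok <- genes$tx_end[i] > genes$tx_start[i] &&
      genes$strand[i] %in% c("+", "-") &&
      all(e > s) &&
      !is.unsorted(s, strictly = TRUE) &&
      all(s[-1] >= e[-length(e)]) && # pairwise disjoint
      s[1] >= genes$tx_start[i] && e[length(e)] <= genes$tx_end[i]
    if (!ok) {
      abort(sprintf("line %d: invalid gene model '%s'", lineno[i], genes$tx_id[i]))
    }
  }
  invisible(genes)
}

#' Write gene models as refFlat
#'
#' Inverse of [read_gene_annotation()] for the refFlat dialect; rows are
#' sorted by chromosome then txStart so output is deterministic.
#'
#' @param genes Gene model tibble as returned by [read_gene_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  genes <- arrange(genes, .data$chrom, .data$tx_start, .data$tx_id)
  lines <- pmap(genes, function(tx_id, gene_symbols, chrom, strand, tx_start, tx_end,
                                 exon_starts, exon_ends, ...) {
    paste(
      paste(gene_symbols, collapse = ","), tx_id, chrom, strand,
      tx_start, tx_end, tx_start, tx_end, length(exon_starts),
      paste0(paste(exon_starts, collapse = ","), ","),
      paste0(paste(exon_ends, collapse = ","), ","),
      sep = "\t"
    )
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read a tag library from a BED file
#'
#' Mapped sequencing tags as BED3+ intervals; the strand column (field 6) is
#' used when present and defaults to `"+"` otherwise. `total_reads` (the line
#' count) is attached as an attribute and equals `nrow()`.
#'
#' @param path Path to a BED file of mapped tags.
#' @param mark,cell_type Optional labels attached as attributes.
#' @return A tibble with `chrom`, `start`, `end`, `strand`.
#' @export
read_tags <- function(path, mark = NULL, cell_type = NULL) {
  lc <- read_lines_nocomment(path)
  if (length(lc$lines) == 0) {
    tags <- tibble(chrom = character(), start = integer(), end = integer(), strand = character())
  } else {
    f <- split_fields(lc$lines)
    nf <- vapply(f, length, 1L)
    if (any(nf < 3)) {
      abort(sprintf("line %d: BED requires >= 3 fields", lc$lineno[which(nf < 3)[1]]))
    }
    strand <- ifelse(nf >= 6, vapply(f, function(x) x[min(6L, length(x))], ""), "+")
    strand[!strand %in% c("+", "-")] <- "+"
    tags <- tibble(
      chrom = vapply(f, `[[`, "", 1),
      start = parse_int_field(vapply(f, `[[`, "", 2), lc$lineno, "start"),
      end = parse_int_field(vapply(f, `[[`, "", 3), lc$lineno, "end"),
      strand = strand
    )
    bad <- which(tags$end <= tags$start)
    if (length(bad) > 0) {
      abort(sprintf("line %d: end <= start", lc$lineno[bad[1]]))
    }
  }
  tags <- sort_intervals(tags)
  tag_library(tags, mark = mark, cell_type = cell_type)
}

#' Label a tibble of tags as a tag library
#'
#' @param tags Interval tibble with optional `strand` column.
#' @param mark,cell_type Optional labels (e.g. `"H3K4me3"`, `"Treg"`).
#' @return The validated tibble with `mark`, `cell_type` and `total_reads`
#'   attributes.
#' @export
tag_library <- function(tags, mark = NULL, cell_type = NULL) {
  tags <- validate_intervals(tags, "tags")
  if (!"strand" %in% names(tags)) tags$strand <- "+"
  attr(tags, "mark") <- mark
  attr(tags, "cell_type") <- cell_type
  attr(tags, "total_reads") <- nrow(tags)
  tags
}

#' Write a tag library as BED6
#'
#' @param tags Tag tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tags <- function(tags, path) {
  tags <- sort_intervals(tags)
  strand <- if ("strand" %in% names(tags)) tags$strand else rep("+", nrow(tags))
  writeLines(
    sprintf("%s\t%d\t%d\ttag_%d\t0\t%s", tags$chrom, tags$start, tags$end,
            seq_len(nrow(tags)), strand),
    path
  )
  invisible(path)
}

#' Read peaks from a BED file
#'
#' BED3+ where field 4 is the peak name and field 5, when present, holds the
#' peak tag count (UCSC score slot). Peaks without a count column get
#' `tag_count = 0`.
#'
#' @param path Path to a BED file of peaks.
#' @return A tibble with `chrom`, `start`, `end`, `name`, `tag_count`.
#' @export
read_peaks <- function(path) {
  lc <- read_lines_nocomment(path)
  if (length(lc$lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), tag_count = integer()))
  }
  f <- split_fields(lc$lines)
  nf <- vapply(f, length, 1L)
  if (any(nf < 3)) {
    abort(sprintf("line %d: BED requires >= 3 fields", lc$lineno[which(nf < 3)[1]]))
  }
  peaks <- tibble(
    chrom = vapply(f, `[[`, "", 1),
    start = parse_int_field(vapply(f, `[[`, "", 2), lc$lineno, "start"),
    end = parse_int_field(vapply(f, `[[`, "", 3), lc$lineno, "end"),
    name = ifelse(nf >= 4, vapply(f, function(x) x[min(4L, length(x))], ""), NA_character_),
    tag_count = ifelse(
      nf >= 5,
      parse_int_field(vapply(f, function(x) if (length(x) >= 5) x[[5]] else "0", ""),
                      lc$lineno, "score"),
      0L
    )
  )
  bad <- which(peaks$end <= peaks$start)
  if (length(bad) > 0) abort(sprintf("line %d: end <= start", lc$lineno[bad[1]]))
  peaks$name[is.na(peaks$name)] <- sprintf("peak_%d", which(is.na(peaks$name)))
  sort_intervals(peaks)
}

#' Write peaks as BED5
#'
#' Score field carries the peak tag count so that
#' `read_peaks(write_peaks(x))` round-trips coordinates and counts.
#'
#' @param peaks Peak tibble (needs `chrom`, `start`, `end`; `name` and
#'   `tag_count` are filled in when absent).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  peaks <- validate_intervals(peaks, "peaks")
  peaks <- sort_intervals(peaks)
  if (!"name" %in% names(peaks)) peaks$name <- sprintf("peak_%d", seq_len(nrow(peaks)))
  if (!"tag_count" %in% names(peaks)) peaks$tag_count <- 0L
  writeLines(
    sprintf("%s\t%d\t%d\t%s\t%d", peaks$chrom, peaks$start, peaks$end,
            peaks$name, as.integer(peaks$tag_count)),
    path
  )
  invisible(path)
}

#' Read / write chromosome sizes
#'
#' Standard two-column `chrom.sizes` text (name, length).
#'
#' @param path Path to the file.
#' @return A tibble with `chrom` and `length`.
#' @export
read_chrom_sizes <- function(path) {
  lc <- read_lines_nocomment(path)
  f <- split_fields(lc$lines)
  sizes <- tibble(
    chrom = vapply(f, `[[`, "", 1),
    length = parse_int_field(vapply(f, `[[`, "", 2), lc$lineno, "length")
  )
  if (any(sizes$length <= 0)) abort("chromosome lengths must be positive")
  arrange(sizes, .data$chrom)
}

#' @rdname read_chrom_sizes
#' @param sizes Chromosome sizes tibble.
#' @export
write_chrom_sizes <- function(sizes, path) {
  sizes <- arrange(sizes, .data$chrom)
  writeLines(sprintf("%s\t%d", sizes$chrom, as.integer(sizes$length)), path)
  invisible(path)
}

#' Write an analysis report to disk
#'
#' Writes any of the package's report objects (distribution reports, peak
#' comparisons, gene Venn partitions, metagene profiles, enrichment tables or
#' plain tibbles) as TSV or JSON with deterministic row and key order, so
#' identical inputs give byte-identical files.
#'
#' @param report A report object or tibble.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  x <- report_payload(report, format)
  if (format == "tsv") {
    readr::write_tsv(x, path, progress = FALSE)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

report_payload <- function(report, format) {
  if (inherits(report, "peak_comparison")) {
    if (format == "json") return(as.list(glance(report))) # scalar JSON keys
    return(tidy(report))
  }
  if (inherits(report, "gene_venn")) {
    if (format == "json") {
      return(list(
        n_common = length(report$common),
        n_specific_a = length(report$specific_a),
        n_specific_b = length(report$specific_b),
        common = sort(report$common),
        specific_a = sort(report$specific_a),
        specific_b = sort(report$specific_b)
      ))
    }
    return(tidy(report))
  }
  if (inherits(report, "metagene_profile")) return(tidy(report))
  if (is.data.frame(report)) {
    x <- as_tibble(report)
    x[] <- lapply(x, function(col) {
      if (is.list(col)) vapply(col, paste, "", collapse = ",") else col
    })
    if (all(c("chrom", "start") %in% names(x))) x <- sort_intervals(x)
    return(x)
  }
  if (is.list(report)) return(report)
  abort("unsupported report type")
}
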