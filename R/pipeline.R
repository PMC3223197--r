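# End-to-end orchestration: simulate or load inputs, call (or consume)
# peaks per cell type and mark, then produce every report the comparative
# analysis defines — genomic distribution, metagene profiles, common vs
# lineage-specific partitions, promoter enrichment with cross-lineage
# correlation, gene Venn, and within-cell cross-mark overlap. All report
# files are deterministic functions of (inputs, config, seed).

#' Default pipeline configuration
#'
#' A configuration is a plain named list (loadable from YAML via
#' [read_pipeline_config()]). With `simulate = TRUE` inputs come from
#' [simulate_study()]; otherwise `annotation`, `chrom_sizes` and a `tags`
#' map `tags[[mark]][[cell]] = path` must point at existing files.
#' Pre-called peaks can be supplied per library via `peaks[[mark]][[cell]]`
#' together with `skip_calling = TRUE`.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed; the single source of randomness.
#' @param simulate Use the synthetic-data generator for inputs.
#' @param sim Parameter overrides passed to [sim_params()].
#' @param promoter_halfwidth Promoter half-width (bp).
#' @param caller Overrides passed to [peak_caller_params()].
#' @param correlation_method,log2_ratios,cpm Flags forwarded to
#'   [enrichment_correlation()] and [promoter_mark_table()].
#' @param assignment_mode Peak-to-class mode for [distribution_report()].
#' @param skip_calling Consume external peaks instead of calling.
#' @param annotation,chrom_sizes,tags,peaks Input paths (non-simulated runs).
#' @return A config list for [run_pipeline()].
#' @export
pipeline_config <- function(out_dir = "histmark_out", seed = 1L,
                            simulate = TRUE, sim = list(),
                            promoter_halfwidth = 1000L, caller = list(),
                            correlation_method = "pearson",
                            log2_ratios = FALSE, cpm = FALSE,
                            assignment_mode = "precedence",
                            skip_calling = FALSE,
                            annotation = NULL, chrom_sizes = NULL,
                            tags = NULL, peaks = NULL) {
  list(
    out_dir = out_dir, seed = as.integer(seed), simulate = simulate, sim = sim,
    promoter_halfwidth = as.integer(promoter_halfwidth), caller = caller,
    correlation_method = correlation_method, log2_ratios = log2_ratios,
    cpm = cpm, assignment_mode = assignment_mode, skip_calling = skip_calling,
    annotation = annotation, chrom_sizes = chrom_sizes,
    tags = tags, peaks = peaks
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A config list with defaults applied.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

validate_pipeline_inputs <- function(config) {
  if (isTRUE(config$simulate)) return(invisible(config))
  problems <- character()
  need <- function(path, what) {
    if (is.null(path)) {
      problems <<- c(problems, sprintf("missing config entry: %s", what))
    } else if (!file.exists(path)) {
      problems <<- c(problems, sprintf("%s not found: %s", what, path))
    }
  }
  need(config$annotation, "annotation")
  need(config$chrom_sizes, "chrom_sizes")
  if (is.null(config$tags)) {
    problems <- c(problems, "missing config entry: tags")
  } else {
    for (m in names(config$tags)) {
      for (cc in names(config$tags[[m]])) {
        need(config$tags[[m]][[cc]], sprintf("tags[%s][%s]", m, cc))
      }
    }
  }
  if (isTRUE(config$skip_calling)) {
    if (is.null(config$peaks)) {
      problems <- c(problems, "skip_calling requires a peaks map")
    } else {
      for (m in names(config$peaks)) {
        for (cc in names(config$peaks[[m]])) {
          need(config$peaks[[m]][[cc]], sprintf("peaks[%s][%s]", m, cc))
        }
      }
    }
  }
  if (length(problems) > 0) {
    abort(paste(c("invalid pipeline inputs:", problems), collapse = "\n  "))
  }
  invisible(config)
}

#' Run the full comparative pipeline
#'
#' Validates inputs up front (aggregating every missing path into one
#' error), then runs all stages and writes, per mark: peak BED5 + TSV per
#' cell type, a genomic-distribution TSV per cell type, a metagene-profile
#' TSV per cell type, common/specific BEDs with a JSON comparison summary, a
#' promoter enrichment TSV with its cross-lineage correlation, and a gene
#' Venn JSON; plus a cross-mark comparison JSON per cell type and a
#' `manifest.json` (package version, seed, config echo). Per-stage timings
#' go to `run.log` and stderr; report files contain no timestamps, so
#' identical configs and seeds give byte-identical reports.
#'
#' @param config Config list from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @return Invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_pipeline_inputs(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  t0 <- Sys.time()
  stage <- function(msg) {
    line <- sprintf("[%6.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"), msg)
    inform(line)
    writeLines(line, log_con)
  }

  out <- function(...) file.path(config$out_dir, sprintf(...))

  stage("loading inputs")
  if (isTRUE(config$simulate)) {
    sim_args <- config$sim
    sim_args$seed <- sim_args$seed %||% config$seed
    params <- do.call(sim_params, sim_args)
    study <- simulate_study(params)
    sizes <- study$sizes
    genes <- study$genes
    tag_libs <- study$tags
    write_chrom_sizes(sizes, out("genome.chrom.sizes"))
    write_gene_annotation(genes, out("genes.refflat"))
    write_report(study$truth$peaks |> mutate(region_class = as.character(.data$region_class)),
                 out("planted_truth.tsv"), "tsv")
    for (m in names(tag_libs)) {
      for (cc in names(tag_libs[[m]])) {
        write_tags(tag_libs[[m]][[cc]], out("tags_%s_%s.bed", m, cc))
      }
    }
  } else {
    sizes <- read_chrom_sizes(config$chrom_sizes)
    genes <- read_gene_annotation(config$annotation)
    study <- NULL
    tag_libs <- map(config$tags, function(cells) {
      imap(cells, function(path, cc) read_tags(path, cell_type = cc))
    })
  }
  marks <- names(tag_libs)
  cells <- names(tag_libs[[1]])

  stage("building genome partition")
  partition <- if (!is.null(study)) study$partition else {
    build_partition(genes, sizes, config$promoter_halfwidth)
  }

  caller_params <- do.call(peak_caller_params, config$caller)
  peak_sets <- map(setNames(marks, marks), function(m) {
    map(setNames(cells, cells), function(cc) {
      if (isTRUE(config$skip_calling)) {
        stage(sprintf("reading external peaks %s / %s", m, cc))
        read_peaks(config$peaks[[m]][[cc]])
      } else {
        stage(sprintf("calling peaks %s / %s", m, cc))
        call_peaks(tag_libs[[m]][[cc]], sizes, caller_params)
      }
    })
  })

  distributions <- list()
  profiles <- list()
  for (m in marks) {
    for (cc in cells) {
      pk <- peak_sets[[m]][[cc]]
      write_peaks(pk, out("peaks_%s_%s.bed", m, cc))
      write_report(pk, out("peaks_%s_%s.tsv", m, cc), "tsv")
      stage(sprintf("distribution + metagene %s / %s", m, cc))
      dist <- distribution_report(partition, pk, mode = config$assignment_mode)
      distributions[[m]][[cc]] <- dist
      write_report(as_tibble(dist), out("distribution_%s_%s.tsv", m, cc), "tsv")
      prof <- metagene_profile(genes, tag_libs[[m]][[cc]])
      profiles[[m]][[cc]] <- prof
      write_report(prof, out("metagene_%s_%s.tsv", m, cc), "tsv")
    }
  }

  comparisons <- list()
  enrichment <- list()
  correlations <- list()
  venns <- list()
  for (m in marks) {
    stage(sprintf("comparing lineages for %s", m))
    cmp <- compare_peak_sets(peak_sets[[m]][[cells[1]]], peak_sets[[m]][[cells[2]]],
                             labels = cells)
    comparisons[[m]] <- cmp
    write_peaks(common_peaks(cmp, "a"), out("common_%s_%s.bed", m, cells[1]))
    write_peaks(common_peaks(cmp, "b"), out("common_%s_%s.bed", m, cells[2]))
    write_peaks(specific_peaks(cmp, "a"), out("specific_%s_%s.bed", m, cells[1]))
    write_peaks(specific_peaks(cmp, "b"), out("specific_%s_%s.bed", m, cells[2]))
    write_report(cmp, out("comparison_%s.json", m), "json")

    records <- promoter_mark_table(
      partition, peak_sets[[m]][[cells[1]]], peak_sets[[m]][[cells[2]]],
      tag_libs[[m]][[cells[1]]], tag_libs[[m]][[cells[2]]],
      cpm = config$cpm
    )
    enrichment[[m]] <- records
    write_report(records, out("promoter_enrichment_%s.tsv", m), "tsv")
    correlations[[m]] <- tryCatch(
      enrichment_correlation(records, method = config$correlation_method,
                             log2_transform = config$log2_ratios),
      error = function(e) {
        # degenerate table (too few marked promoters / no variance): report NA
        inform(sprintf("correlation undefined for %s: %s", m, conditionMessage(e)))
        tibble(method = config$correlation_method, estimate = NA_real_,
               n = nrow(records))
      }
    )
    venn <- gene_venn(
      marked_promoters(partition, peak_sets[[m]][[cells[1]]]),
      marked_promoters(partition, peak_sets[[m]][[cells[2]]]),
      labels = cells
    )
    venns[[m]] <- venn
    write_report(venn, out("gene_venn_%s.json", m), "json")
  }
  write_report(bind_rows(correlations, .id = "mark"), out("correlations.tsv"), "tsv")

  cross_mark <- list()
  if (length(marks) >= 2) {
    for (cc in cells) {
      stage(sprintf("cross-mark comparison in %s", cc))
      xm <- cross_mark_comparison(peak_sets[[marks[1]]][[cc]],
                                  peak_sets[[marks[2]]][[cc]],
                                  labels = marks[1:2])
      cross_mark[[cc]] <- xm
      write_report(xm, out("cross_mark_%s.json", cc), "json")
    }
  }

  manifest <- list(
    package = "histmarkr",
    version = as.character(utils::packageVersion("histmarkr")),
    seed = config$seed,
    config = config[!vapply(config, is.null, TRUE)]
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  stage("done")

  invisible(list(
    partition = partition, peaks = peak_sets, distributions = distributions,
    profiles = profiles, comparisons = comparisons, enrichment = enrichment,
    correlations = correlations, venns = venns, cross_mark = cross_mark,
    truth = if (!is.null(study)) study$truth else NULL,
    out_dir = config$out_dir
  ))
}
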