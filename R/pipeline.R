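#' Assemble a run configuration
#'
#' A run configuration names the inputs (library TSV, sample sheet, and
#' either a counts TSV or a directory of `<sample>.fastq` files) plus every
#' stage parameter of the pipeline. Unknown keys are rejected so typos
#' fail loudly. Configurations can be written/read as YAML; the fully
#' resolved configuration is written next to every run's outputs.
#'
#' @param library Path of the library TSV.
#' @param sample_sheet Path of the sample sheet TSV.
#' @param counts Path of a counts TSV (skips the counting stage), or NULL.
#' @param fastq_dir Directory holding `<sample>.fastq` files, or NULL.
#' @param out_dir Output directory.
#' @param adapter,max_mismatch,min_mean_quality,revcomp Counting-stage
#'   parameters; see [count_reads()].
#' @param normalization,fixed_dispersion Testing-stage parameters; see
#'   [test_hairpins()] (`fixed_dispersion = NULL` estimates from data).
#' @param filter_unannotated,filter_medc_maxt,min_total Filter switches.
#' @param combine,weighting Collapse-stage parameters; see
#'   [collapse_genes()].
#' @param alpha Hit-calling threshold; see [call_hits()].
#' @param seed Integer seed recorded with the run.
#' @return A `run_config` object (validated named list).
#' @export
run_config <- function(library, sample_sheet, counts = NULL,
                       fastq_dir = NULL, out_dir = "slicscreen_run",
                       adapter = default_adapter(), max_mismatch = 0L,
                       min_mean_quality = 20, revcomp = FALSE,
                       normalization = "median_ratio",
                       fixed_dispersion = NULL,
                       filter_unannotated = TRUE, filter_medc_maxt = TRUE,
                       min_total = NULL,
                       combine = "p", weighting = "equal",
                       alpha = 0.05, seed = 1L, ...) {
  extra <- list(...)
  if (length(extra) > 0)
    abort(paste0("unknown configuration key(s): ",
                 paste(names(extra), collapse = ", ")))
  cfg <- list(library = library, sample_sheet = sample_sheet,
              counts = counts, fastq_dir = fastq_dir, out_dir = out_dir,
              adapter = adapter, max_mismatch = as.integer(max_mismatch),
              min_mean_quality = min_mean_quality, revcomp = revcomp,
              normalization = normalization,
              fixed_dispersion = fixed_dispersion,
              filter_unannotated = filter_unannotated,
              filter_medc_maxt = filter_medc_maxt, min_total = min_total,
              combine = combine, weighting = weighting,
              alpha = alpha, seed = as.integer(seed))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

run_config_keys <- function() setdiff(names(formals(run_config)), "...")

validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), run_config_keys())
  if (length(unknown) > 0)
    abort(paste0("unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")))
  if (is.null(cfg$counts) && is.null(cfg$fastq_dir))
    abort("configuration needs either 'counts' or 'fastq_dir'")
  stopifnot(cfg$combine %in% c("p", "q"),
            cfg$weighting %in% c("equal", "sqrt_mean_count"),
            cfg$normalization %in% c("median_ratio", "total"),
            cfg$alpha > 0, cfg$alpha <= 1)
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' Missing keys take the [run_config()] defaults; unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), run_config_keys())
  if (length(unknown) > 0)
    abort(paste0("unknown configuration key(s) in ", path, ": ",
                 paste(unknown, collapse = ", ")))
  do.call(run_config, vals)
}

#' Run the full screen-analysis pipeline
#'
#' Executes the stages of a pooled dropout screen analysis on one or more
#' screens (screens are distinguished by `screen_id` in the sample sheet):
#' hairpin counting from FASTQ (skipped when a counts TSV is supplied),
#' per-hairpin differential representation with filters
#' ([test_hairpins()]), gene collapse ([collapse_genes()]), hit calling
#' ([call_hits()]) and, when at least two screens are present, cross-screen
#' intersection ([intersect_screens()]). Every intermediate table is
#' written as TSV under `out_dir`, together with the resolved
#' configuration (YAML) and a run log; identical configuration and inputs
#' reproduce byte-identical TSVs.
#'
#' @param config A `run_config`, or the path of a YAML configuration.
#' @return Invisibly, a list with the in-memory results (`counts`,
#'   `report`, per-screen `stats`, `genes`, `hits`, `common`) and `paths`
#'   of everything written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  log_path <- file.path(out, "run.log")
  cat(sprintf("slicscreen %s | R %s | seed %d\n",
              as.character(utils::packageVersion("slicscreen")),
              paste(R.version$major, R.version$minor, sep = "."),
              config$seed),
      file = log_path)
  log_line <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e))))
    log_line("stage %-10s %.2fs", name, proc.time()[["elapsed"]] - t0)
    res
  }

  inputs <- stage("inputs", {
    for (p in c(config$library, config$sample_sheet, config$counts))
      if (!is.null(p) && !file.exists(p))
        abort(paste0("input file not found: ", p))
    list(library = read_library(config$library),
         samples = read_sample_sheet(config$sample_sheet))
  })
  library <- inputs$library
  samples <- inputs$samples
  if (!"screen_id" %in% names(samples)) samples$screen_id <- "screen1"

  report <- NULL
  if (!is.null(config$counts)) {
    counts <- stage("read_counts", read_counts(config$counts))
  } else {
    cr <- stage("count", {
      files <- setNames(file.path(config$fastq_dir,
                                  paste0(samples$sample, ".fastq")),
                        samples$sample)
      cr <- count_reads(files, library, adapter = config$adapter,
                        max_mismatch = config$max_mismatch,
                        min_mean_quality = config$min_mean_quality,
                        revcomp = config$revcomp)
      write_counts(cr$counts, file.path(out, "counts.tsv"))
      readr::write_tsv(cr$report, file.path(out, "mapping_report.tsv"),
                       progress = FALSE)
      cr
    })
    counts <- cr$counts
    report <- cr$report
  }

  screens <- unique(samples$screen_id)
  per_screen <- lapply(screens, function(sid) {
    sub_samples <- samples[samples$screen_id == sid, , drop = FALSE]
    sub_counts <- counts[, c("hairpin_id", sub_samples$sample)]
    st <- stage(paste0("test:", sid),
      test_hairpins(sub_counts, sub_samples, library,
                    dispersion = config$fixed_dispersion,
                    normalization = config$normalization,
                    filter_unann = config$filter_unannotated,
                    filter_consistency = config$filter_medc_maxt,
                    min_total = config$min_total))
    readr::write_tsv(dplyr::arrange(tibble::as_tibble(st), .data$hairpin_id),
                     file.path(out, paste0("hairpin_stats_", sid, ".tsv")),
                     progress = FALSE)
    gn <- stage(paste0("collapse:", sid),
      collapse_genes(st, mode = config$combine,
                     weighting = config$weighting))
    readr::write_tsv(tibble::as_tibble(gn),
                     file.path(out, paste0("gene_results_", sid, ".tsv")),
                     progress = FALSE)
    ht <- stage(paste0("call:", sid),
                call_hits(gn, alpha = config$alpha, screen_id = sid))
    readr::write_tsv(tibble::as_tibble(ht),
                     file.path(out, paste0("hits_", sid, ".tsv")),
                     progress = FALSE)
    list(stats = st, genes = gn, hits = ht)
  })
  names(per_screen) <- screens

  common <- NULL
  if (length(screens) >= 2) {
    common <- stage("intersect",
                    intersect_screens(lapply(per_screen, `[[`, "hits")))
    readr::write_tsv(common, file.path(out, "common_hits.tsv"),
                     progress = FALSE)
  }

  resolved <- unclass(config)
  resolved <- resolved[!vapply(resolved, is.null, TRUE)]
  yaml::write_yaml(resolved, file.path(out, "config.yaml"))
  log_line("done: %d screen(s), output in %s", length(screens), out)

  invisible(list(counts = counts, report = report, screens = per_screen,
                 common = common,
                 paths = list(out_dir = out, config = file.path(out, "config.yaml"),
                              log = log_path)))
}

#' Validate pipeline inputs
#'
#' Cross-checks the structural invariants of a library, sample sheet and
#' count table: unique hairpin ids and guides, uniform guide length,
#' non-empty gene labels, unique sample ids, valid arm labels,
#' non-negative integer counts, and agreement between the count rows /
#' columns and the library / sample sheet.
#'
#' @param library Library tibble (or path of a library TSV).
#' @param samples Optional sample sheet tibble or path.
#' @param counts Optional wide count tibble or path.
#' @return A tibble of violations (`component`, `line`, `problem`); zero
#'   rows when everything is consistent. Line numbers count the TSV header
#'   as line 1.
#' @export
validate_inputs <- function(library, samples = NULL, counts = NULL) {
  if (is.character(library)) library <- read_library(library)
  if (is.character(samples)) samples <- read_sample_sheet(samples)
  if (is.character(counts)) counts <- read_counts(counts)
  probs <- list()
  add <- function(component, line, problem)
    probs[[length(probs) + 1]] <<- tibble::tibble(
      component = component, line = as.integer(line), problem = problem)

  dup <- which(duplicated(library$hairpin_id))
  for (i in dup) add("library", i + 1,
                     paste0("duplicate hairpin_id: ", library$hairpin_id[i]))
  dup <- which(duplicated(library$guide))
  for (i in dup) add("library", i + 1,
                     paste0("duplicate guide: ", library$guide[i]))
  glen <- nchar(library$guide)
  off <- which(glen != glen[1])
  for (i in off) add("library", i + 1,
                     sprintf("guide length %d differs from %d", glen[i], glen[1]))
  bad <- which(is.na(library$gene) | library$gene == "")
  for (i in bad) add("library", i + 1, "empty gene label")

  if (!is.null(samples)) {
    dup <- which(duplicated(samples$sample))
    for (i in dup) add("sample_sheet", i + 1,
                       paste0("duplicate sample id: ", samples$sample[i]))
    bad <- which(!samples$arm %in% c("vehicle", "treatment"))
    for (i in bad) add("sample_sheet", i + 1,
                       paste0("invalid arm: ", samples$arm[i]))
  }

  if (!is.null(counts)) {
    extra <- which(!counts$hairpin_id %in% library$hairpin_id)
    for (i in extra) add("counts", i + 1,
                         paste0("hairpin absent from library: ",
                                counts$hairpin_id[i]))
    m <- counts_matrix(counts)
    bad_rows <- which(apply(m, 1, function(r)
      any(r < 0) || any(r != round(r))))
    for (i in bad_rows) add("counts", i + 1,
                            "counts must be non-negative integers")
    if (!is.null(samples)) {
      missing <- setdiff(samples$sample, colnames(m))
      for (s in missing) add("counts", NA,
                             paste0("sample in sheet without counts: ", s))
      extra_s <- setdiff(colnames(m), samples$sample)
      for (s in extra_s) add("counts", NA,
                             paste0("count column not in sample sheet: ", s))
    }
  }
  if (length(probs) == 0)
    return(tibble::tibble(component = character(0), line = integer(0),
                          problem = character(0)))
  dplyr::bind_rows(probs)
}
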