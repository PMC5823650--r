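## Plain-text readers/writers for the pipeline's interchange formats.
## All TSVs carry a single header line; hairpin-keyed tables are written
## sorted lexicographically by hairpin_id so outputs are byte-stable.

#' Read and write shRNA library tables
#'
#' The library TSV has columns `hairpin_id`, `guide`, `gene`; the optional
#' FASTA mirrors it with the hairpin id as record id and the guide as
#' sequence.
#'
#' @param library Library tibble.
#' @param tsv Path of the library TSV.
#' @param fasta Optional FASTA path to write alongside.
#' @return `read_library()` returns the library tibble; the writer returns
#'   `tsv` invisibly.
#' @export
write_library <- function(library, tsv, fasta = NULL) {
  lib <- dplyr::arrange(library[, c("hairpin_id", "guide", "gene")],
                        .data$hairpin_id)
  readr::write_tsv(lib, tsv, progress = FALSE)
  if (!is.null(fasta)) {
    x <- Biostrings::DNAStringSet(setNames(lib$guide, lib$hairpin_id))
    Biostrings::writeXStringSet(x, fasta)
  }
  invisible(tsv)
}

#' @rdname write_library
#' @export
read_library <- function(tsv) {
  lib <- readr::read_tsv(tsv, col_types = "ccc", progress = FALSE)
  stopifnot(all(c("hairpin_id", "guide", "gene") %in% names(lib)))
  lib
}

#' Read and write hairpin count tables
#'
#' Wide TSV: `hairpin_id` column followed by one integer column per
#' sample, rows sorted lexicographically.
#'
#' @param counts Wide count tibble.
#' @param path TSV path.
#' @return `read_counts()` returns the count tibble; the writer returns
#'   `path` invisibly.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(dplyr::arrange(counts, .data$hairpin_id), path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  cnt <- readr::read_tsv(path, col_types = readr::cols(
    hairpin_id = readr::col_character(),
    .default = readr::col_integer()), progress = FALSE)
  stopifnot("hairpin_id" %in% names(cnt))
  cnt
}

#' Read and write sample sheets
#'
#' Columns `sample`, `arm` (vehicle/treatment), `replicate`, `screen_id`.
#'
#' @param samples Sample sheet tibble.
#' @param path TSV path.
#' @return `read_sample_sheet()` returns the tibble; the writer returns
#'   `path` invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  readr::write_tsv(samples, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  sh <- readr::read_tsv(path, col_types = readr::cols(
    replicate = readr::col_integer(), .default = readr::col_character()),
    progress = FALSE)
  stopifnot(all(c("sample", "arm") %in% names(sh)))
  sh
}

#' Write a full simulated screen to disk
#'
#' Emits every interchange file of one simulated screen: library TSV +
#' FASTA, counts TSV, sample sheet TSV, gene- and hairpin-level truth
#' TSVs, and optionally per-sample FASTQ.
#'
#' @param sim A `screen_sim` from [simulate_screen()].
#' @param dir Output directory (created if needed).
#' @param fastq Also emit per-sample FASTQ via [emit_fastq()] (uses the
#'   configuration's `junk_fraction`, `read_length` and seed).
#' @return Named list of written paths, invisibly.
#' @export
write_screen <- function(sim, dir, fastq = FALSE) {
  stopifnot(inherits(sim, "screen_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    library = file.path(dir, "library.tsv"),
    library_fasta = file.path(dir, "library.fasta"),
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_hairpins = file.path(dir, "truth_hairpins.tsv")
  )
  write_library(sim$library, paths$library, paths$library_fasta)
  write_counts(sim$counts, paths$counts)
  write_sample_sheet(sim$samples, paths$samples)
  readr::write_tsv(sim$truth_genes, paths$truth_genes, progress = FALSE)
  readr::write_tsv(dplyr::arrange(sim$truth_hairpins, .data$hairpin_id),
                   paths$truth_hairpins, progress = FALSE)
  if (fastq) {
    fq_dir <- file.path(dir, "fastq")
    manifest <- emit_fastq(sim$counts, sim$library, fq_dir,
                           junk_fraction = sim$config$junk_fraction,
                           read_length = sim$config$read_length,
                           seed = sim$config$rng_seed + 2L)
    paths$fastq <- manifest$path
  }
  invisible(paths)
}
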