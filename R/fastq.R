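#' Default 5' adapter used by the simulator and the counter
#'
#' The read layout emitted by [emit_fastq()] is
#' `adapter + guide + random tail`, padded to the configured read length;
#' [count_reads()] locates this adapter by exact substring search.
#'
#' @return A length-one character string.
#' @export
default_adapter <- function() "TAGCCTGCAGGT"

#' Write simulated per-sample FASTQ files from a hairpin count table
#'
#' Each hairpin contributes exactly its count of reads per sample, laid out
#' as `adapter + guide + random tail` at constant quality (Phred+33 'I').
#' A configured fraction of adapter-less junk reads is injected to exercise
#' the preprocessing stage, and reads are shuffled within each file.
#'
#' @param counts Wide count tibble (`hairpin_id` + one column per sample).
#' @param library Library tibble with `hairpin_id` and `guide`.
#' @param dir Output directory; one `<sample>.fastq` per count column.
#' @param adapter 5' adapter sequence (non-empty).
#' @param junk_fraction Each emitted record is junk (no adapter, random
#'   sequence) with this probability, so a file with `n` true reads holds
#'   about `n / (1 - junk_fraction)` records.
#' @param read_length Total read length; must fit adapter + guide.
#' @param seed Integer seed controlling tails, junk and shuffling.
#' @return A tibble with columns `sample`, `path`, `n_true`, `n_junk`,
#'   `n_records`, invisibly usable as a manifest for [count_reads()].
#' @export
emit_fastq <- function(counts, library, dir,
                       adapter = default_adapter(),
                       junk_fraction = 0, read_length = 50L, seed = 1L) {
  stopifnot(nchar(adapter) > 0, junk_fraction >= 0, junk_fraction < 1)
  guide_len <- unique(nchar(library$guide))
  stopifnot(length(guide_len) == 1)
  tail_len <- read_length - nchar(adapter) - guide_len
  if (tail_len < 0)
    abort("read_length too short for adapter + guide")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  guide_of <- setNames(library$guide, library$hairpin_id)
  if (anyNA(guide_of[counts$hairpin_id]))
    abort("counts contain hairpins absent from the library")
  m <- counts_matrix(counts)
  qual <- strrep("I", read_length)

  withr::with_seed(seed, {
    manifest <- purrr::map(colnames(m), function(s) {
      n_true <- sum(m[, s])
      guides <- rep(guide_of[rownames(m)], m[, s])
      tails <- if (tail_len > 0) random_dna(n_true, tail_len) else
        character(n_true)
      true_seq <- if (n_true > 0) paste0(adapter, guides, tails) else
        character(0)
      n_junk <- if (junk_fraction > 0 && n_true > 0)
        rbinom(1, n_true, junk_fraction / (1 - junk_fraction)) else 0L
      junk_seq <- random_dna(n_junk, read_length)
      while (any(has_ad <- grepl(adapter, junk_seq, fixed = TRUE)))
        junk_seq[has_ad] <- random_dna(sum(has_ad), read_length)
      seqs <- c(true_seq, junk_seq)
      ord <- sample.int(length(seqs))
      seqs <- seqs[ord]
      path <- file.path(dir, paste0(s, ".fastq"))
      write_fastq(path, sprintf("%s_read%07d", s, seq_along(seqs)),
                  seqs, qual)
      tibble::tibble(sample = s, path = path, n_true = n_true,
                     n_junk = as.integer(n_junk),
                     n_records = length(seqs))
    })
    dplyr::bind_rows(manifest)
  })
}

write_fastq <- function(path, ids, seqs, qual) {
  if (length(seqs) == 0) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(rep(qual, length(x))))
  invisible(path)
}
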