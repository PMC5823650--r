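#' Build a hash index over library guide sequences
#'
#' Exact-match lookup table from guide sequence to hairpin id, optionally
#' extended with the full 1-substitution neighborhood of every guide.
#' Lookup uses a best-stratum rule: a query equal to exactly one library
#' guide maps to that hairpin; otherwise (with `max_mismatch = 1`) the
#' 1-mismatch neighborhood is consulted, and a query within one mismatch of
#' two or more distinct hairpins is reported ambiguous.
#'
#' @param library Library tibble with `hairpin_id` and `guide`.
#' @param max_mismatch 0 (exact only) or 1.
#' @return A `guide_index` object.
#' @export
build_guide_index <- function(library, max_mismatch = 0L) {
  stopifnot(max_mismatch %in% c(0L, 1L))
  if (anyDuplicated(library$guide) > 0)
    abort("duplicate guide sequences in library")
  glen <- unique(nchar(library$guide))
  if (length(glen) != 1) abort("guides must share a single length")
  exact <- setNames(library$hairpin_id, library$guide)
  neighbor <- NULL
  if (max_mismatch == 1L) {
    nb <- substitution_neighbors(library$guide, library$hairpin_id)
    first <- !duplicated(nb$variant)
    neighbor <- setNames(nb$hairpin_id[first], nb$variant[first])
    conflict <- unique(nb$variant[nb$hairpin_id != neighbor[nb$variant]])
    neighbor[conflict] <- NA_character_   # NA marks an ambiguous neighbor
  }
  structure(list(exact = exact, neighbor = neighbor,
                 guide_length = glen, max_mismatch = max_mismatch),
            class = "guide_index")
}

## All 3*L single-substitution variants of each guide (proper changes only).
substitution_neighbors <- function(guides, hairpin_ids) {
  L <- nchar(guides[1])
  bases <- c("A", "C", "G", "T")
  out_v <- vector("list", L)
  out_h <- vector("list", L)
  for (pos in seq_len(L)) {
    orig <- substr(guides, pos, pos)
    vs <- lapply(bases, function(b) {
      keep <- orig != b
      g <- guides[keep]
      substr(g, pos, pos) <- b
      list(v = g, h = hairpin_ids[keep])
    })
    out_v[[pos]] <- unlist(lapply(vs, `[[`, "v"), use.names = FALSE)
    out_h[[pos]] <- unlist(lapply(vs, `[[`, "h"), use.names = FALSE)
  }
  list(variant = unlist(out_v, use.names = FALSE),
       hairpin_id = unlist(out_h, use.names = FALSE))
}

#' Look up guide candidates in a guide index
#'
#' @param index A [build_guide_index()] result.
#' @param queries Character vector of candidate guide sequences.
#' @return A tibble with `query`, `hairpin_id` (NA unless uniquely mapped)
#'   and `status` in `mapped`, `unmapped`, `ambiguous`.
#' @export
lookup_guides <- function(index, queries) {
  hp <- unname(index$exact[queries])
  status <- ifelse(is.na(hp), "unmapped", "mapped")
  if (!is.null(index$neighbor)) {
    miss <- is.na(hp)
    if (any(miss)) {
      present <- queries[miss] %in% names(index$neighbor)
      nb <- rep(NA_character_, sum(miss))
      nb[present] <- unname(index$neighbor[queries[miss][present]])
      # present but NA in the table = ambiguous neighborhood
      st <- ifelse(present, ifelse(is.na(nb), "ambiguous", "mapped"),
                   "unmapped")
      hp[miss] <- nb
      status[miss] <- st
    }
  }
  tibble::tibble(query = queries, hairpin_id = hp, status = status)
}

#' Extract guide candidates from reads
#'
#' Reproduces the screen's preprocessing stage: reads without the adapter
#' (exact substring, first occurrence) are discarded as non-barcoded;
#' surviving reads below the mean-quality floor are discarded as low
#' quality; otherwise the `guide_length` bases immediately after the
#' adapter are returned. A read too short to hold a full guide after the
#' adapter counts as non-barcoded.
#'
#' @param seqs Character vector of read sequences.
#' @param quals Character vector of Phred+33 quality strings (same length).
#' @param adapter Adapter sequence searched as an exact substring.
#' @param guide_length Number of bases to extract after the adapter.
#' @param min_mean_quality Minimum mean Phred score over the whole read.
#' @return A tibble with `guide` (NA when discarded) and `reason` (NA when
#'   kept, else `no_adapter` or `low_quality`).
#' @export
preprocess_reads <- function(seqs, quals, adapter,
                             guide_length, min_mean_quality = 20) {
  stopifnot(length(seqs) == length(quals), nchar(adapter) > 0)
  n <- length(seqs)
  if (n == 0)
    return(tibble::tibble(guide = character(0), reason = character(0)))
  pos <- regexpr(adapter, seqs, fixed = TRUE)
  start <- pos + nchar(adapter)
  ok_ad <- pos > 0 & (start + guide_length - 1L) <= nchar(seqs)
  widths <- nchar(quals)
  scores <- as.integer(charToRaw(paste(quals, collapse = ""))) - 33L
  mean_q <- rowsum(scores, rep.int(seq_len(n), widths))[, 1] / widths
  reason <- rep(NA_character_, n)
  reason[!ok_ad] <- "no_adapter"
  reason[ok_ad & mean_q < min_mean_quality] <- "low_quality"
  guide <- rep(NA_character_, n)
  keep <- is.na(reason)
  guide[keep] <- substr(seqs[keep], start[keep],
                        start[keep] + guide_length - 1L)
  tibble::tibble(guide = guide, reason = reason)
}

#' Count hairpin reads per sample from FASTQ files
#'
#' The counting stage of the pipeline: reads are preprocessed with
#' [preprocess_reads()], candidates are mapped against the library with
#' [lookup_guides()], and per-sample tallies are returned together with a
#' mapping report whose categories partition every file's records.
#'
#' @param fastq_files Named character vector of FASTQ paths (names are
#'   sample ids) or a manifest tibble with `sample` and `path` columns.
#' @param library Library tibble (`hairpin_id`, `guide`, `gene`).
#' @param adapter Adapter sequence; see [preprocess_reads()].
#' @param max_mismatch Guide-matching tolerance, 0 (default) or 1.
#' @param min_mean_quality Mean-Phred floor for keeping a read.
#' @param revcomp Also search the reverse-complemented read when the
#'   adapter is absent from the forward strand.
#' @return A list with `counts` (wide tibble: every library hairpin, one
#'   column per sample) and `report` (per sample: total_reads,
#'   discarded_no_adapter, discarded_low_quality, unmapped, ambiguous,
#'   mapped).
#' @export
count_reads <- function(fastq_files, library,
                        adapter = default_adapter(), max_mismatch = 0L,
                        min_mean_quality = 20, revcomp = FALSE) {
  if (is.data.frame(fastq_files))
    fastq_files <- setNames(fastq_files$path, fastq_files$sample)
  if (is.null(names(fastq_files)) || any(names(fastq_files) == ""))
    abort("fastq_files must be named by sample id")
  missing <- !file.exists(fastq_files)
  if (any(missing))
    abort(paste0("FASTQ file not found for sample(s): ",
                 paste(names(fastq_files)[missing], collapse = ", ")))
  index <- build_guide_index(library, max_mismatch)
  lib_sorted <- sort(library$hairpin_id)
  tallies <- purrr::imap(fastq_files, function(path, s) {
    fq <- read_fastq(path)
    pp <- preprocess_reads(fq$seq, fq$qual, adapter,
                           index$guide_length, min_mean_quality)
    if (revcomp && any(no_ad <- pp$reason %in% "no_adapter")) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(fq$seq[no_ad])))
      pp_rc <- preprocess_reads(rc, fq$qual[no_ad], adapter,
                                index$guide_length, min_mean_quality)
      pp[no_ad, ] <- pp_rc
    }
    kept <- !is.na(pp$guide)
    lk <- lookup_guides(index, pp$guide[kept])
    cnt <- table(factor(lk$hairpin_id[lk$status == "mapped"],
                        levels = lib_sorted))
    list(
      counts = as.integer(cnt),
      report = tibble::tibble(
        sample = s,
        total_reads = nrow(pp),
        discarded_no_adapter = sum(pp$reason %in% "no_adapter"),
        discarded_low_quality = sum(pp$reason %in% "low_quality"),
        unmapped = sum(lk$status == "unmapped"),
        ambiguous = sum(lk$status == "ambiguous"),
        mapped = sum(lk$status == "mapped")
      )
    )
  })
  cnt <- do.call(cbind, lapply(tallies, `[[`, "counts"))
  rownames(cnt) <- lib_sorted
  colnames(cnt) <- names(fastq_files)
  list(counts = counts_tibble(cnt),
       report = dplyr::bind_rows(lapply(tallies, `[[`, "report")))
}

read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  list(seq = as.character(x),
       qual = as.character(S4Vectors::mcols(x)$qualities))
}
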