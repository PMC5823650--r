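#' Flag hairpins targeting unannotated transcripts
#'
#' Reproduces the screen's annotation filter: every hairpin whose library
#' gene label is the [unannotated_sentinel()] is flagged `unannotated` and
#' thereby excluded from multiple-testing adjustment and gene collapse.
#' Idempotent; hairpins already carrying a filter flag keep it.
#'
#' @param stats Per-hairpin statistics tibble (needs `hairpin_id`; a
#'   `filtered` column is added when absent).
#' @param library Library tibble with `hairpin_id` and `gene`.
#' @return `stats` with the `filtered` flag set (and `gene` filled from the
#'   library where missing).
#' @export
filter_unannotated <- function(stats, library) {
  stats <- ensure_filter_col(stats)
  gene <- library$gene[match(stats$hairpin_id, library$hairpin_id)]
  if (!"gene" %in% names(stats)) stats$gene <- gene
  hit <- !is.na(gene) & gene == unannotated_sentinel() & is.na(stats$filtered)
  stats$filtered[hit] <- "unannotated"
  stats
}

#' Direction-consistency filter on raw counts (medC > maxT)
#'
#' Drops hairpins whose raw counts contradict their called direction: a
#' hairpin called enriched in treatment is dropped when the median raw
#' vehicle count exceeds the maximum raw treatment count, and, mirrored, a
#' hairpin called depleted is dropped when the median raw treatment count
#' exceeds the maximum raw vehicle count. The rule operates on raw,
#' pre-normalization counts.
#'
#' @param stats Per-hairpin statistics tibble with `hairpin_id` and
#'   `direction`.
#' @param counts Raw wide count tibble.
#' @param samples Sample sheet tibble (`sample`, `arm`).
#' @return `stats` with inconsistent hairpins flagged `medC_gt_maxT`.
#' @seealso [medc_maxt_keep()] for the single-hairpin rule.
#' @export
filter_medc_maxt <- function(stats, counts, samples) {
  stats <- ensure_filter_col(stats)
  samples <- align_samples(counts, samples)
  m <- counts_matrix(counts)
  m <- m[match(stats$hairpin_id, rownames(m)), , drop = FALSE]
  veh <- m[, samples$arm == "vehicle", drop = FALSE]
  trt <- m[, samples$arm == "treatment", drop = FALSE]
  med_veh <- apply(veh, 1, median)
  med_trt <- apply(trt, 1, median)
  max_veh <- apply(veh, 1, max)
  max_trt <- apply(trt, 1, max)
  drop <- ifelse(stats$direction == "enriched",
                 med_veh > max_trt,
                 med_trt > max_veh)
  hit <- drop & is.na(stats$filtered)
  stats$filtered[hit] <- "medC_gt_maxT"
  stats
}

#' Single-hairpin direction-consistency rule
#'
#' @param vehicle,treatment Raw counts of one hairpin in each arm.
#' @param direction `"depleted"` or `"enriched"`.
#' @return TRUE to keep the hairpin, FALSE to drop it.
#' @examples
#' medc_maxt_keep(c(20, 21, 22), c(10, 12), "enriched")  # FALSE: 21 > 12
#' @export
medc_maxt_keep <- function(vehicle, treatment, direction) {
  stopifnot(direction %in% c("depleted", "enriched"))
  if (direction == "enriched") median(vehicle) <= max(treatment)
  else median(treatment) <= max(vehicle)
}

#' Low-abundance filter
#'
#' Optional plumbing filter (off by default in the pipeline): hairpins
#' whose total raw count across all samples falls below `min_total` are
#' flagged `low_count`.
#'
#' @param stats Per-hairpin statistics tibble.
#' @param counts Raw wide count tibble.
#' @param min_total Minimum total raw count across samples.
#' @return `stats` with low-abundance hairpins flagged.
#' @export
filter_low_count <- function(stats, counts, min_total = 10) {
  stats <- ensure_filter_col(stats)
  tot <- rowSums(counts_matrix(counts))
  tot <- tot[match(stats$hairpin_id, names(tot))]
  hit <- tot < min_total & is.na(stats$filtered)
  stats$filtered[hit] <- "low_count"
  stats
}

ensure_filter_col <- function(stats) {
  if (!"filtered" %in% names(stats))
    stats$filtered <- NA_character_
  stats
}
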