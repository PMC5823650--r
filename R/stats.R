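#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH false-discovery-rate adjustment (via [stats::p.adjust()]),
#' the "q-value" of the per-hairpin stage: monotone in p-rank and bounded
#' by 1.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return Adjusted q-values in the original order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  p.adjust(pvals, method = "BH")
}

#' Per-hairpin differential representation between treatment and vehicle
#'
#' The hairpin-level testing stage of the screen pipeline. Counts are
#' normalized ([normalize_sizes()]), equalized to a common library size
#' (rounded pseudo-counts) and summed per arm; each hairpin's arm sums are
#' tested with the conditional negative-binomial exact test
#' ([nb_exact_test()]) at a common dispersion that is estimated from the
#' data ([estimate_dispersion()]) unless supplied. Log2 fold-change uses a
#' pseudo-count of 0.5 on each arm's mean normalized count, and the sign of
#' the fold-change sets the hairpin's direction. Filters then run in the
#' screen's stated order — annotation filter, then the medC > maxT
#' direction-consistency filter (and optionally a low-count filter) — and
#' BH q-values are computed over the surviving hairpins only (filtered
#' hairpins carry `q = NA`).
#'
#' @param counts Raw wide count tibble (`hairpin_id` + one column per
#'   sample).
#' @param samples Sample sheet tibble (`sample`, `arm` in
#'   vehicle/treatment, optionally `replicate`, `screen_id`).
#' @param library Optional library tibble; enables the annotation filter
#'   and attaches gene symbols.
#' @param dispersion A fixed dispersion (single number), a
#'   `dispersion_fit`, or NULL to estimate from the data (requires >= 2
#'   replicates per arm).
#' @param normalization `"median_ratio"` (default) or `"total"`.
#' @param filter_unann Apply the unannotated-gene filter (needs `library`).
#' @param filter_consistency Apply the medC > maxT filter.
#' @param min_total Minimum total raw count, or NULL (default) to disable
#'   the low-count filter.
#' @return An `shrna_stats` tibble: one row per hairpin with columns
#'   `hairpin_id`, `gene`, `mean_vehicle`, `mean_treatment` (normalized
#'   means), `logFC`, `p_two`, `p_dep`, `p_enr`, `q`, `direction`,
#'   `filtered`. The dispersion and size factors used are attached as
#'   attributes `dispersion` and `size_factors`.
#' @examples
#' cfg <- sim_config(n_genes = 30, seq_depth_per_sample = 2e4)
#' sim <- simulate_screen(simulate_library(cfg), cfg)
#' st <- test_hairpins(sim$counts, sim$samples, sim$library,
#'                     dispersion = 0.1)
#' dplyr::arrange(st, p_dep)
#' @export
test_hairpins <- function(counts, samples, library = NULL,
                          dispersion = NULL,
                          normalization = c("median_ratio", "total"),
                          filter_unann = TRUE,
                          filter_consistency = TRUE,
                          min_total = NULL) {
  normalization <- match.arg(normalization)
  samples <- align_samples(counts, samples)
  sf <- normalize_sizes(counts, method = normalization)
  phi <- resolve_dispersion(dispersion, counts, samples, sf)

  m <- counts_matrix(counts)
  fac <- sf$size_factor[match(colnames(m), sf$sample)]
  norm <- sweep(m, 2, fac, "/")
  y <- round(norm)
  trt_cols <- samples$arm == "treatment"
  n_treat <- sum(trt_cols)
  n_ctrl <- sum(!trt_cols)
  t_sum <- rowSums(y[, trt_cols, drop = FALSE])
  c_sum <- rowSums(y[, !trt_cols, drop = FALSE])

  pv <- nb_exact_test(t_sum, c_sum, phi, n_treat, n_ctrl)
  mean_trt <- rowMeans(norm[, trt_cols, drop = FALSE])
  mean_veh <- rowMeans(norm[, !trt_cols, drop = FALSE])
  logfc <- log2((mean_trt + 0.5) / (mean_veh + 0.5))

  stats <- tibble::tibble(
    hairpin_id = rownames(m),
    gene = if (!is.null(library))
      library$gene[match(rownames(m), library$hairpin_id)] else NA_character_,
    mean_vehicle = mean_veh,
    mean_treatment = mean_trt,
    logFC = logfc,
    p_two = pv$p_two,
    p_dep = pv$p_dep,
    p_enr = pv$p_enr,
    direction = ifelse(logfc < 0, "depleted", "enriched"),
    filtered = NA_character_
  )
  if (filter_unann && !is.null(library))
    stats <- filter_unannotated(stats, library)
  if (filter_consistency)
    stats <- filter_medc_maxt(stats, counts, samples)
  if (!is.null(min_total))
    stats <- filter_low_count(stats, counts, min_total)

  stats$q <- NA_real_
  keep <- is.na(stats$filtered)
  stats$q[keep] <- bh_adjust(stats$p_two[keep])
  stats <- stats[, c("hairpin_id", "gene", "mean_vehicle", "mean_treatment",
                     "logFC", "p_two", "p_dep", "p_enr", "q", "direction",
                     "filtered")]
  attr(stats, "dispersion") <- phi
  attr(stats, "size_factors") <- sf
  class(stats) <- c("shrna_stats", class(stats))
  stats
}

resolve_dispersion <- function(dispersion, counts, samples, sf) {
  if (is.null(dispersion))
    return(estimate_dispersion(counts, samples, size_factors = sf)$common)
  if (inherits(dispersion, "dispersion_fit")) return(dispersion$common)
  if (is.numeric(dispersion) && length(dispersion) == 1 && dispersion >= 0)
    return(dispersion)
  abort("dispersion must be NULL, a dispersion_fit, or a single number >= 0")
}

#' @rdname test_hairpins
#' @param x An `shrna_stats` tibble.
#' @param ... Unused.
#' @method glance shrna_stats
#' @export
glance.shrna_stats <- function(x, ...) {
  tibble::tibble(
    n_hairpins = nrow(x),
    n_tested = sum(is.na(x$filtered)),
    n_filtered = sum(!is.na(x$filtered)),
    dispersion = attr(x, "dispersion"),
    n_q_lt_0.05 = sum(x$q < 0.05, na.rm = TRUE)
  )
}
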