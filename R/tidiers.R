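## broom-style tidiers for the simulator container.

#' Tidy a simulated screen into long counts
#'
#' @param x A `screen_sim` from [simulate_screen()].
#' @param ... Unused.
#' @return A long tibble: `hairpin_id`, `gene`, `class`, `sample`, `arm`,
#'   `replicate`, `count`.
#' @method tidy screen_sim
#' @export
tidy.screen_sim <- function(x, ...) {
  long <- tidyr::pivot_longer(x$counts, -"hairpin_id",
                              names_to = "sample", values_to = "count")
  long <- dplyr::left_join(long, x$samples, by = "sample")
  info <- x$truth_hairpins[, c("hairpin_id", "gene", "class")]
  dplyr::left_join(long, info, by = "hairpin_id")[
    , c("hairpin_id", "gene", "class", "sample", "arm", "replicate",
        "count")]
}

#' One-row summary of a simulated screen
#'
#' @param x A `screen_sim`.
#' @param ... Unused.
#' @return A tibble with library size, sample count, per-class gene
#'   totals, and total reads.
#' @method glance screen_sim
#' @export
glance.screen_sim <- function(x, ...) {
  cls <- table(factor(x$truth_genes$class,
                      levels = c("neutral", "essential",
                                 "synthetic_lethal", "resistance")))
  tibble::tibble(
    n_hairpins = nrow(x$counts),
    n_genes = nrow(x$truth_genes),
    n_samples = nrow(x$samples),
    n_neutral = as.integer(cls[["neutral"]]),
    n_essential = as.integer(cls[["essential"]]),
    n_synthetic_lethal = as.integer(cls[["synthetic_lethal"]]),
    n_resistance = as.integer(cls[["resistance"]]),
    total_reads = sum(counts_matrix(x$counts))
  )
}
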