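#' Weighted Z-transform (Stouffer) combination of p-values
#'
#' Combines member p-values via normal quantiles:
#' `z_i = qnorm(1 - p_i)`, `Zw = sum(w_i z_i) / sqrt(sum(w_i^2))`,
#' combined `p = 1 - pnorm(Zw)`. Inputs are clipped to
#' `[1e-300, 1 - 1e-16]` so the quantile stays finite in double precision.
#' The statistic is invariant to rescaling all weights by a positive
#' constant, and a single member is returned unchanged.
#'
#' @param p Numeric vector of p-values.
#' @param w Non-negative weights, not all zero; equal by default.
#' @return A list with `z` (the combined weighted Z) and `p` (the combined
#'   upper-tail p-value).
#' @examples
#' stouffer_weighted_z(c(0.05, 0.05))$p   # ~0.0100
#' @export
stouffer_weighted_z <- function(p, w = rep(1, length(p))) {
  stopifnot(length(p) >= 1, length(w) == length(p))
  if (any(w < 0)) abort("weights must be non-negative")
  if (all(w == 0)) abort("weights must not all be zero")
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  z <- qnorm(p, lower.tail = FALSE)
  zw <- sum(w * z) / sqrt(sum(w^2))
  list(z = zw, p = pnorm(zw, lower.tail = FALSE))
}

#' E-value of a gene-level p-value
#'
#' The expected number of false gene-level hits at this significance,
#' i.e. the Bonferroni expectation `p * n_genes`.
#'
#' @param p Combined p-value(s) in [0, 1].
#' @param n_genes Number of genes tested (>= 1).
#' @return `p * n_genes`.
#' @export
compute_evalue <- function(p, n_genes) {
  stopifnot(n_genes >= 1, all(p >= 0 & p <= 1))
  p * n_genes
}

#' Collapse hairpin statistics to gene-level scores
#'
#' Aggregates each gene's surviving (unfiltered) hairpins into one score by
#' weighted Z-transformation. For the synthetic-lethal (depleted) direction
#' the default combines the one-sided depletion p-values; `mode = "q"`
#' instead combines direction-signed BH q-values (`q` when the hairpin's
#' direction matches the collapse direction, `1 - q` otherwise), a literal
#' q-combination retained for fidelity although it carries no calibration
#' guarantee. Weights are equal by default or proportional to the square
#' root of the hairpin's mean normalized abundance
#' (`weighting = "sqrt_mean_count"`). The E-value is computed against the
#' number of genes with at least one surviving hairpin, and the table is
#' sorted ascending by the combined p so it reads as a ranked candidate
#' list.
#'
#' @param stats An `shrna_stats` tibble from [test_hairpins()].
#' @param mode `"p"` (combine one-sided p-values, default) or `"q"`
#'   (combine signed BH q-values).
#' @param weighting `"equal"` (default) or `"sqrt_mean_count"`.
#' @param direction `"depleted"` (synthetic-lethal calling, default) or
#'   `"enriched"` (resistance screens).
#' @return A `gene_results` tibble: `gene`, `k` (hairpins combined), `Zw`,
#'   `P_wZP`, `E`, `direction`, `hairpins` (comma-joined member ids),
#'   sorted by `P_wZP`. The number of genes tested is attached as
#'   attribute `n_genes`.
#' @examples
#' cfg <- sim_config(n_genes = 30, seq_depth_per_sample = 2e4)
#' sim <- simulate_screen(simulate_library(cfg), cfg)
#' st <- test_hairpins(sim$counts, sim$samples, sim$library,
#'                     dispersion = 0.1)
#' collapse_genes(st)
#' @export
collapse_genes <- function(stats, mode = c("p", "q"),
                           weighting = c("equal", "sqrt_mean_count"),
                           direction = c("depleted", "enriched")) {
  mode <- match.arg(mode)
  weighting <- match.arg(weighting)
  direction <- match.arg(direction)
  keep <- stats[is.na(stats$filtered) & !is.na(stats$gene) &
                  stats$gene != unannotated_sentinel(), , drop = FALSE]
  if (nrow(keep) == 0)
    return(empty_gene_results(direction))

  keep$p_in <- if (mode == "p") {
    if (direction == "depleted") keep$p_dep else keep$p_enr
  } else {
    ifelse(keep$direction == direction, keep$q, 1 - keep$q)
  }
  keep$w <- switch(weighting,
    equal = 1,
    sqrt_mean_count = sqrt((keep$mean_vehicle + keep$mean_treatment) / 2))

  res <- keep |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      k = dplyr::n(),
      Zw = stouffer_weighted_z(.data$p_in, .data$w)$z,
      P_wZP = stouffer_weighted_z(.data$p_in, .data$w)$p,
      hairpins = paste(.data$hairpin_id, collapse = ","),
      .groups = "drop"
    )
  n_genes <- nrow(res)
  res$E <- compute_evalue(res$P_wZP, n_genes)
  res$direction <- direction
  res <- res[order(res$P_wZP, res$gene),
             c("gene", "k", "Zw", "P_wZP", "E", "direction", "hairpins")]
  attr(res, "n_genes") <- n_genes
  class(res) <- c("gene_results", class(res))
  res
}

empty_gene_results <- function(direction) {
  res <- tibble::tibble(gene = character(0), k = integer(0),
                        Zw = numeric(0), P_wZP = numeric(0), E = numeric(0),
                        direction = character(0), hairpins = character(0))
  attr(res, "n_genes") <- 0L
  class(res) <- c("gene_results", class(res))
  res
}

#' @rdname collapse_genes
#' @param x A `gene_results` tibble.
#' @param ... Unused.
#' @method glance gene_results
#' @export
glance.gene_results <- function(x, ...) {
  tibble::tibble(n_genes = attr(x, "n_genes") %||% nrow(x),
                 n_P_lt_0.05 = sum(x$P_wZP < 0.05),
                 min_P = if (nrow(x)) min(x$P_wZP) else NA_real_)
}
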