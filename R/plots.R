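## ggplot2 views of the pipeline's result objects.

#' Volcano plot of per-hairpin differential representation
#'
#' Log2 fold-change against -log10 two-sided p, coloured by filter status
#' and BH significance.
#'
#' @param object An `shrna_stats` tibble from [test_hairpins()].
#' @param q_cut Highlight hairpins with `q` below this cutoff.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shrna_stats
#' @export
autoplot.shrna_stats <- function(object, q_cut = 0.05, ...) {
  df <- tibble::as_tibble(object)
  df$status <- dplyr::case_when(
    !is.na(df$filtered) ~ paste0("filtered: ", df$filtered),
    !is.na(df$q) & df$q < q_cut ~ sprintf("q < %g", q_cut),
    TRUE ~ "not significant")
  ggplot2::ggplot(df, ggplot2::aes(.data$logFC, -log10(.data$p_two),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "log2 fold-change (treatment / vehicle)",
                  y = expression(-log[10] ~ p),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Ranked gene-score plot
#'
#' Genes ordered by their combined P(wZP), with the hit threshold drawn;
#' the characteristic hockey-stick of a screen with planted (or real)
#' synthetic-lethal genes.
#'
#' @param object A `gene_results` tibble from [collapse_genes()].
#' @param alpha Threshold line to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gene_results
#' @export
autoplot.gene_results <- function(object, alpha = 0.05, ...) {
  df <- tibble::as_tibble(object)
  df$rank <- rank(df$P_wZP, ties.method = "first")
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, -log10(.data$P_wZP))) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "gene rank", y = expression(-log[10] ~ "P(wZP)")) +
    ggplot2::theme_minimal()
}

#' Abundance overview of a simulated screen
#'
#' Mean count per hairpin in each arm, coloured by planted gene class;
#' synthetic-lethal hairpins fall below the diagonal.
#'
#' @param object A `screen_sim` from [simulate_screen()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot screen_sim
#' @export
autoplot.screen_sim <- function(object, ...) {
  m <- counts_matrix(object$counts)
  arms <- object$samples$arm
  df <- tibble::tibble(
    hairpin_id = rownames(m),
    vehicle = rowMeans(m[, arms == "vehicle", drop = FALSE]),
    treatment = rowMeans(m[, arms == "treatment", drop = FALSE]))
  df$class <- object$truth_hairpins$class[
    match(df$hairpin_id, object$truth_hairpins$hairpin_id)]
  ggplot2::ggplot(df, ggplot2::aes(.data$vehicle + 1, .data$treatment + 1,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(linetype = "dashed") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean vehicle count + 1",
                  y = "mean treatment count + 1", colour = "class") +
    ggplot2::theme_minimal()
}

#' P-value calibration histogram
#'
#' Histogram of per-hairpin p-values; flat under the null, spiked near
#' zero when real depletion is present.
#'
#' @param stats An `shrna_stats` tibble.
#' @param which Which p-value column to plot.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_p_calibration <- function(stats, which = c("p_two", "p_dep", "p_enr"),
                               bins = 20) {
  which <- match.arg(which)
  df <- tibble::as_tibble(stats)[is.na(stats$filtered), ]
  ggplot2::ggplot(df, ggplot2::aes(.data[[which]])) +
    ggplot2::geom_histogram(bins = bins, boundary = 0, fill = "grey40") +
    ggplot2::labs(x = which, y = "hairpins") +
    ggplot2::theme_minimal()
}
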