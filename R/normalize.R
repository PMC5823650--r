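#' Per-sample size factors for a hairpin count table
#'
#' Depth normalization for pooled-screen counts. `total` scales by column
#' sums; `median_ratio` uses the median, over hairpins with all-positive
#' counts, of each sample's ratio to the per-hairpin geometric mean
#' (the median-of-ratios estimator familiar from RNA-seq, robust to a
#' minority of strongly depleted hairpins). Factors are rescaled to
#' geometric mean 1 so the implied common library size is the geometric
#' mean of the originals.
#'
#' @param counts Wide count tibble (`hairpin_id` + one column per sample).
#' @param method `"median_ratio"` (default) or `"total"`.
#' @return A tibble with `sample` and `size_factor`.
#' @examples
#' cnt <- tibble::tibble(hairpin_id = c("a", "b"),
#'                       s1 = c(10L, 30L), s2 = c(20L, 60L))
#' normalize_sizes(cnt, method = "total")
#' @export
normalize_sizes <- function(counts, method = c("median_ratio", "total")) {
  method <- match.arg(method)
  m <- counts_matrix(counts)
  totals <- colSums(m)
  if (any(totals <= 0))
    abort(paste0("sample(s) with zero total counts: ",
                 paste(colnames(m)[totals <= 0], collapse = ", ")))
  f <- if (method == "total") {
    totals
  } else {
    pos <- rowSums(m > 0) == ncol(m)
    if (!any(pos))
      abort("median_ratio needs at least one hairpin with all-positive counts")
    ref <- exp(rowMeans(log(m[pos, , drop = FALSE])))
    apply(m[pos, , drop = FALSE] / ref, 2, median)
  }
  f <- f / geomean(f)
  tibble::tibble(sample = colnames(m), size_factor = unname(f))
}
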