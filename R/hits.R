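#' Call per-screen synthetic-lethal hits
#'
#' Thresholds a gene-level table at `P_wZP < alpha` (strict inequality),
#' keeping only the depleted direction — genes whose hairpins are
#' underrepresented in the treatment arm.
#'
#' @param genes A `gene_results` tibble from [collapse_genes()].
#' @param alpha Significance threshold in (0, 1].
#' @param screen_id Label identifying this screen in downstream
#'   intersections; defaults to `"screen1"`.
#' @return A `hit_list` tibble (`screen_id`, `gene`, `P_wZP`, `E`), sorted
#'   ascending by `P_wZP`, with the threshold attached as attribute
#'   `alpha`.
#' @export
call_hits <- function(genes, alpha = 0.05, screen_id = "screen1") {
  stopifnot(alpha > 0, alpha <= 1)
  hit <- genes[genes$P_wZP < alpha & genes$direction == "depleted", ,
               drop = FALSE]
  out <- tibble::tibble(screen_id = rep(screen_id, nrow(hit)),
                        gene = hit$gene, P_wZP = hit$P_wZP, E = hit$E)
  out <- out[order(out$P_wZP, out$gene), ]
  attr(out, "alpha") <- alpha
  class(out) <- c("hit_list", class(out))
  out
}

#' Intersect hit lists across screens into common hits
#'
#' Genes called in every screen (set intersection on the gene symbol,
#' case-sensitive) form the common synthetic-lethal table, the cross-cell-
#' line result of a multi-screen design. Rows carry each screen's `P_wZP`
#' and are sorted ascending by the worst (maximum) per-screen `P_wZP`.
#'
#' @param ... Two or more `hit_list` tibbles, or a single list of them.
#' @return A tibble with `gene`, one `P_wZP_<screen_id>` column per
#'   screen, and `max_P_wZP`.
#' @examples
#' a <- tibble::tibble(screen_id = "s1", gene = c("A", "B"),
#'                     P_wZP = c(0.01, 0.02), E = c(1, 2))
#' b <- tibble::tibble(screen_id = "s2", gene = c("B", "C"),
#'                     P_wZP = c(0.03, 0.04), E = c(3, 4))
#' intersect_screens(a, b)
#' @export
intersect_screens <- function(...) {
  lists <- list(...)
  if (length(lists) == 1 && !is.data.frame(lists[[1]]))
    lists <- lists[[1]]
  if (length(lists) < 2)
    abort("intersect_screens needs at least two hit lists")
  ids <- vapply(lists, function(h) {
    sid <- unique(h$screen_id)
    if (length(sid) == 0) NA_character_ else sid[1]
  }, "")
  ids[is.na(ids)] <- paste0("screen", which(is.na(ids)))
  if (anyDuplicated(ids) > 0)
    ids <- make.unique(ids, sep = "_")
  common <- Reduce(intersect, lapply(lists, function(h) h$gene))
  out <- tibble::tibble(gene = common)
  for (i in seq_along(lists)) {
    h <- lists[[i]]
    out[[paste0("P_wZP_", ids[i])]] <- h$P_wZP[match(common, h$gene)]
  }
  pcols <- paste0("P_wZP_", ids)
  out$max_P_wZP <- if (nrow(out))
    do.call(pmax, out[pcols]) else numeric(0)
  out[order(out$max_P_wZP, out$gene), ]
}

#' The packaged common-hit fixture table
#'
#' Twelve gene symbols (with full names) reported as common
#' synthetic-lethal-in-crizotinib hits across the H2228 and H3122 ALK+
#' NSCLC screens; shipped as a plain-text fixture for intersection tests
#' and as a worked example of the common-hit output format.
#'
#' @return A tibble with `gene` and `gene_name`.
#' @export
common_slic_hits <- function() {
  path <- system.file("extdata", "common_slic_hits.tsv", package = "slicscreen",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = "cc", progress = FALSE)
}
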