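## Shared internal helpers.

#' Sentinel gene label for hairpins targeting unannotated transcripts
#'
#' Hairpins in pooled libraries that map to transcripts without a gene
#' annotation carry this sentinel in the `gene` column; the annotation
#' filter removes them before multiple-testing adjustment and gene collapse.
#'
#' @return A length-one character string.
#' @export
unannotated_sentinel <- function() "UNANNOTATED"

geomean <- function(x) exp(mean(log(x)))

#' Convert a wide count tibble to an integer matrix
#'
#' Count tables throughout the package are tibbles with a `hairpin_id`
#' column followed by one integer column per sample. This helper extracts
#' the numeric part as a matrix with hairpin ids as rownames.
#'
#' @param counts Wide count tibble (`hairpin_id` + one column per sample).
#' @return Integer matrix, hairpins in rows, samples in columns.
#' @export
counts_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), "hairpin_id" %in% names(counts))
  m <- as.matrix(counts[setdiff(names(counts), "hairpin_id")])
  storage.mode(m) <- "double"
  rownames(m) <- counts$hairpin_id
  m
}

counts_tibble <- function(m) {
  tibble::as_tibble(as.data.frame(m), rownames = "hairpin_id")
}

## Checks that a sample sheet matches the count columns; returns sheet rows
## reordered to the count column order.
align_samples <- function(counts, samples) {
  stopifnot(is.data.frame(samples),
            all(c("sample", "arm") %in% names(samples)))
  ids <- setdiff(names(counts), "hairpin_id")
  if (anyDuplicated(samples$sample))
    abort("duplicate sample ids in sample sheet")
  missing <- setdiff(ids, samples$sample)
  if (length(missing) > 0)
    abort(paste0("samples in counts but not in sample sheet: ",
                 paste(missing, collapse = ", ")))
  bad_arm <- setdiff(unique(samples$arm), c("vehicle", "treatment"))
  if (length(bad_arm) > 0)
    abort(paste0("arm must be 'vehicle' or 'treatment', got: ",
                 paste(bad_arm, collapse = ", ")))
  samples[match(ids, samples$sample), , drop = FALSE]
}

## Random DNA strings of fixed length (vectorised).
random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  chars <- sample(c("A", "C", "G", "T"), n * len, replace = TRUE)
  apply(matrix(chars, nrow = n), 1, paste0, collapse = "")
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
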