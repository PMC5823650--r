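#' Estimate the negative-binomial dispersion of a screen
#'
#' Fits a single common dispersion phi (count variance mu + phi * mu^2)
#' shared by all hairpins, by maximizing the conditional negative-binomial
#' log-likelihood: counts are first equalized to a common library size
#' (scaled by size factors and rounded to pseudo-counts), then within each
#' arm the likelihood of the replicate counts conditional on their sum —
#' which is free of the hairpin's abundance — is summed over hairpins and
#' maximized by a one-dimensional search of phi over [1e-6, 10].
#'
#' Replication is required: conditioning removes the mean, so an arm with a
#' single sample carries no dispersion information. Unreplicated designs
#' must supply a fixed dispersion to the testing step instead (e.g.
#' `dispersion = 0.2` in [test_hairpins()], or `fixed_dispersion` in a run
#' configuration).
#'
#' With `tagwise = TRUE`, per-hairpin method-of-moments estimates are
#' shrunk toward the common value with a fixed prior weight (in units of
#' residual degrees of freedom), giving a light-weight empirical-Bayes
#' tagwise dispersion.
#'
#' @param counts Wide count tibble.
#' @param samples Sample sheet tibble (`sample`, `arm`).
#' @param size_factors Optional tibble from [normalize_sizes()]; computed
#'   with the `median_ratio` method when absent.
#' @param tagwise Also compute shrunken per-hairpin dispersions.
#' @param prior_weight Prior weight (pseudo-degrees-of-freedom) pulling
#'   tagwise estimates toward the common value.
#' @return A `dispersion_fit` object with elements `common`, `tagwise`
#'   (named vector or NULL), `method`, `n_hairpins`. Supports [tidy()] and
#'   [glance()].
#' @export
estimate_dispersion <- function(counts, samples, size_factors = NULL,
                                tagwise = FALSE, prior_weight = 20) {
  samples <- align_samples(counts, samples)
  reps <- table(samples$arm)
  if (any(reps < 2))
    abort(paste0(
      "dispersion estimation needs >= 2 replicates per arm; ",
      "this design has ", paste(sprintf("%s=%d", names(reps), reps),
                                collapse = ", "),
      ". Supply a fixed dispersion instead (e.g. dispersion = 0.2)."))
  if (is.null(size_factors)) size_factors <- normalize_sizes(counts)
  m <- counts_matrix(counts)
  sf <- size_factors$size_factor[match(colnames(m), size_factors$sample)]
  y <- round(sweep(m, 2, sf, "/"))   # pseudo-counts at the common size

  arms <- split(seq_len(ncol(y)), samples$arm)
  negll <- function(log_phi) {
    r <- 1 / exp(log_phi)
    ll <- 0
    for (cols in arms) {
      ya <- y[, cols, drop = FALSE]
      ma <- length(cols)
      s <- rowSums(ya)
      ll <- ll + sum(lgamma(ya + r)) - nrow(ya) * ma * lgamma(r) +
        nrow(ya) * lgamma(ma * r) - sum(lgamma(s + ma * r))
    }
    -ll
  }
  opt <- optimise(negll, interval = log(c(1e-6, 10)), tol = 1e-6)
  common <- exp(opt$minimum)

  tw <- NULL
  if (tagwise) {
    phi_mom <- moment_dispersion(y, samples$arm)
    df <- sum(vapply(arms, length, 0L)) - length(arms)
    tw <- pmax(0, (prior_weight * common + df * phi_mom) /
                 (prior_weight + df))
    names(tw) <- rownames(y)
  }
  structure(list(common = common, tagwise = tw,
                 method = if (tagwise) "CML+tagwise" else "CML",
                 n_hairpins = nrow(y)),
            class = "dispersion_fit")
}

## Method-of-moments phi per hairpin, pooled across arms:
## var = mu + phi mu^2  =>  phi = (s^2 - mu)/mu^2, truncated at 0.
moment_dispersion <- function(y, arm) {
  arms <- split(seq_len(ncol(y)), arm)
  num <- 0
  den <- 0
  for (cols in arms) {
    ya <- y[, cols, drop = FALSE]
    mu <- rowMeans(ya)
    s2 <- apply(ya, 1, var)
    w <- length(cols) - 1
    num <- num + w * (s2 - mu) / pmax(mu, 1e-8)^2
    den <- den + w
  }
  pmax(0, num / den)
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat(sprintf("<dispersion_fit> common phi = %.4g (%s, %d hairpins)\n",
              x$common, x$method, x$n_hairpins))
  invisible(x)
}

#' @rdname estimate_dispersion
#' @param x A `dispersion_fit`.
#' @param ... Unused.
#' @method tidy dispersion_fit
#' @export
tidy.dispersion_fit <- function(x, ...) {
  if (is.null(x$tagwise))
    return(tibble::tibble(hairpin_id = character(0), phi = numeric(0)))
  tibble::tibble(hairpin_id = names(x$tagwise), phi = unname(x$tagwise))
}

#' @rdname estimate_dispersion
#' @method glance dispersion_fit
#' @export
glance.dispersion_fit <- function(x, ...) {
  tibble::tibble(common_dispersion = x$common, method = x$method,
                 n_hairpins = x$n_hairpins)
}
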