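#' Conditional negative-binomial exact test for two-arm count data
#'
#' Tests differential representation of a hairpin between arms. With
#' library sizes equalized, the arm sums `t` (treatment, over `n_treat`
#' replicates) and `c` (vehicle, over `n_ctrl` replicates) are
#' negative-binomial with sizes `n_treat/phi` and `n_ctrl/phi`; conditional
#' on `n = t + c` the distribution of `t` under the null is free of the
#' hairpin's abundance and can be enumerated exactly. At `phi = 0` it
#' degenerates to Binomial(n, n_treat / (n_treat + n_ctrl)).
#'
#' One-sided p-values are tail sums including the observed outcome
#' (`p_dep = P(T <= t | n)`, `p_enr = P(T >= t | n)`, so
#' `p_dep + p_enr >= 1`); the two-sided p-value sums the probability of
#' every outcome no more probable than the observed one (within relative
#' tolerance 1e-10, so floating-point ties count as ties). The degenerate
#' case `t = c = 0` carries no information and returns p = 1.
#'
#' @param t,c Non-negative integer arm sums (vectors are tested pairwise).
#' @param phi Negative-binomial dispersion (>= 0; 0 = Poisson/binomial).
#' @param n_treat,n_ctrl Number of replicates summed into `t` and `c`.
#' @return A tibble with columns `p_two`, `p_dep`, `p_enr`.
#' @examples
#' nb_exact_test(0, 10, phi = 0)          # p_dep = 2^-10
#' nb_exact_test(5, 20, phi = 0.1)
#' @export
nb_exact_test <- function(t, c, phi, n_treat = 1L, n_ctrl = 1L) {
  stopifnot(length(t) == length(c), phi >= 0,
            n_treat >= 1, n_ctrl >= 1)
  if (any(t < 0) || any(c < 0) || any(t != round(t)) || any(c != round(c)))
    abort("t and c must be non-negative integers")
  res <- purrr::map2(t, c, function(ti, ci)
    exact_test_one(ti, ci, phi, n_treat, n_ctrl))
  tibble::tibble(p_two = vapply(res, `[[`, 0, "p_two"),
                 p_dep = vapply(res, `[[`, 0, "p_dep"),
                 p_enr = vapply(res, `[[`, 0, "p_enr"))
}

## log pmf of T | T + C = n under the null, over x = 0..n.
cond_log_pmf <- function(n, phi, n_treat, n_ctrl) {
  x <- 0:n
  lw <- if (phi == 0) {
    dbinom(x, n, n_treat / (n_treat + n_ctrl), log = TRUE)
  } else {
    r_t <- n_treat / phi
    r_c <- n_ctrl / phi
    w <- lgamma(x + r_t) - lfactorial(x) +
      lgamma(n - x + r_c) - lfactorial(n - x)
    w - logsumexp(w)
  }
  lw
}

exact_test_one <- function(t, c, phi, n_treat, n_ctrl) {
  n <- t + c
  if (n == 0) return(list(p_two = 1, p_dep = 1, p_enr = 1))
  p <- exp(cond_log_pmf(n, phi, n_treat, n_ctrl))
  p <- p / sum(p)
  obs <- p[t + 1L]
  list(p_two = min(1, sum(p[p <= obs * (1 + 1e-10)])),
       p_dep = min(1, sum(p[seq_len(t + 1L)])),
       p_enr = min(1, sum(p[(t + 1L):(n + 1L)])))
}
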