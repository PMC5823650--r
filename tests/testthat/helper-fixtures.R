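# Shared fixture builders: tiny in-code screens and an independent oracle
# for the conditional exact test.

# Small deterministic screen; overrides merge into a fast desk default.
tiny_config <- function(...) {
  defaults <- list(n_genes = 60, hairpins_per_gene_range = c(3L, 5L),
                   guide_length = 12L, frac_unannotated = 0.05,
                   seq_depth_per_sample = 3e4, seq_dispersion = 0.05,
                   rng_seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

tiny_screen <- function(...) {
  cfg <- tiny_config(...)
  simulate_screen(simulate_library(cfg), cfg)
}

# A three-guide library exercising the exact / 1-mismatch / ambiguous paths.
toy_library <- function() {
  tibble::tibble(
    hairpin_id = c("h1", "h2", "h3"),
    guide = c("AAAAAAAA", "AAAAAAAT", "CCCCCCCC"),
    gene = c("G1", "G1", "G2"))
}

# Independent oracle for the conditional exact test: normalizes the product
# of the two arms' negative-binomial pmfs directly via dnbinom/dbinom
# (an arbitrary mean mu must cancel out of the conditional distribution).
oracle_cond_pmf <- function(n, phi, n_treat, n_ctrl, mu = 7.3) {
  x <- 0:n
  w <- if (phi == 0) {
    dbinom(x, n, n_treat / (n_treat + n_ctrl))
  } else {
    dnbinom(x, size = n_treat / phi, mu = n_treat * mu) *
      dnbinom(n - x, size = n_ctrl / phi, mu = n_ctrl * mu)
  }
  w / sum(w)
}

oracle_exact_test <- function(t, c, phi, n_treat = 1, n_ctrl = 1) {
  n <- t + c
  if (n == 0) return(list(p_two = 1, p_dep = 1, p_enr = 1))
  p <- oracle_cond_pmf(n, phi, n_treat, n_ctrl)
  obs <- p[t + 1]
  list(p_two = min(1, sum(p[p <= obs * (1 + 1e-10)])),
       p_dep = sum(p[seq_len(t + 1)]),
       p_enr = sum(p[(t + 1):(n + 1)]))
}

# Hand step-up BH: q_i = min_{j >= i} p_(j) * n / j, capped at 1.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
  q[order(o)]
}

# Read a FASTQ as a tibble of 4-line records.
read_fastq_records <- function(path) {
  lines <- readLines(path)
  tibble::tibble(id = lines[c(TRUE, FALSE, FALSE, FALSE)],
                 seq = lines[c(FALSE, TRUE, FALSE, FALSE)],
                 qual = lines[c(FALSE, FALSE, FALSE, TRUE)])
}
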