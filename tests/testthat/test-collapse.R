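test_that("weighted Z combination matches its closed forms", {
  # single member passes through
  expect_equal(stouffer_weighted_z(0.05)$p, 0.05, tolerance = 1e-12)
  expect_equal(stouffer_weighted_z(0.3, w = 2.7)$p, 0.3, tolerance = 1e-12)
  # two identical members: Zw = qnorm(0.95) * sqrt(2)
  res <- stouffer_weighted_z(c(0.05, 0.05))
  expect_equal(res$z, qnorm(0.95) * sqrt(2), tolerance = 1e-10)
  expect_lt(abs(res$p - 0.0100), 1e-4)
  # four members, equal weights, against the direct formula
  p4 <- c(0.01, 0.04, 0.2, 0.5)
  res <- stouffer_weighted_z(p4)
  expect_equal(res$z, sum(qnorm(1 - p4)) / 2, tolerance = 1e-10)
  expect_equal(res$p, 1 - pnorm(sum(qnorm(1 - p4)) / 2), tolerance = 1e-10)
  expect_lt(abs(res$p - 0.00696), 1e-4)
  # a zero weight removes the member
  expect_equal(stouffer_weighted_z(c(0.05, 0.9), w = c(1, 0))$p, 0.05,
               tolerance = 1e-12)
})

test_that("weight rescaling leaves the combination unchanged", {
  withr::with_seed(41, {
    for (i in 1:10) {
      p <- runif(sample(2:6, 1))
      w <- runif(length(p), 0.1, 2)
      a <- stouffer_weighted_z(p, w)
      b <- stouffer_weighted_z(p, 7 * w)
      expect_equal(a$z, b$z, tolerance = 1e-14)
      expect_equal(a$p, b$p, tolerance = 1e-14)
    }
  })
})

test_that("consistent evidence accumulates with more hairpins", {
  p0 <- 0.2
  combined <- vapply(1:6, function(m)
    stouffer_weighted_z(rep(p0, m))$p, 0)
  expect_true(all(diff(combined) < 0))
})

test_that("degenerate weights are rejected", {
  expect_error(stouffer_weighted_z(c(0.1, 0.2), w = c(0, 0)), "zero")
  expect_error(stouffer_weighted_z(c(0.1, 0.2), w = c(1, -1)),
               "non-negative")
})

test_that("E-values are the Bonferroni expectation", {
  expect_equal(compute_evalue(0.05, 1000), 50)
  expect_equal(compute_evalue(1e-5, 50000), 0.5)
  expect_equal(compute_evalue(0, 10), 0)
})

fake_stats <- function(df) {
  defaults <- list(mean_vehicle = 100, mean_treatment = 50,
                   filtered = NA_character_, direction = "depleted")
  for (col in names(defaults))
    if (!col %in% names(df)) df[[col]] <- defaults[[col]]
  if (!"q" %in% names(df)) df$q <- df$p_dep
  df
}

test_that("gene collapse keeps identities, E-values and ordering", {
  st <- fake_stats(tibble::tibble(
    hairpin_id = c("a1", "b1", "b2"),
    gene = c("A", "B", "B"),
    p_dep = c(0.02, 0.3, 0.4),
    p_enr = 1 - c(0.02, 0.3, 0.4)))
  res <- collapse_genes(st)
  expect_equal(res$gene, c("A", "B"))           # sorted by P_wZP
  a <- res[res$gene == "A", ]
  expect_equal(a$k, 1L)
  expect_equal(a$P_wZP, 0.02, tolerance = 1e-12)
  expect_equal(a$E, 0.02 * 2, tolerance = 1e-12)  # two genes tested
  expect_equal(attr(res, "n_genes"), 2L)
  expect_equal(res$Zw[2], stouffer_weighted_z(c(0.3, 0.4))$z)
})

test_that("filtered hairpins and fully-filtered genes drop out", {
  st <- fake_stats(tibble::tibble(
    hairpin_id = c("a1", "a2", "b1", "u1"),
    gene = c("A", "A", "B", unannotated_sentinel()),
    p_dep = c(0.01, 0.5, 0.2, 0.001),
    p_enr = 1 - c(0.01, 0.5, 0.2, 0.001),
    filtered = c(NA, "medC_gt_maxT", "low_count", "unannotated")))
  res <- collapse_genes(st)
  expect_equal(res$gene, "A")
  expect_equal(res$k, 1L)
  expect_equal(res$P_wZP, 0.01, tolerance = 1e-12)
  expect_equal(res$E, 0.01)                     # one gene tested
  expect_equal(nrow(collapse_genes(st[0, ])), 0)
})

test_that("the literal q-combination and abundance weighting run end to end", {
  st <- fake_stats(tibble::tibble(
    hairpin_id = c("a1", "a2", "b1", "b2"),
    gene = c("A", "A", "B", "B"),
    p_dep = c(0.01, 0.02, 0.6, 0.7),
    p_enr = 1 - c(0.01, 0.02, 0.6, 0.7),
    q = c(0.04, 0.04, 0.9, 0.9),
    direction = c("depleted", "depleted", "enriched", "enriched"),
    mean_vehicle = c(100, 400, 100, 100),
    mean_treatment = c(50, 200, 150, 150)))
  res_q <- collapse_genes(st, mode = "q")
  expect_equal(res_q$P_wZP[res_q$gene == "A"],
               stouffer_weighted_z(c(0.04, 0.04))$p, tolerance = 1e-12)
  # enriched hairpins enter the depletion collapse as 1 - q
  expect_equal(res_q$P_wZP[res_q$gene == "B"],
               stouffer_weighted_z(c(0.1, 0.1))$p, tolerance = 1e-10)
  res_w <- collapse_genes(st, weighting = "sqrt_mean_count")
  wA <- sqrt(c(75, 300))
  expect_equal(res_w$Zw[res_w$gene == "A"],
               stouffer_weighted_z(c(0.01, 0.02), wA)$z, tolerance = 1e-12)
})

test_that("the enrichment direction is collapsed symmetrically", {
  st <- fake_stats(tibble::tibble(
    hairpin_id = c("a1", "a2"), gene = c("A", "A"),
    p_dep = c(0.9, 0.95), p_enr = c(0.1, 0.05),
    direction = "enriched"))
  res <- collapse_genes(st, direction = "enriched")
  expect_equal(res$P_wZP, stouffer_weighted_z(c(0.1, 0.05))$p,
               tolerance = 1e-12)
  expect_equal(res$direction, "enriched")
})
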