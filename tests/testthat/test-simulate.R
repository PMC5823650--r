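test_that("library geometry follows the configuration", {
  cfg <- tiny_config(n_genes = 100, hairpins_per_gene_range = c(3L, 3L),
                     frac_unannotated = 0.1)
  lib <- simulate_library(cfg)
  ann <- lib[lib$gene != unannotated_sentinel(), ]
  expect_equal(nrow(ann), 300)
  expect_equal(sum(lib$gene == unannotated_sentinel()), 30)
  expect_false(anyDuplicated(lib$hairpin_id) > 0)
  expect_false(anyDuplicated(lib$guide) > 0)
  expect_true(all(nchar(lib$guide) == cfg$guide_length))
  expect_true(all(grepl("^[ACGT]+$", lib$guide)))
  # every annotated gene keeps at least one hairpin
  expect_equal(dplyr::n_distinct(ann$gene), 100)
})

test_that("infeasible guide uniqueness is an explicit error", {
  cfg <- tiny_config(n_genes = 25000, hairpins_per_gene_range = c(3L, 3L),
                     guide_length = 8L, frac_unannotated = 0)
  expect_error(simulate_library(cfg), "unique guides")
  # guide lengths below the sequence-complexity floor are rejected earlier
  expect_error(sim_config(guide_length = 2), "guide_length")
})

test_that("the same configuration and seed reproduce identical bytes", {
  cfg <- tiny_config()
  lib1 <- simulate_library(cfg)
  lib2 <- simulate_library(cfg)
  expect_identical(lib1, lib2)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_library(lib1, tempfile(), fasta = f1)
  write_library(lib2, tempfile(), fasta = f2)
  expect_identical(readLines(f1), readLines(f2))
  sim1 <- simulate_screen(lib1, cfg)
  sim2 <- simulate_screen(lib2, cfg)
  expect_identical(sim1$counts, sim2$counts)
  expect_identical(sim1$truth_hairpins, sim2$truth_hairpins)
})

test_that("planted truth satisfies its class invariants", {
  sim <- tiny_screen(frac_essential = 0.1, frac_synthetic_lethal = 0.2,
                     frac_resistance = 0.05)
  th <- sim$truth_hairpins
  neutral <- th[th$class == "neutral", ]
  expect_true(all(neutral$vehicle_multiplier == 1))
  expect_true(all(neutral$treatment_multiplier == 1))
  sl <- th[th$class == "synthetic_lethal", ]
  expect_true(all(sl$vehicle_multiplier == 1))
  expect_true(all(sl$treatment_multiplier < 1))
  ess <- th[th$class == "essential", ]
  expect_true(all(ess$vehicle_multiplier < 1))
  expect_equal(ess$vehicle_multiplier, ess$treatment_multiplier)
  expect_equal(table(sim$truth_genes$class)[["synthetic_lethal"]],
               round(0.2 * 60))
})

test_that("a pure-null screen has unit expected arm ratio", {
  sim <- tiny_screen(seq_depth_per_sample = 1e6, seq_dispersion = 0)
  expect_true(all(sim$truth_hairpins$vehicle_multiplier == 1))
  expect_true(all(sim$truth_hairpins$treatment_multiplier == 1))
  m <- counts_matrix(sim$counts)
  arms <- sim$samples$arm
  ratio <- rowMeans(m[, arms == "treatment"]) / rowMeans(m[, arms == "vehicle"])
  expect_equal(mean(ratio), 1, tolerance = 0.01)
})

test_that("synthetic-lethal depletion converges to the planted fold", {
  # full knockdown, no sequencing noise beyond Poisson, deep sequencing:
  # the normalized treatment/vehicle ratio of SL hairpins approaches 1/4
  cfg <- tiny_config(n_genes = 500, hairpins_per_gene_range = c(3L, 3L),
                     frac_unannotated = 0, frac_synthetic_lethal = 0.02,
                     sl_depletion_fold = 4, seq_dispersion = 0,
                     knockdown_shape1 = 1e8, knockdown_shape2 = 1e-8,
                     initial_abundance_sigma = 0.3,
                     seq_depth_per_sample = 1e7, replicates_per_arm = 1L)
  sim <- simulate_screen(simulate_library(cfg), cfg)
  expect_true(all(sim$truth_hairpins$knockdown > 0.999))
  m <- counts_matrix(sim$counts)
  sf <- normalize_sizes(sim$counts, method = "total")
  norm <- sweep(m, 2, sf$size_factor[match(colnames(m), sf$sample)], "/")
  arms <- sim$samples$arm
  sl <- sim$truth_hairpins$class == "synthetic_lethal"
  ratio <- norm[, arms == "treatment"] / norm[, arms == "vehicle"]
  expect_equal(mean(ratio[sl]), 1 / 4, tolerance = 0.05)
})

test_that("essential hairpins drop out of both arms", {
  sim <- tiny_screen(frac_essential = 0.2, essential_fitness_cost = 0.3,
                     seq_depth_per_sample = 2e5)
  m <- counts_matrix(sim$counts)
  arms <- sim$samples$arm
  ess <- sim$truth_hairpins$class == "essential"
  neu <- sim$truth_hairpins$class == "neutral"
  for (arm in c("vehicle", "treatment")) {
    cols <- arms == arm
    expect_lt(mean(m[ess, cols]), mean(m[neu, cols]))
  }
})

test_that("stronger planted folds deplete SL hairpins more, on average", {
  mean_sl_ratio <- function(fold, seed) {
    sim <- tiny_screen(frac_synthetic_lethal = 0.2, sl_depletion_fold = fold,
                       frac_unannotated = 0, rng_seed = seed,
                       seq_depth_per_sample = 2e4)
    m <- counts_matrix(sim$counts)
    arms <- sim$samples$arm
    sl <- sim$truth_hairpins$class == "synthetic_lethal"
    (mean(m[sl, arms == "treatment"]) + 0.5) /
      (mean(m[sl, arms == "vehicle"]) + 0.5)
  }
  seeds <- 1:20
  for (pair in list(c(1, 2), c(2, 4), c(4, 8))) {
    lo <- mean(vapply(seeds, function(s) mean_sl_ratio(pair[1], s), 0))
    hi <- mean(vapply(seeds, function(s) mean_sl_ratio(pair[2], s), 0))
    expect_gt(lo, hi)
  }
})

test_that("shared class assignments reproduce across screens", {
  cfg1 <- tiny_config(frac_synthetic_lethal = 0.2, rng_seed = 5L)
  lib <- simulate_library(cfg1)
  s1 <- simulate_screen(lib, cfg1, screen_id = "a")
  cfg2 <- tiny_config(frac_synthetic_lethal = 0.2, rng_seed = 6L)
  s2 <- simulate_screen(lib, cfg2, screen_id = "b", classes = s1$truth_genes)
  expect_identical(s1$truth_genes, s2$truth_genes)
  expect_false(identical(s1$counts, s2$counts))
})

test_that("tidiers expose the simulation as tables", {
  sim <- tiny_screen(frac_essential = 0.1)
  long <- tidy(sim)
  expect_equal(nrow(long), nrow(sim$counts) * nrow(sim$samples))
  expect_true(all(c("hairpin_id", "gene", "class", "arm", "count") %in%
                    names(long)))
  g <- glance(sim)
  expect_equal(g$n_essential, round(0.1 * 60))
  expect_equal(g$total_reads, sum(counts_matrix(sim$counts)))
})
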