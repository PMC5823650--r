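#' Configuration for a simulated pooled shRNA screen
#'
#' Bundles every tunable of the screen simulator: library geometry, planted
#' gene-class fractions and effect sizes, the selection and treatment
#' phases, sequencing depth and overdispersion, and the random seed. The
#' defaults describe a desk-scale dropout screen: 2,000 genes with 3-5
#' hairpins each, two replicates per arm, 2e6 reads per sample, and a drug
#' dose killing 80% of the population (an IC80 analog).
#'
#' Planted classes: `essential` genes lose fitness in both arms during the
#' puromycin selection/expansion phase; `synthetic_lethal` genes are
#' depleted only in the treatment arm, by `sl_depletion_fold` at knockdown
#' efficiency 1 (scaled down for weaker hairpins); `resistance` genes are
#' enriched in the treatment arm by `resistance_fold`. All remaining genes
#' are neutral. Because pooled-screen readout is compositional, the uniform
#' `drug_population_kill` cancels after depth normalization; synthetic
#' lethality is planted as extra depletion beyond that uniform kill.
#'
#' @param n_genes Number of annotated genes in the library.
#' @param hairpins_per_gene_range Integer interval; hairpins per gene drawn
#'   uniformly from it.
#' @param guide_length Guide length in nucleotides.
#' @param frac_unannotated Extra hairpins targeting unannotated transcripts,
#'   as a fraction of the annotated hairpin total (they exercise the
#'   annotation filter).
#' @param frac_essential,frac_synthetic_lethal,frac_resistance Fractions of
#'   genes per planted class; must sum to at most 1.
#' @param sl_depletion_fold Total extra depletion fold in the treatment arm
#'   for a synthetic-lethal hairpin at knockdown efficiency 1 (>= 1).
#' @param resistance_fold Enrichment fold in the treatment arm for a
#'   resistance hairpin at knockdown efficiency 1 (>= 1).
#' @param essential_fitness_cost Per-doubling selection coefficient for
#'   essential-gene hairpins during the selection phase.
#' @param selection_doublings Population doublings in the puromycin
#'   selection/expansion phase.
#' @param treatment_doublings Population doublings during the 72h treatment
#'   window; neutral growth shared by all hairpins (compositionally
#'   invisible), kept for completeness of the phase description.
#' @param drug_population_kill Fraction of the treatment-arm population
#'   killed uniformly by the drug, in [0, 1).
#' @param knockdown_shape1,knockdown_shape2 Beta parameters of the
#'   per-hairpin knockdown-efficiency distribution. The Beta(5, 2) default
#'   makes most hairpins effective with an occasional weak one, the pattern
#'   the weighted-Z collapse must tolerate.
#' @param initial_abundance_sigma Log-scale standard deviation of initial
#'   hairpin abundance after transduction.
#' @param seq_depth_per_sample Expected sequencing reads per sample.
#' @param seq_dispersion Negative-binomial dispersion of sequencing counts
#'   (variance mu + phi * mu^2); 0 gives Poisson counts.
#' @param replicates_per_arm Samples per arm.
#' @param junk_fraction Fraction of adapter-less junk reads injected when
#'   emitting FASTQ.
#' @param read_length Read length for emitted FASTQ records.
#' @param rng_seed Integer seed; the same configuration and seed reproduce
#'   the library, counts, truth and FASTQ byte-for-byte.
#'
#' @return A `sim_config` object (a validated named list).
#' @examples
#' cfg <- sim_config(n_genes = 50, seq_depth_per_sample = 1e4)
#' cfg$frac_synthetic_lethal
#' @export
sim_config <- function(n_genes = 2000,
                       hairpins_per_gene_range = c(3L, 5L),
                       guide_length = 21L,
                       frac_unannotated = 0.02,
                       frac_essential = 0,
                       frac_synthetic_lethal = 0,
                       frac_resistance = 0,
                       sl_depletion_fold = 4,
                       resistance_fold = 2,
                       essential_fitness_cost = 0.2,
                       selection_doublings = 10L,
                       treatment_doublings = 2L,
                       drug_population_kill = 0.8,
                       knockdown_shape1 = 5,
                       knockdown_shape2 = 2,
                       initial_abundance_sigma = 0.5,
                       seq_depth_per_sample = 2e6,
                       seq_dispersion = 0.1,
                       replicates_per_arm = 2L,
                       junk_fraction = 0,
                       read_length = 50L,
                       rng_seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    hairpins_per_gene_range = as.integer(hairpins_per_gene_range),
    guide_length = as.integer(guide_length),
    frac_unannotated = frac_unannotated,
    frac_essential = frac_essential,
    frac_synthetic_lethal = frac_synthetic_lethal,
    frac_resistance = frac_resistance,
    sl_depletion_fold = sl_depletion_fold,
    resistance_fold = resistance_fold,
    essential_fitness_cost = essential_fitness_cost,
    selection_doublings = as.integer(selection_doublings),
    treatment_doublings = as.integer(treatment_doublings),
    drug_population_kill = drug_population_kill,
    knockdown_shape1 = knockdown_shape1,
    knockdown_shape2 = knockdown_shape2,
    initial_abundance_sigma = initial_abundance_sigma,
    seq_depth_per_sample = seq_depth_per_sample,
    seq_dispersion = seq_dispersion,
    replicates_per_arm = as.integer(replicates_per_arm),
    junk_fraction = junk_fraction,
    read_length = as.integer(read_length),
    rng_seed = as.integer(rng_seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 2) abort("n_genes must be >= 2")
  r <- cfg$hairpins_per_gene_range
  if (length(r) != 2 || any(r < 1) || r[1] > r[2])
    abort("hairpins_per_gene_range must be an increasing interval of counts >= 1")
  if (cfg$guide_length < 8) abort("guide_length must be >= 8")
  fr <- c(cfg$frac_essential, cfg$frac_synthetic_lethal, cfg$frac_resistance)
  if (any(fr < 0) || sum(fr) > 1)
    abort("class fractions must be non-negative and sum to <= 1")
  if (cfg$frac_unannotated < 0) abort("frac_unannotated must be >= 0")
  if (cfg$sl_depletion_fold < 1) abort("sl_depletion_fold must be >= 1")
  if (cfg$resistance_fold < 1) abort("resistance_fold must be >= 1")
  if (cfg$drug_population_kill < 0 || cfg$drug_population_kill >= 1)
    abort("drug_population_kill must lie in [0, 1)")
  if (cfg$seq_dispersion < 0) abort("seq_dispersion must be >= 0")
  if (cfg$junk_fraction < 0 || cfg$junk_fraction >= 1)
    abort("junk_fraction must lie in [0, 1)")
  if (cfg$replicates_per_arm < 1) abort("replicates_per_arm must be >= 1")
  if (cfg$seq_depth_per_sample < 1) abort("seq_depth_per_sample must be >= 1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d genes, %d-%d hairpins/gene, guide %d nt\n",
              x$n_genes, x$hairpins_per_gene_range[1],
              x$hairpins_per_gene_range[2], x$guide_length))
  cat(sprintf("  planted: %.1f%% essential, %.1f%% synthetic-lethal, %.1f%% resistance\n",
              100 * x$frac_essential, 100 * x$frac_synthetic_lethal,
              100 * x$frac_resistance))
  cat(sprintf("  depth %.3g/sample, dispersion %.3g, %d replicates/arm, seed %d\n",
              x$seq_depth_per_sample, x$seq_dispersion,
              x$replicates_per_arm, x$rng_seed))
  invisible(x)
}
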