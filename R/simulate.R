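#' Simulate a pooled shRNA library
#'
#' Draws a hairpin library with 3-5 (configurable) distinct guides per gene
#' plus a configured fraction of extra hairpins targeting unannotated
#' transcripts (labelled with [unannotated_sentinel()]), mimicking
#' genome-wide lentiviral shRNA libraries at reduced scale.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `hairpin_id`, `guide`, `gene`, sorted by
#'   `hairpin_id`. Guides are unique random DNA strings of the configured
#'   length.
#' @examples
#' lib <- simulate_library(sim_config(n_genes = 20))
#' dplyr::count(lib, gene == unannotated_sentinel())
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$rng_seed, {
    r <- config$hairpins_per_gene_range
    genes <- sprintf("GENE%05d", seq_len(config$n_genes))
    per_gene <- if (r[1] == r[2]) rep(r[1], config$n_genes) else
      sample(seq(r[1], r[2]), config$n_genes, replace = TRUE)
    gene_col <- rep(genes, per_gene)
    hp_idx <- unlist(lapply(per_gene, seq_len), use.names = FALSE)
    n_ann <- length(gene_col)
    n_unann <- round(config$frac_unannotated * n_ann)
    total <- n_ann + n_unann
    if (config$guide_length * log(4) < log(total))
      abort(sprintf(
        "cannot draw %d unique guides of length %d (only 4^%d exist)",
        total, config$guide_length, config$guide_length))
    guides <- random_dna(total, config$guide_length)
    while (anyDuplicated(guides) > 0) {
      dup <- duplicated(guides)
      guides[dup] <- random_dna(sum(dup), config$guide_length)
    }
    lib <- tibble::tibble(
      hairpin_id = c(paste0(gene_col, "_sh", hp_idx),
                     sprintf("UNANN%05d_sh1", seq_len(n_unann))),
      guide = guides,
      gene = c(gene_col, rep(unannotated_sentinel(), n_unann))
    )
    dplyr::arrange(lib, .data$hairpin_id)
  })
}

#' Simulate a pooled dropout screen with planted ground truth
#'
#' Runs the generative model of a two-arm (vehicle vs drug) pooled shRNA
#' screen over a library from [simulate_library()]:
#' log-normal initial hairpin abundance after low-MOI transduction; a
#' puromycin selection/expansion phase in which essential-gene hairpins pay
#' a per-doubling fitness cost in both arms; a treatment phase in which the
#' drug kills a uniform fraction of the treated population while
#' synthetic-lethal hairpins suffer extra depletion (gene fold scaled by the
#' hairpin's knockdown efficiency) and resistance hairpins are enriched;
#' and Gamma-Poisson (negative-binomial) sequencing of each replicate
#' sample at the configured depth and dispersion.
#'
#' @param library Library tibble from [simulate_library()].
#' @param config The same [sim_config()] used for the library.
#' @param screen_id Label for this screen (cell line analog); appears in
#'   the sample sheet.
#' @param classes Optional gene-class assignment to reuse (a tibble with
#'   `gene` and `class`, e.g. `truth_genes` from another screen): lets two
#'   screens share the same planted genes while drawing independent
#'   knockdown efficiencies, abundances and counts, as in a multi-cell-line
#'   design. When NULL (default), classes are drawn from the configured
#'   fractions.
#' @return A `screen_sim` object: list with `counts` (wide tibble,
#'   `hairpin_id` + one column per sample), `samples` (sample sheet:
#'   sample, arm, replicate, screen_id), `truth_genes` (gene, class),
#'   `truth_hairpins` (hairpin_id, gene, class, knockdown and realized
#'   per-arm abundance multipliers), plus the `library` and `config`.
#' @examples
#' cfg <- sim_config(n_genes = 50, frac_synthetic_lethal = 0.1,
#'                   seq_depth_per_sample = 1e4)
#' sim <- simulate_screen(simulate_library(cfg), cfg)
#' head(sim$counts)
#' @export
simulate_screen <- function(library, config, screen_id = "screen1",
                            classes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$rng_seed + 1L, {
    genes <- sort(unique(library$gene[library$gene != unannotated_sentinel()]))
    G <- length(genes)
    if (is.null(classes)) {
      n_ess <- round(config$frac_essential * G)
      n_sl <- round(config$frac_synthetic_lethal * G)
      n_res <- round(config$frac_resistance * G)
      shuffled <- sample(genes)
      class_of <- setNames(rep("neutral", G), genes)
      class_of[shuffled[seq_len(n_ess)]] <- "essential"
      class_of[shuffled[n_ess + seq_len(n_sl)]] <- "synthetic_lethal"
      class_of[shuffled[n_ess + n_sl + seq_len(n_res)]] <- "resistance"
    } else {
      stopifnot(all(c("gene", "class") %in% names(classes)),
                setequal(classes$gene, genes))
      class_of <- setNames(classes$class, classes$gene)[genes]
    }

    hp <- library
    hp$class <- ifelse(hp$gene == unannotated_sentinel(), "neutral",
                       class_of[hp$gene])
    n_hp <- nrow(hp)
    hp$knockdown <- rbeta(n_hp, config$knockdown_shape1, config$knockdown_shape2)

    a0 <- rlnorm(n_hp, meanlog = 0, sdlog = config$initial_abundance_sigma)
    # selection phase: essential hairpins depleted in BOTH arms
    sel_mult <- ifelse(
      hp$class == "essential",
      2^(-config$essential_fitness_cost * hp$knockdown * config$selection_doublings),
      1)
    a_sel <- a0 * sel_mult
    # treatment phase: both arms share neutral growth; the treated arm adds
    # a uniform drug kill plus hairpin-specific modifier effects
    growth <- 2^config$treatment_doublings
    treat_mod <- rep(1, n_hp)
    sl <- hp$class == "synthetic_lethal"
    rs <- hp$class == "resistance"
    treat_mod[sl] <- config$sl_depletion_fold^(-hp$knockdown[sl])
    treat_mod[rs] <- config$resistance_fold^(hp$knockdown[rs])
    a_veh <- a_sel * growth
    a_trt <- a_sel * growth * (1 - config$drug_population_kill) * treat_mod

    R <- config$replicates_per_arm
    sample_ids <- c(sprintf("%s_veh_rep%d", screen_id, seq_len(R)),
                    sprintf("%s_trt_rep%d", screen_id, seq_len(R)))
    arms <- rep(c("vehicle", "treatment"), each = R)
    abund <- cbind(matrix(a_veh, n_hp, R), matrix(a_trt, n_hp, R))
    cnt <- matrix(0L, n_hp, 2 * R, dimnames = list(hp$hairpin_id, sample_ids))
    for (j in seq_len(2 * R)) {
      mu <- config$seq_depth_per_sample * abund[, j] / sum(abund[, j])
      cnt[, j] <- if (config$seq_dispersion == 0) rpois(n_hp, mu)
                  else rnbinom(n_hp, size = 1 / config$seq_dispersion, mu = mu)
    }

    structure(list(
      counts = counts_tibble(cnt),
      samples = tibble::tibble(sample = sample_ids, arm = arms,
                               replicate = rep(seq_len(R), 2),
                               screen_id = screen_id),
      truth_genes = tibble::tibble(gene = genes,
                                   class = unname(class_of[genes])),
      truth_hairpins = tibble::tibble(
        hairpin_id = hp$hairpin_id, gene = hp$gene, class = hp$class,
        knockdown = hp$knockdown,
        # relative fitness effects; the uniform drug kill is excluded since
        # it cancels in the compositional readout
        vehicle_multiplier = sel_mult,
        treatment_multiplier = sel_mult * treat_mod),
      library = library,
      config = config,
      screen_id = screen_id
    ), class = "screen_sim")
  })
}

#' @export
print.screen_sim <- function(x, ...) {
  cat(sprintf("<screen_sim '%s'> %d hairpins x %d samples\n",
              x$screen_id, nrow(x$counts), nrow(x$samples)))
  cls <- table(x$truth_genes$class)
  cat("  gene classes:",
      paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
  invisible(x)
}
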