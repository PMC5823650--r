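---
title: "Methods: pooled shRNA dropout screens for drug synthetic lethality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled shRNA dropout screens for drug synthetic lethality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicscreen)
```

## The experimental design being modelled

A pooled shRNA synthetic-lethal screen asks which gene knockdowns kill
cells only in the presence of a drug. Cells are transduced with a
genome-wide lentiviral hairpin library at low multiplicity of infection
(about one integration per cell), selected in puromycin for roughly two
weeks — a phase that also purges hairpins against constitutively
essential genes — and then split into a vehicle arm and a drug arm dosed
near the IC80. After a short treatment window (72 h in the motivating
design) the hairpin inserts of each arm are amplified and sequenced. A
gene is synthetic lethal with the drug when its hairpins are
*underrepresented* in the drug arm relative to vehicle.

Two properties of this readout drive every modelling choice below:

* **It is compositional.** Sequencing measures relative, not absolute,
  abundance. A uniform population kill (the IC80 dose itself) rescales
  every hairpin equally and cancels after depth normalization; only
  *differential* depletion is observable.
* **Counts are overdispersed.** Replicate libraries vary more than
  Poisson sampling allows; we use the standard negative-binomial
  variance μ + φμ².

## Per-hairpin inference

### Normalization

`normalize_sizes()` offers total-count factors and median-of-ratios
factors (each sample's median ratio to the per-hairpin geometric mean,
over hairpins with all-positive counts). Median-of-ratios is the
default: in a depletion screen the drug arm loses reads asymmetrically,
and a median-based estimator is robust to the depleted minority. Factors
are rescaled to geometric mean 1 so the implied common library size is
the geometric mean of the observed sizes.

### The conditional exact test

For each hairpin, counts are scaled to the common library size, rounded
to pseudo-counts, and summed within arms to give `t` (treatment, over
`n_t` replicates) and `c` (vehicle, over `n_c`). Sums of i.i.d.
negative-binomial counts are negative binomial, so under the null the
conditional distribution of `t` given `n = t + c` is

$$P(T = x \mid n) \propto
  \frac{\Gamma(x + n_t/\varphi)}{x!}\,
  \frac{\Gamma(n - x + n_c/\varphi)}{(n-x)!},$$

which is free of the (unknown, hairpin-specific) abundance — the same
conditioning trick used by exact tests for RNA-seq. `nb_exact_test()`
enumerates this distribution directly. Choices worth recording:

* At φ = 0 the expression degenerates to Binomial(n, n_t/(n_t+n_c));
  the implementation switches to the binomial pmf explicitly rather than
  taking a numerical limit.
* One-sided p-values include the observed outcome in the tail
  (`p_dep = P(T ≤ t)`), so `p_dep + p_enr ≥ 1` and each one-sided p is
  conservative at the atom, the usual convention for discrete tests.
* The two-sided p sums the probability of every outcome whose pmf value
  is at most that of the observed outcome, with a relative tolerance of
  1e-10 so that floating-point ties (e.g. the exact symmetry at
  `t = c`) are counted as ties.
* `t = c = 0` carries no information and returns p = 1, log-fold-change
  0 by convention.
* Log2 fold-changes use a pseudo-count of 0.5 on each arm's mean
  normalized count; the sign of this fold-change defines the hairpin's
  direction (`logFC < 0` → depleted).

### Dispersion

The common dispersion is estimated by conditional maximum likelihood:
with counts equalized to the common library size, the likelihood of each
arm's replicate counts conditional on their sum depends only on φ, and
`estimate_dispersion()` maximizes the summed conditional log-likelihood
by a one-dimensional search of log φ over [10⁻⁶, 10]. On simulated
Poisson data the estimate collapses to the lower boundary (≈ 10⁻⁶), and
a planted φ of 0.2 is recovered within a few percent at 10⁴ hairpins
(both are tested, and the estimate is cross-checked against an
independent RNA-seq implementation of common-dispersion CML).

Conditioning removes all mean information, so an arm with one replicate
contributes nothing: unreplicated designs raise an explicit error rather
than falling back to a silent default, because a made-up φ would
invalidate every calibration statement downstream. Users who accept that
trade-off pass `dispersion = 0.2` (or any chosen value) explicitly. An
optional tagwise mode shrinks per-hairpin moment estimates toward the
common value with a fixed prior weight of 20 pseudo-degrees-of-freedom;
it is provided for exploration and not used by the default pipeline.

### Filters

Filters run in the pipeline's stated order — direction statistics are
computed for every hairpin first, then:

1. **Annotation filter.** Hairpins whose library record carries the
   `UNANNOTATED` sentinel are flagged and excluded from adjustment and
   collapse.
2. **Direction consistency (medC > maxT).** A hairpin called *enriched*
   is dropped when the median raw vehicle count exceeds the maximum raw
   treatment count; mirrored, a *depleted* call is dropped when the
   median raw treatment count exceeds the maximum raw vehicle count. The
   mirrored reading of the rule's "vice versa" is an interpretation made
   by this package: the rule is understood as a consistency check
   between the called direction and the raw counts, operating on raw
   (pre-normalization) values.
3. **Low-count filter** (optional, off by default): total raw count
   below 10. It is disabled by default to stay faithful to the stated
   pipeline; the exact test already loses power gracefully at low
   counts.

BH q-values (`bh_adjust()`, step-up with monotonicity) are computed over
the surviving hairpins only; filtered hairpins carry `q = NA`.

## Gene-level collapse

`collapse_genes()` combines each gene's surviving hairpins by weighted
Z-transformation: `z_i = Φ⁻¹(1 − p_i)`,
`Z_w = Σ w_i z_i / √(Σ w_i²)`, `P(wZP) = 1 − Φ(Z_w)`. Decisions:

* **What is combined.** The default combines one-sided *depletion*
  p-values. Combining BH q-values — the literal description of the
  original workflow — has no calibration guarantee (q-values are not
  uniform under the null), so the literal behaviour is retained behind
  `mode = "q"` (entering `q` for direction-consistent hairpins and
  `1 − q` otherwise) while the calibrated combination is the default.
  Both modes are tested. One-sided depletion inputs are the reading
  consistent with calling genes from hairpins underrepresented in the
  drug arm; the enrichment direction is available symmetrically for
  resistance screens.
* **Weights.** Equal weights by default; the original workflow's weight
  definition is not public, so a principled option
  (`sqrt_mean_count`, weight ∝ √mean normalized abundance, an
  information proxy) is provided. The statistic is invariant to weight
  rescaling; a zero weight removes a member exactly.
* **Clipping.** Inputs are clipped to [1e-300, 1 − 1e-16] so the normal
  quantile stays finite in double precision.
* **E-value.** Defined as `P(wZP) × G` with `G` the number of genes
  having at least one surviving hairpin — the expected count of false
  gene-level hits at that threshold (a Bonferroni expectation). The
  formula is an adopted definition, since the original reference leaves
  it unstated.

`call_hits()` applies a strict `P(wZP) < α` threshold (α = 0.05 default)
in the depleted direction; `intersect_screens()` intersects two or more
screens' hit lists on the case-sensitive gene symbol and reports each
screen's P(wZP) per common gene, ordered by the worst screen. Symbols
(not transcript identifiers) are the identity for intersection because
the library table is the single source of gene labels.

## The simulator

`simulate_library()` and `simulate_screen()` generate the study
conditions end to end: a library of 3–5 random 21-nt guides per gene
(plus ~2% extra hairpins labelled `UNANNOTATED` to exercise the
annotation filter); log-normal initial abundance (σ = 0.5, the spread of
a well-made pool after transduction); a selection phase of 10 doublings
in which essential-gene hairpins pay a per-doubling fitness cost of 0.2
scaled by knockdown efficiency, in *both* arms; a treatment phase in
which the drug kills 80% of the treated population uniformly (the IC80
analog) while synthetic-lethal hairpins suffer extra depletion —
`sl_depletion_fold^(-knockdown)`, i.e. the configured fold is the total
extra depletion over the 72-h window at full knockdown — and resistance
hairpins are enriched analogously. Knockdown efficiencies are
Beta(5, 2): most hairpins are effective, a minority are weak, which is
exactly the pattern the weighted-Z collapse must tolerate (one weak
hairpin should not veto an otherwise consistent gene). Sequencing draws
Gamma–Poisson counts at 2×10⁶ reads per sample with dispersion 0.1, two
replicates per arm.

Because the readout is compositional, the uniform kill is invisible by
construction; synthetic lethality is planted as depletion *beyond* the
uniform kill, and the recorded truth multipliers exclude the kill for
the same reason.

`emit_fastq()` writes read-level data (adapter + guide + random tail at
constant Phred 40, plus a configurable fraction of adapter-less junk
reads) and `count_reads()` inverts it exactly when no junk or mismatches
are present — an identity that is tested. The read layout is an
invented, minimal one: real amplicon chemistry is richer, but the
counting stage only assumes "guide at a fixed offset after an adapter".

What the simulator deliberately does **not** model: PCR amplification
bias, multiple integrations per cell (MOI > 1), hairpin off-target
effects, cell-cycle or density dependence, and correlated dispersion
between arms. Passing tests therefore demonstrate that the inference
machinery is correct and calibrated *under the stated count model*, not
that real screens are free of these artifacts.

## Numerical and testing choices

Problem sizes in the test-suite and acceptance script are the package's
desk-scale preset: 2,000 genes × 4 hairpins (8,000 annotated hairpins),
2 replicates per arm, 2×10⁶ reads per sample — large enough for stable
fractions (null calibration bands of 3–7% at α = 5%) and small enough to
run in seconds. Specific numerical conventions:

* guide uniqueness is feasibility-checked (`4^L` against the requested
  library size) before sampling, with rejection resampling of
  duplicates;
* the guide index resolves queries by best stratum (exact before
  1-substitution neighborhood) and reports any stratum tie as
  ambiguous — ambiguous reads are never counted;
* mean read quality is the mean Phred score over the whole read;
  adapter search is an exact substring scan, first occurrence;
* all simulation entry points take integer seeds and are byte-stable:
  identical configuration and seed reproduce identical libraries,
  counts, truth tables and FASTQ files; pipeline output TSVs are
  likewise byte-stable (the run log contains timings and is exempt).

## Known limitations

* The exact test treats replicates through their arm sums; per-replicate
  variation enters only through the dispersion estimate. Strongly
  unbalanced replicate quality is better served by GLM frameworks, which
  are out of scope here.
* Combining hairpins assumes their p-values are independent under the
  null; hairpins sharing off-target families violate this and are not
  modelled.
* The medC > maxT rule is a hard filter; near-threshold hairpins can
  flip between runs of deeply resequenced libraries.
* E-values inherit the accuracy of P(wZP) in the extreme tail, where
  the normal approximation of the weighted Z is least reliable.
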