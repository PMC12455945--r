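---
title: "Restriction-tag urobiome profiling and SIRS risk modeling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restriction-tag urobiome profiling and SIRS risk modeling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urotag)
```

# The problem

Low-biomass body sites such as renal pelvis urine carry microbial
communities that conventional shotgun metagenomics struggles to profile:
input DNA is scarce and contamination can dominate. Restriction-tag
profiling (the 2bRAD-M strategy) sidesteps this by sequencing only the
fixed-length fragments that a type-IIB restriction enzyme excises around
its recognition sites, and identifying species through tags that are
*unique* to one species in a reference database. `urotag` implements that
profiling chain and the downstream statistics used to relate the urobiome
of kidney-stone patients to postoperative systemic inflammatory response
syndrome (SIRS), together with a synthetic-data generator so that every
stage can be exercised and validated without patient data.

# Marker database and profiler

**In-silico digestion.** A type-IIB enzyme is described by its (possibly
degenerate) recognition pattern and two flank widths; every digestion
product has fixed length `flank_left + site + flank_right`. The default
models BcgI (`CGA-N6-TGC`, 12-nt flanks, 36-nt tags), the standard enzyme
for this assay; both strands are scanned and each tag is canonicalized as
the lexicographic minimum of itself and its reverse complement, so a genome
and its reverse complement digest identically. Windows truncated by contig
ends or containing `N` are dropped: the profiler matches reads exactly, and
a tag that cannot be matched exactly carries no information. Tags observed
in two or more species are removed from all species; what remains are the
species-unique markers, with `T_i` denoting species *i*'s theoretical
marker count.

**Read assignment and the G score.** Reads are assigned to species by exact
canonical-tag lookup (marker sets are disjoint, so a read maps to at most
one species). For each species in a sample the profiler records `S_i`
(reads on its markers) and `t_i` (distinct markers hit). False-positive
species calls in low-biomass samples typically show many reads piled on
one or two markers; the G score penalizes exactly that pattern. The
default convention is

$$G_i = \sqrt{S_i \times t_i},$$

with the plain product `S_i * t_i` available as a mode. Species with
`G >= 5` (boundary retained) are kept. Relative abundance is
marker-normalized:

$$a_i = \frac{S_i / T_i}{\sum_j S_j / T_j},$$

so species with larger marker complements are not inflated. Species called
in negative controls are flagged as putative reagent/environmental
contaminants, removed, and the profile renormalized; the screen reports the
overlap with clinical samples, which may legitimately be empty.

**Numerical choices.** Matching is exact — no mismatch tolerance — because
the assay defines no alignment model; sequencing error is represented in
the generator instead, where an errored 36-mer simply fails lookup and
slightly reduces effective depth without biasing composition. Reads shorter
than the tag length or containing `N` are skipped and counted, never
errors.

# Synthetic-data generator

The generator is a first-class module: it defines the conditions under
which the pipeline's statistical behavior is demonstrated.

* **Genomes**: random backgrounds are patched until free of spurious
  recognition sites, then exact site instances are planted at spaced
  positions; a truth ledger records every planted tag. Optionally a tag
  window is copied between species pairs to create known cross-species
  collisions for the database-construction path.
* **Communities**: a log-normal base composition (`sigma_species = 1`, the
  standard rank-abundance convention in microbiome simulation); planted
  differential species receive signed log2 fold-changes (alternating
  direction); the positive group's mean composition is tilted by the
  exponent `1 + diversity_deficit`, which monotonically lowers its
  Shannon/Simpson diversity without changing species identity — mirroring
  the reduced diversity observed in SIRS-positive patients. Per-sample
  variation is log-normal (`sigma_sample = 0.4`).
* **Reads**: drawn from marker loci only — per-read species multinomial
  with probability proportional to `composition * T_i` (so the
  marker-normalized estimator is unbiased for the planted composition),
  marker uniform within species, strand random, substitution errors at
  0.1% per base by default.
* **Clinical covariates**: distributions are matched to the
  characteristics reported for post-PCNL SIRS cohorts — normal for
  mean ± SD fields, log-normal matched
  to median and IQR for skewed fields, a median-matched gamma (shape 6)
  for operative time, categorical fields at the overall rates. Only the
  three covariates that separated the outcome groups differ by group by
  default: the albumin-globulin ratio AGR (1.53 ± 0.21 negatives vs
  1.40 ± 0.28 positives), operative time (median 70 vs 100 min) and
  urinary leukocytes (median 63 vs 219 /µL). SIRS labels are assigned by
  group (19/96 positive fraction), not re-randomized.

What the generator does **not** emulate: whole-genome shotgun reads (reads
come from marker loci only), platform-specific error profiles,
phylogenetically structured compositions, compositional correlation between
microbial features and clinical covariates, and batch effects. Passing
tests therefore demonstrate the pipeline's correctness and calibration
under a controlled community model, not the effect sizes of any real
cohort. One consequence of the closed (sum-to-one) composition model is
worth noting: planting fold-changes at some species necessarily shifts all
other species by a common renormalization factor, so "unchanged" species
are unchanged only up to that shift.

# Diversity

Chao1 (`S_obs + F1(F1-1)/(2(F2+1))`, bias-corrected) is computed on
integer read counts, where singletons exist; Shannon (`-Σ p log p`) and
Gini-Simpson (`1 - Σ p²`) on relative abundances — a deliberate split that
respects each estimator's domain. Beta diversity offers Bray-Curtis, binary Jaccard and
Euclidean distances (via `vegan`), principal-coordinate analysis by
classical scaling (negative eigenvalues reported, excluded from
variance-explained), and a two-group PERMANOVA whose pseudo-F uses the
standard within/between decomposition of squared distances. The PERMANOVA
p-value enumerates all `choose(n, n1)` label assignments when that number
is at most 500 (`p = count/total`, deterministic) and otherwise uses 999
seeded random permutations with `p = (1 + count)/(1 + n_perm)`; the
observed assignment always counts once. Alpha-diversity group comparisons
use the Wilcoxon rank-sum test, exact at small sample sizes without ties.

# Differential taxa

Four approaches produce a common tidy result format (taxon, statistic,
effect, p, BH q, enriched group, significance flag); multiplicity is
corrected *within* each method, never across methods, because the methods
are reported separately.

* **Wilcoxon**: two-sided rank-sum per taxon, BH across taxa, enrichment by
  the higher median (tie: higher mean).
* **lefse_lite**: a concrete re-specification of the LDA-effect-size idea
  for a two-group design (the original's subclass logic is vacuous here).
  Stage 1 is a Kruskal-Wallis screen at 0.05. Stage 2 rescales abundances
  to the per-sample 10⁶ convention and, over 30 within-class bootstrap
  subsamples, averages the between-class separation of the taxon's means;
  the score is `sign × log10(max(|separation|, 1))`, so the conventional
  ≥ 3.0 threshold corresponds to a 10³ separation on the 10⁶ scale. This
  is not byte-compatible with the original LEfSe.
* **linear_assoc**: per-taxon linear model on log2-transformed
  total-sum-scaled abundance with a half-minimum pseudocount and the group
  indicator (optional covariates), the documented default of multivariable
  microbiome association tools; significance at BH `q < 0.25`.
* **indval**: indicator value `A × B × 100` (specificity × fidelity),
  maximized over groups, with a permutation p that enumerates label
  assignments exhaustively at small n (same rule as PERMANOVA).

The consensus candidate set intersects the 50 most abundant species (by
mean relative abundance — the ranking statistic is configurable since the
convention is not fixed) with the union of method-flagged taxa.

# Prediction

Clinical covariates are compared with a normality-routed t/Wilcoxon test
for continuous variables and chi-square/Fisher for categorical ones
(Fisher whenever any expected *or observed* cell count is below 5, so
sparse tables are always handled exactly). Risk-factor modeling follows
the conventional two-stage scheme: per-variable logistic fits with Wald
odds ratios and 95% CIs, variables at `p < 0.05` entering a joint
multivariate fit. Complete separation is detected and reported with an
infinite-OR sentinel rather than silently unstable estimates; collinear
designs raise errors. ROC/AUC uses the rank (Mann-Whitney) formulation
with half-credit ties, which makes the AUC literally the score-label
concordance and invariant under monotone transforms.

Microbial biomarkers are selected by a 500-tree random forest on the
consensus candidates with a *strict* Mean-Decrease-Gini cutoff (`MDG > 2`).
Model evaluation uses stratified k-fold cross-validation (default 10-fold,
reduced with a warning when a class is smaller than k); the combined
microbial + clinical model standardizes its features (species on the log2
pseudocount scale) and reports the in-sample AUC and the cross-validated
AUC separately and labeled as such — the two are deliberately never
conflated.

# Design decisions taken where the method description was open

* The enzyme is not named by the assay description; BcgI-style
  `CGA-N6-TGC` with 12-nt flanks is the field's standard and is fully
  configurable, so tests can use short synthetic patterns.
* The G-score appears in the literature both as the plain product `S×t`
  and as `sqrt(S·t)`; the square-root form is the default here, with the
  plain product as an explicit mode recorded in run logs.
* The G threshold comparison is `>= 5`; the boundary case is pinned by a
  test.
* Marker uniqueness is computed at species level (union over a species'
  genomes first), and species left without unique markers are recorded as
  unprofilable rather than dropped.
* Simpson is reported as Gini-Simpson with an inverse-Simpson option.
* The random-forest importance ranking runs within the candidate set
  (matching the biomarker-funnel design), not the full matrix.

# Problem sizes and runtime envelope

The test suite and the reproduction script run on deliberately small
problems chosen to exercise every code path while keeping a full run in
the minutes range: genomes of 3–20 kb with 3–10 planted markers, 5–50
species databases, cohorts of 96 samples at depths up to 10⁵ reads for
recovery checks, 300–400 replicates for null-calibration estimates, and 25
seeds for the combined-vs-clinical dominance property. Null calibration
targets (rejection near 5%) have Monte-Carlo standard errors near 1% at
these replicate counts, which the test tolerances reflect.

# Known limitations

* Exact matching only; true alignment-based assignment (and therefore
  mismatch-tolerant profiling of divergent strains) is out of scope.
* The real 86k-species marker database is not reproduced; databases here
  are built from user or synthetic genomes at toy scale.
* `lefse_lite` and `linear_assoc` are method-faithful re-specifications,
  not drop-in replacements for LEfSe/MaAsLin2 output.
* The generator's clinical covariates are matched on summary statistics
  (means/medians/IQRs), not full distributions, which are unknowable from
  a summary table.
* Functional (pathway) prediction is out of scope.

# A minimal end-to-end run

```{r, eval = FALSE}
cfg <- default_config()
cfg$n_samples <- 24L; cfg$n_species <- 8L; cfg$genome_length <- 4000L
cfg$markers_per_species <- 5L; cfg$depth <- 1500L
manifest <- run_pipeline(cfg, out_dir = "demo_run")
```

This writes per-stage TSV/JSON outputs and a manifest of MD5 checksums;
re-running with the identical config reproduces identical checksums.
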