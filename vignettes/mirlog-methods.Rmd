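---
title: "Methods: the miRNA SNV meta-predictor and its synthetic test bench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the miRNA SNV meta-predictor and its synthetic test bench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Single-nucleotide variants in microRNA hairpins can perturb biogenesis
(Drosha/Dicer processing of the precursor) or targeting (seed pairing), but
curated pathogenic examples are scarce: a realistic training set holds a few
dozen deleterious SNVs against hundreds of common, presumably neutral ones.
`mirlogr` combines ten precomputed noncoding-variant scores into one
probability with a pipeline built specifically for that regime — strong
inter-score collinearity, severe class imbalance, and partially missing
features — and surrounds the model with the anatomy, statistics and
input-emulation machinery needed to use and validate it.

## Hairpin anatomy

Hairpins are represented as tibbles (genomic span, strand, 5'→3' sequence in
the RNA alphabet, 0–2 mature arms in hairpin-local 1-based coordinates). The
subregion map is a pure function of that anatomy:

* **seed** — mature positions 1–8. The package deliberately uses the
  first-to-eighth convention rather than the canonical 2–8 targeting
  definition; the two conventions silently disagree at position 1, so one had
  to be fixed, and the 1–8 reading matches the annotation scheme the rest of
  the subregion arithmetic assumes.
* **rest of mature** — positions 9 to the mature end. Matures shorter than
  8 nt are rejected (the seed would be undefined).
* **loop / out of loop** — only for hairpins with two annotated matures: the
  positions strictly between the arms, and the positions outside both arms.
* **rest of pre-miRNA** — all non-mature positions when the hairpin has at
  most one mature. Hairpins with zero annotated matures are retained and
  enumerated entirely as this class.

The map is a partition: every nucleotide receives exactly one label, which the
test suite asserts as an invariant. Enumeration emits the three non-reference
alleles per unambiguous base, reported on the genomic plus strand; `N` bases
are skipped with a warning. HGVS-style names (`id:n.<offset><ref>><alt>`) use
hairpin-sense RNA alleles, so on minus-strand hairpins the genomic alleles are
complemented. Overlapping hairpins each contribute their own records: a shared
genomic locus is counted once per hairpin, which is the convention that makes
the 3 x (total nt) arithmetic exact.

All coordinates are 1-based inclusive (GFF3 and VCF convention) at every
interface; hairpin-local offsets are also 1-based.

## Feature assembly and imputation

The ten tools have two native resolutions: allele-level scores are keyed by
(chrom, pos, ref, alt); conservation-type scores (phyloP, phastCons) and
LINSIGHT score positions, so one value is broadcast to the three alternative
alleles of a site. Assembly keeps native scales (no rescaling) so the wide
table stays interpretable; standardization happens inside the model where it
belongs to the training fold.

Missing scores are imputed by an iterative Extra-Trees imputer: missing cells
start at the column mean, then each incomplete column in turn (least-missing
first, the same sweep order as the reference round-robin imputer) is regressed
on the other nine columns with an extremely-randomized-trees regressor
(`ranger`, `splitrule = "extratrees"`, no bootstrap, 126 trees by default) and
its missing entries are replaced by predictions, for up to 10 sweeps or until
the largest relative change drops below `tol = 1e-3`. The whole run is
repeated `repeats = 10` times with distinct seeds and the imputed values are
**averaged**. The averaging reading is a design choice: "repeat" could also
mean pooling or a stability diagnostic, but averaging is the only
interpretation that changes the estimate and provably reduces its variance;
the per-repeat values are still exposed as an attribute for diagnostic use.
Two further choices: observed cells are restored bit-identically after
averaging, and the autosomal flag never participates in imputation (it is
never missing, and imputing through a boolean would leak the chromosome into
the score columns).

A column with no observed value at all is an error, not something to guess at.

## The classifier

The pipeline is standardize → PCA → append the autosomal flag → degree-2
polynomial expansion → bagging of L2 logistic regressions, all refitted inside
every training fold so cross-validation never leaks.

Decisions where the design was genuinely open:

* **PCA retention.** All 10 components are kept. The rotation exists to remove
  collinearity among the tools, not to reduce dimension; no retention count is
  part of the method's definition, and truncation would discard signal the
  polynomial step can use.
* **Placement of the autosomal flag.** The flag is appended *after* the PCA
  (it is not a score and should not be rotated with them) and *before* the
  polynomial expansion, so it interacts multiplicatively with every component.
  That gives the ensemble exactly the degree of freedom the flag exists for:
  re-weighting the scoring systems on X-chromosome SNVs, where some tools are
  undefined.
* **Bootstrap asymmetry.** Each base learner trains on all deleterious rows
  (never resampled) plus `round(ratio * n_deleterious)` neutral rows drawn
  with replacement, and on `ceiling(feature_fraction * 77)` derived features
  drawn without replacement. With 24 deleterious rows, undersampling the
  majority class per learner is the only way every learner sees a balanced
  problem while the ensemble still sees all neutral SNVs.
* **Feature subsampling as a fraction.** Whether the per-learner feature draw
  is a count or a fraction is not fixed by the method description; a fraction
  keeps the grid meaningful when the derived-feature count changes.
* **Base learner.** `glmnet` with `alpha = 0` and a single fixed `lambda`
  (the `l2` hyperparameter), `standardize = FALSE` because the pipeline
  standardizes once, globally per training fold.

### Tuning and evaluation

Hyperparameters (`l2`, `ratio`, `feature_fraction`) are tuned by grid search
under repeated stratified cross-validation: default 12 folds, 4 repeats.
Deleterious rows are shuffled and dealt round-robin, so 24 deleterious SNVs
land exactly 2 per fold; neutral rows are dealt to balance total fold sizes.
Fewer deleterious rows than folds is an error that advises reducing the fold
count. Grid ties are broken toward **stronger regularization first** (largest
`l2`), then the smaller neutral ratio, then the smaller feature fraction — the
overfitting-averse direction, which matters because separable data produce
AUC-1 ties across large parts of any grid.

AUC is the rank statistic (the normalized Mann–Whitney U with midranks), which
the tests pin against brute-force counting over all (positive, negative)
pairs. Per-repeat AUCs and the pooled out-of-fold AUC are both reported, since
either aggregation is defensible; the ROC curve is computed from the pooled
scores. The default grid (`l2` in {0.01, 0.1, 1, 10}, ratio in {1, 2, 4, 8},
fraction in {0.3, 0.6, 1}) is a reasonable lattice around the defaults and is
fully configurable.

Models serialize to versioned JSON (scaler, rotation, per-learner coefficients
and subsets, seed), so a stored model reproduces its scores exactly and the
artifact stays a text file.

## Population-variability statistics

* **Coverage rule**: a hairpin is properly covered when ≥ 20 reads cover
  ≥ 80% of its bases in ≥ 80% of individuals; every comparison is inclusive,
  so the exact 20/80%/80% boundary passes. The function accepts either the
  summarized per-base form (fraction of individuals at depth) or long
  per-individual depths.
* **Density** is SNVs per kilobase; multi-allelic sites count once per
  alternative allele, consistent with the 3-alleles enumeration. Density
  comparisons use the 2x2 chi-square on (variant, non-variant) counts without
  continuity correction — the cohort-scale tables are large — with a
  `small_expected` flag when any expected cell is below 5.
* **Ts/Tv** uses the six strand-symmetric substitution categories; an empty
  transversion set reports an infinite ratio rather than failing.
* **Percentile selection**: the threshold is the type-7 (linear-interpolation)
  quantile and the selection is *strictly greater*, so a constant score vector
  selects nothing. The convention is stated because "99th percentile"
  pairings with a concrete threshold are only reproducible under a fixed
  quantile rule.
* **AF boundary**: in dataset construction both neutral rules are strict
  (`AF > 0.10` for the stringent set, `AF < 0.10` for the relaxed set), so a
  variant at exactly 10% joins neither; it appears in the audit log instead of
  being silently decided. Every excluded input row is audited with a reason,
  and dataset + audit row counts reconcile to the input row count.

## What the synthetic generators emulate — and what they do not

The generators are pure functions of (config, seed) and write the exact
dialects the package reads (miRBase-style GFF3/FASTA, per-tool TSVs, VCF
v4.2), so round-trip fidelity is testable. Defaults encode the documented
cohort conditions: hairpin lengths 41–180 nt with mean ~80 (a right-skewed
Beta over the band — a uniform draw over 41–180 would have mean 110, far from
the ~80 nt average typical of human pre-miRNAs), mature lengths uniform 16–28
(mean 22),
half of hairpins with two matures, 11% MCAR missingness, SNV density
71.9/kb, Ts/Tv 2.03, 73% of variants at AF ≤ 0.01%, and labeled sets of
24 + 219. Scores come from a 3-latent-factor model (a shared deleteriousness
axis, a conservation axis on the position-level tools, a functional axis on
four allele-level tools) plus idiosyncratic noise, which reproduces the
observed regime in which half of the principal components carry ~90% of the
variance. Class separation is a single knob `d_prime`, the shift of
deleterious rows along the first latent factor: 6 gives the near-separable
regime, 0 the null. The FILTER pass fraction defaults to 1 so that density and
Ts/Tv targets are recovered from PASS records; it can be lowered to exercise
filter handling.

What the generators do **not** emulate: real sequence composition and
secondary structure, site-specific mutation-rate variation, linkage between
neighbouring variants, non-MCAR missingness (real missingness clusters by
tool coverage), and the true joint distribution of the ten tools. Passing
tests therefore demonstrate the correctness of the machinery — coordinate
arithmetic, rule application, estimator contracts, statistical formulas —
under controlled conditions, not the real-data discriminative performance of
the meta-predictor, which depends on external score tracks and curated
pathogenic sets outside this package's scope.

## Problem sizes and numerical tolerances

The test suite exercises the arithmetic at full annotation scale (1,869
hairpins, 152,975 nt, 458,925 enumerated SNVs) where it is cheap, and scales
the stochastic work to what demonstrates the property: imputation oracles on
250-row matrices, CV properties with 8–50 base learners, generator-recovery
checks on ~700 kb cohorts (~50,000 variants) with 3-sampling-sd bands, and a
complete simulate → assemble → impute → datasets → tune → train → score →
annotate → stats pipeline on a 6-hairpin toy set whose outputs are asserted to
be byte-identical across reruns. Sampling-based assertions use 3-sd bands
derived from the binomial/multinomial sampling error of the target quantity;
deterministic assertions use exact or near-machine tolerances. Degenerate
inputs (single-class data, fully missing columns, empty transversions,
constant scores, folds without a class, chromosome-start flanks) have defined
behaviour — error, flag, or documented convention — rather than undefined
output.

## Known limitations

* The meta-predictor's real-world calibration is inherited from its training
  set; with ~24 positive examples the scores are a ranking tool, not
  validated probabilities.
* The imputer is O(repeats x sweeps x columns) Extra-Trees fits; at the full
  458,925-row scale it is a batch job, not interactive (scoring, by contrast,
  is chunked and cheap).
* External annotation resources (dbSNP, disease databases, target predictors,
  structure tools) are represented by a generic key-join interface, not
  fetched or parsed.
* liftOver between assemblies and secondary-structure scoring are out of
  scope; coordinates pass through in the assembly of the input annotation.
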