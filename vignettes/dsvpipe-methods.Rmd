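---
title: "Methods: deletion structural variants in cancer risk, immunity and prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deletion structural variants in cancer risk, immunity and prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `dsvpipe`, their
assumptions, the tunable parameters and their defaults, the synthetic-data
design used to validate each stage, and the numerical and design decisions
taken where several reasonable choices existed.

## Coordinates and the deletion filter

A deletion record anchors on the VCF padding base: `POS` is the base before
the first deleted base and `END` the last deleted base, so the deleted
length is `END − POS`. Internally the package stores `start = POS + 1` (the
first deleted base, 1-based) and an exclusive `end`, so
`length = end − start` and gene overlap uses half-open logic: a deletion
whose exclusive end abuts a gene start does not overlap it. Gene models
arrive as BED (0-based half-open) and are converted on input; overlap
queries run through an interval tree (`GenomicRanges::findOverlaps`), so
annotation is sub-linear in the number of genes.

Filtering keeps deletions that are simultaneously (i) autosomal, (ii)
500–10,000 bp (`min_len`, `max_len`), (iii) at folded minor allele
frequency ≥ 0.05 (`min_maf`), computed as
`f = (het + 2·hom) / (2·N_called)` over all called genotypes and folded at
0.5, and (iv) carried by ≥ 1% of the cancer cohort *and* ≥ 1% of the
non-cancer cohort (`min_carrier_frac_per_cohort`). The frequency criteria
are described ambiguously in the source material (MAF per population in one
place, overall with a per-population presence rule in another); the package
computes MAF over the combined cohort and applies the per-cohort rule to
carrier presence, and both thresholds are exposed as parameters so either
reading can be configured. Missing genotypes count as non-carriers and are
excluded from allele-frequency denominators — a conservative choice made
explicit by the per-criterion rejection tally the filter returns (a record
failing several criteria is tallied under each). Filtering is idempotent
and each criterion is monotone in its parameter; both properties are
tested.

## The attention-weighted risk classifier

Input is the binary carrier vector `x_n ∈ {0,1}^m`. A per-deletion scalar
weight vector `W` and an embedding table `E` (m × e) produce the sample
representation `r_n = Σ_j x_{nj} · W_j · E_j`, an `e`-vector; `r_n` feeds a
ReLU MLP whose two output logits pass through a softmax. Training minimizes
class-weighted binary cross-entropy with mini-batch Adam. Risk-associated
deletions are those with strictly positive learned `W_j`.

The architecture's source description fixes neither the embedding size,
depth, widths, optimizer nor epochs. Defaults, chosen for a small tabular
problem and all configurable via `attention_hyper()`:

| parameter | default | rationale |
|---|---|---|
| embedding size `e` | 32 | small relative to m, keeps `W_j E_j` expressive |
| hidden layers | (64, 16), ReLU | two narrow layers suffice for binary inputs |
| optimizer | Adam, lr 1e-3 | robust default for this scale |
| epochs / batch | 200 / 32 | with early stopping, an upper bound |
| early stopping | patience 20 on a 10% stratified validation split | guards against overfitting m ≫ planted signal |
| class weights | inverse frequency | cohorts are imbalanced (e.g. 192 vs 499); sensitivity matters |

`W` is initialized uniform on [0, 0.1] — strictly positive — so that the
positive-weight selection rule reflects training dynamics rather than the
sign symmetry of a zero-centred initialization; no constraint keeps `W`
positive afterwards, and informative deletions for the *control* class are
driven negative. `E` is Gaussian with sd `1/√e`. Because the forward pass
only uses the products `W_j E_j`, doubling `W` while halving `E` is a
no-op; the selection rule is therefore meaningful only relative to this
one-sided initialization, which is why the initialization is part of the
model definition and covered by tests.

Sensitivity and specificity are computed at the 0.5 probability cutoff with
"cancer" as the positive class (the source states no threshold), and AUC is
the rank-based (Mann–Whitney) estimate. Cross-validation is stratified
k-fold (default 5); the comparison models are a single-hidden-layer MLP
(`nnet`), a linear SVM (`e1071`), logistic regression (`glm`) and a random
forest (`randomForest`). The final positive-weight selection comes from a
model retrained on all samples after cross-validation, since per-fold
selections need not agree.

PCA of the selected carrier submatrix is centred and unscaled. The
hierarchical clustering of selected deletions uses the Jaccard distance on
binary carrier profiles (`dist(method = "binary")`) with average linkage —
the distance/linkage pair is not specified in the source and both are
parameters.

## Association statistics

All 2×2 tables are laid out rows = exposure, columns = group, so
`OR = ad/(bc) > 1` means exposure enrichment in the first group.

* **Fisher's exact test** uses the minimum-likelihood two-sided rule: the
  sum of hypergeometric probabilities (margins fixed) at most
  `(1 + 1e-7)` times that of the observed table. The test suite checks this
  against full enumeration over every admissible table up to N = 30 and a
  random sweep to N = 60.
* **Continuity-corrected chi-square** implements
  `χ² = N · (max(|ad − bc| − N/2, 0))² / (r₁r₂c₁c₂)` with the upper χ²₁
  tail; the clamp at zero matters for near-null tables.
* **Odds-ratio intervals** are Woolf (log-scale normal) intervals; when any
  cell is zero the Haldane–Anscombe +0.5 correction is applied and flagged;
  two zero cells in a cross pattern leave the OR undefined and raise an
  error.
* **FDR** is Benjamini–Hochberg, applied within each analysis family (the
  gene spectrum; each FCH stratum; the category-enrichment cells)
  separately, since the scope of adjustment is not specified in the source.
  Note the step-up adjustment is *not* idempotent — re-adjusting adjusted
  values multiplies by `n/rank` again — so the package tests monotonicity
  and the adjusted-≥-raw property instead.
* **Characteristics table**: per covariate, Yates-corrected chi-square when
  the table is 2×2 with all expected counts ≥ 5, Pearson chi-square for
  larger all-expected-≥-5 tables, Fisher's exact test otherwise, with the
  rule recorded per row. This is a reconstruction: published per-row
  p-values of the kind this table reproduces are not all consistent with
  any single expected-count rule, so the package states which test produced
  each number.

Gene-level exposure collapses multiple deletions per gene by logical OR,
and a deletion overlapping several genes contributes to each — no
prioritization rule being available, the ambiguity is resolved towards
completeness.

## Immune expression screen

Expression is min–max scaled per gene across samples,
`(x − min)/(max − min)`; a zero-range gene becomes all zeros and is
flagged. The screen computes the point-biserial correlation of every
deletion (0/1 carrier) against every gene:

`r_pb = (ȳ₁ − ȳ₀)/s_y · √(n₁ n₀ / n²)`,

with `s_y` the population (divide-by-n) standard deviation. This is
algebraically the Pearson correlation of `y` with the 0/1 indicator — the
identity is the test oracle (agreement to 1e-12) — and `r_pb` is invariant
under the min–max scaling itself (positive affine maps), so normalization
affects presentation, not selection. A deletion is immune-associated when
`max_g |r| > 0.3`; the absolute-value reading is the default because both
signs are biologically meaningful (a deletion may raise or lower
expression), with a positive-only option (`use_abs = FALSE`).

Category composition per deletion is the fraction of its selected genes in
each of the six immune functional categories (housekeeping, checkpoint
pathways, cytokine signaling, lymphocyte markers, lymphocyte regulation,
tumor characterization); ratios sum to 1 per deletion. Enrichment is the
hypergeometric upper tail given the category size, panel size and the
deletion's selected-gene count — the standard category test, chosen because
the source names none — with BH across all deletion-by-category cells.

## Prognostic stratification

The survival SVM is the linear ranking formulation: minimize
`½‖w‖² + γ Σ_{(i,j)} max(0, 1 − w·(x_i − x_j))` over comparable pairs —
`(i, j)` comparable when sample `j` failed (event observed) before sample
`i`'s observed time. `w·x` scores predicted event lateness, so deletions
enriched in early-recurring patients get negative coefficients. The convex
objective is minimized by gradient descent with Armijo backtracking, so the
recorded objective path is non-increasing by construction; γ defaults to 1.
Feature importance is `|w_j|` with ties broken by column order, and the
number of deletions taken forward (`k`, e.g. 65) is a parameter — the
source gives no rule for choosing it. Memory is O(pairs × features); at the
few-hundred-patient scale this package targets that is at most a few
million doubles.

Each ranked deletion then gets a univariate Cox fit
(`survival::coxph`, Efron ties); the sign of the log hazard ratio assigns
it to the recurrence-associated (log HR > 0) or non-recurrence-associated
group, with exactly-zero assigned to the better-prognosis group
(conservative) and failed or monotone-likelihood fits dropped with a
warning. Patients split into G1 (`R > P`: strictly more carried
recurrence-associated than non-recurrence-associated deletions) and G2
(ties, including carrying none, read "more than" strictly). Kaplan–Meier
curves (`survfit`) and the two-group log-rank test (`survdiff`,
`(O − E)²/V` against χ²₁) evaluate the separation; a no-event input returns
statistic 0, p = 1 rather than an error.

Univariate Cox was chosen over adjusted models because the hazard ratios
feed a sign rule, not effect estimation; multivariate Cox, time-varying
covariates and competing risks are out of scope.

## Causal discovery

The PC algorithm runs over {deletion indicators, expression, RFS}:

* **CI test**: Fisher-z on partial correlations, obtained by inverting the
  correlation submatrix of the pair plus conditioning set;
  `z = √(n − |S| − 3)·atanh(ρ̂)` against the standard normal. Binary
  deletion indicators enter the same test as numeric 0/1 — the pragmatic
  choice common to constraint-based implementations; correlations are
  clamped to ±(1 − 1e-12) so degenerate duplicates yield p → 0 rather than
  NaN.
* **Skeleton**: the stable (order-independent) variant — adjacency
  snapshots per conditioning-set size — so results do not depend on
  variable order; verified by permutation tests.
* **Orientation**: v-structures from separation sets, then Meek rules 1–4
  to closure; conflicting orientations revert to undirected and are
  counted; every output's directed part is asserted acyclic. On plain PC
  output rule 4 never fires (it needs background knowledge); it is included
  for completeness.
* **Censoring**: RFS enters as the observed time restricted to
  event-observed samples; censoring-aware CI testing is out of scope and
  the restriction is the honest default. α defaults to 0.05.

Mediation extraction returns deletion → gene → RFS paths with both hops
strictly directed as `"directed"`, and paths where a hop remains undirected
as `"compatible"` — some member of the Markov equivalence class orients
them forward. A chain's two edges correctly stay undirected in the CPDAG
(the equivalence class contains both directions), which is why planted
chain recovery is asserted at the skeleton-plus-separation-set level and
mediation paths are accepted as directed *or* compatible.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions every
downstream recovery test runs under.

* **Genotypes** are diploid Hardy–Weinberg draws per cohort. Background
  deletions share an allele frequency (uniform on [0.10, 0.40] by default)
  across cohorts; planted risk deletions specify a control allele frequency
  and a carrier-status odds ratio, and the case allele frequency is solved
  so the carrier OR matches in expectation (`q₁ = 1 − √(1 − p₁)` with `p₁`
  from the odds transform). The OR is defined on carrier status because the
  pipeline uses deletions as binary features. A non-finite implied case
  carrier frequency errors out.
* **Coordinates** are uniform on autosomes with lengths uniform on
  [500, 10000] bp, matching the filter's target range.
* **FCH** is Bernoulli with a logistic link to cancer status at a
  configured odds ratio (default 1.89, the headline value of the study
  design emulated; its control-arm prevalence default 0.435 matches the
  published control counts). The published count table for that analysis
  implies OR ≈ 1.375 rather than 1.89 — an inconsistency in the source that
  the package surfaces by computing, not by tuning to either number.
* **Expression** is standard Gaussian noise except planted pairs,
  `y = β·carrier + Normal(0, σ²)`, giving the closed-form plug-in
  `r_pb = β√(pq)/√(β²pq + σ²)` used as a recovery oracle. Each gene gets
  exactly one of the six categories.
* **Survival** is exponential: hazard `λ₀·exp(Σ log-HR·carrier)` (default
  λ₀ = 0.02 per month) with independent exponential censoring (default
  0.01 per month). Exponential baselines keep closed-form sanity checks;
  cohort defaults (192 vs 499) mirror the emulated study design.
* **Determinism**: one global seed; each stage derives a fixed substream
  seed from it, so identical configs give byte-identical outputs.

What the generator does *not* emulate: read-level noise and genotyping
error, linkage between deletions, population structure and relatedness,
batch effects in expression, and non-proportional hazards. Passing recovery
tests therefore demonstrate correctness of the estimators under the stated
models, not robustness to those real-data complications.

## Calibration and validation design

The validation studies (in `tests/testthat/test-acceptance.R` and
recomputed by `scripts/acceptance.R`) use these problem sizes, chosen so
each study is decisive at desk scale:

* attention recovery: 600 + 600 samples, 300 deletions, 20 planted at
  carrier OR 3 and 20% control carrier frequency, stratified 80/20
  train/test split;
* survival-SVM recovery: 10 replicates of 300 patients, 51 deletions, one
  planted at log HR 1.2;
* hazard-sign partition and G1/G2: 400 patients, 20 planted at log HR ±1;
* PC chain recovery: 10 replicates of n = 2000;
* null calibrations: 500 replicates each. The exact (Fisher) test's
  p-values are *discrete and conservative by construction*, so uniformity
  is assessed on population-scale null tables (3000 per group), where the
  support is dense enough for a Kolmogorov–Smirnov check; log-rank and
  Fisher-z nulls are effectively continuous at cohort scale already. At
  typical cohort sizes the exact test's conservativeness is a real property
  of the procedure, not an implementation artifact.

## Known limitations

* Cohort-specific published headline numbers (e.g. a particular AUC or a
  count of selected deletions) depend on data that is not deposited; the
  package validates the *procedures* by parameter recovery on synthetic
  cohorts instead.
* The attention model's selected set depends on its one-sided
  initialization (by design) and on training noise; selections should be
  read as a ranked candidate pool, not a fixed gene list.
* Gene-level collapsing by logical OR can let one long deletion dominate
  several genes' statistics.
* The survival SVM's pair enumeration grows quadratically with patients;
  for cohorts far beyond ~10³ patients a subsampled or kernelized solver
  would be needed.
* PC output is a Markov equivalence class; an undirected edge is not
  evidence against causation, merely non-identifiability from observational
  data under the model's (linear-Gaussian, causal-sufficiency) assumptions.
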