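# dsvpipe

Germline **deletion structural variants** (DSVs — deletions of roughly
500–10,000 bp called from whole-genome sequencing) carry inherited cancer
risk and prognostic information that single-nucleotide analyses miss.
`dsvpipe` is an R implementation of an end-to-end case/control DSV analysis
for cancer cohorts, aimed at statistical genetics and cancer-genomics
researchers who have population-scale deletion calls (VCF), a cohort table,
and optionally immune gene-expression and recurrence-free-survival (RFS)
outcomes.

The pipeline stages, each usable on its own:

1. **Preprocessing** — read SVTYPE=DEL records from VCF, filter to autosomal
   deletions of 500–10,000 bp with folded MAF ≥ 0.05 carried by ≥ 1% of each
   cohort, and build the binary carrier matrix `x_{n,j} ∈ {0,1}` (sample *n*
   carries deletion *j*), with interval-tree gene annotation.
2. **Attention-weighted risk model** — a neural classifier over the carrier
   vector: a per-deletion scalar weight vector **W** gates an embedding
   table **E** (size *e*), the weighted embeddings are summed to
   `r_n = Σ_j x_{nj} W_j E_j`, passed through an MLP and a softmax over
   {cancer, non-cancer}; training minimizes class-weighted binary
   cross-entropy. Risk-associated deletions are those with learned
   `W_j > 0`. Benchmarked against MLP, linear SVM, logistic regression and
   random forest under stratified 5-fold cross-validation, with PCA and
   Jaccard/average-linkage hierarchical clustering of the selected set.
3. **Association statistics** — per-gene carrier odds ratios
   `OR = ad/(bc)` with Woolf intervals, two-sided Fisher exact tests,
   continuity-corrected chi-square
   `χ² = N(|ad−bc| − N/2)²₊ / (r₁r₂c₁c₂)`, Benjamini–Hochberg FDR,
   family-cancer-history (FCH) analyses and a Table-1-style cohort
   characteristics report.
4. **Immune correlation** — per-gene min–max expression scaling and the
   point-biserial screen
   `r_pb = (ȳ₁ − ȳ₀)/s_y · √(n₁n₀/n²)` of every deletion against every
   immune gene, with |r| > 0.3 selection and hypergeometric enrichment over
   six immune functional categories.
5. **Prognostic stratification** — a linear ranking survival SVM
   (comparable-pairs hinge loss) ranks deletions; univariate Cox fits
   partition the top set by the sign of the log hazard ratio; patients with
   more recurrence-associated than non-recurrence-associated deletions form
   group G1, the rest G2; Kaplan–Meier curves and the log-rank test assess
   the separation.
6. **Causal discovery** — the PC algorithm (Fisher-z partial-correlation
   tests, order-independent skeleton, v-structures, Meek rules) over
   {deletions, immune expression, RFS}, extracting deletion → gene → RFS
   mediation paths.
7. **Synthetic cohorts** — a generator with planted carrier odds ratios
   (Hardy–Weinberg genotypes per cohort), expression couplings and
   proportional-hazards effects, so every stage has a parameter-recovery
   test without external data.

## Worked example

A synthetic cohort of 192 cancer vs 499 non-cancer samples with five
planted risk deletions (carrier OR = 3), one deletion–gene expression
coupling and two planted hazard effects:

```r
library(dsvpipe)

cfg <- simulation_config(
  n_cancer = 192, n_control = 499, m_background = 120,
  planted_risk = data.frame(index = 1:5, or = 3, freq = 0.11),
  planted_expression = data.frame(dsv = 1, gene = 1, beta = 2, sigma = 0.5),
  planted_hazard = data.frame(dsv = c(2, 3), loghr = c(1, -1)),
  n_genes = 40, seed = 1)
sim <- simulate_cohort(cfg)
sim$carriers
#> carrier_matrix: 691 samples x 125 deletions (41.9% carriers)

fit <- train_attention(sim$carriers, sim$cohort$cohort_label, seed = 1)
sel <- select_positive_weight_dsvs(fit)
sum(sim$truth$risk_dsv_ids %in% sel)    # planted deletions recovered
#> 5

fch <- fch_analysis(sim$cohort)
#> FCH odds ratio 1.78 [1.27-2.50], Fisher p = 0.000896

scr <- correlation_screen(sim$carriers, minmax_normalize(sim$expression))
head(scr$pairs, 1)
#>    dsv_id gene_id         r
#> 1 DSV0001   G0001 0.8705771

pats <- sim$cohort[sim$cohort$cohort_label == "cancer", ]
X <- sim$carriers$carriers[pats$sample_id, ]
svm  <- fit_survival_svm(X, pats$rfs_time, pats$rfs_event)
part <- partition_by_hazard(X, pats$rfs_time, pats$rfs_event,
                            dsv_ids = rank_prognostic_dsvs(svm, 10))
st   <- stratify_patients(X[, part$dsv_id], part)
logrank_test(pats$rfs_time, pats$rfs_event, st$group)
#> G1 n=111 vs G2 n=81: log-rank chi-square 19.42, p = 1.05e-05
```

The attention model recovers all five planted risk deletions among its
positive weights; the FCH odds ratio matches the configured 1.89 link
within sampling error; the planted expression coupling appears at
`r ≈ 0.87` (its theoretical point-biserial value for β = 2, σ = 0.5 at 30%
carrier frequency is 0.878); and the hazard-sign stratification separates
G1 from G2 decisively.

A thin command-line front end is installed at
`system.file("cli", "dsvp", package = "dsvpipe")` with subcommands
`filter`, `associate`, `correlate`, `prognosis` and `causal`.

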