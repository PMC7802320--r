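test_that("Fisher's exact test matches hypergeometric enumeration on small tables", {
  expect_equal(fisher_exact_two_sided(two_by_two(0, 5, 5, 0)), 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(two_by_two(2, 0, 0, 2)), 1 / 3,
               tolerance = 1e-12)
  # observed cell at the hypergeometric mode
  expect_gte(fisher_exact_two_sided(two_by_two(11, 32, 14, 42)), 0.99)
  expect_warning(p <- fisher_exact_two_sided(two_by_two(0, 0, 5, 5)), "margin")
  expect_equal(p, 1)
})

test_that("Fisher p equals the enumeration oracle over random tables", {
  set.seed(42)
  for (rep in 1:300) {
    N <- sample(4:60, 1)
    cuts <- sort(sample(0:N, 3, replace = TRUE))
    t <- two_by_two(cuts[1], cuts[2] - cuts[1], cuts[3] - cuts[2], N - cuts[3])
    if (any(rowSums(t) == 0) || any(colSums(t) == 0)) next
    expect_equal(fisher_exact_two_sided(t), fisher_enum_oracle(t),
                 tolerance = 1e-10)
  }
})

test_that("Yates chi-square reproduces printed cohort-table p-values", {
  kras <- yates_chi_square(two_by_two(12, 25, 13, 48))
  expect_equal(kras$p, 0.3245, tolerance = 1e-3)
  mucinous <- yates_chi_square(two_by_two(2, 10, 23, 64))
  expect_equal(mucinous$p, 0.707, tolerance = 1e-3)
  # |ad - bc| <= N/2 clamps the statistic to zero
  clamp <- yates_chi_square(two_by_two(11, 32, 14, 42))
  expect_equal(clamp$statistic, 0)
  expect_equal(clamp$p, 1)
  expect_error(yates_chi_square(two_by_two(0, 0, 5, 5)), "margin")
  # agreement with the standard continuity-corrected implementation
  set.seed(7)
  for (i in 1:50) {
    t <- matrix(sample(1:40, 4, replace = TRUE), 2)
    expect_equal(yates_chi_square(t)$p,
                 suppressWarnings(chisq.test(t, correct = TRUE)$p.value),
                 tolerance = 1e-12)
  }
})

test_that("odds ratio obeys its symmetry laws and handles zeros", {
  sym <- odds_ratio_ci(two_by_two(5, 5, 5, 5))
  expect_equal(sym$or, 1)
  expect_true(sym$ci_low < 1 && sym$ci_high > 1)

  fch <- odds_ratio_ci(two_by_two(91, 177, 86, 230))
  expect_equal(fch$or, 20930 / 15222, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:200) {
    t <- matrix(sample(1:30, 4, replace = TRUE), 2)
    orig <- odds_ratio_ci(t)
    expect_equal(odds_ratio_ci(t(t))$or, orig$or, tolerance = 1e-12)
    expect_equal(odds_ratio_ci(t[2:1, ])$or, 1 / orig$or, tolerance = 1e-12)
    expect_lte(orig$ci_low, orig$or)
    expect_gte(orig$ci_high, orig$or)
  }

  hald <- odds_ratio_ci(two_by_two(0, 5, 5, 5))
  expect_true(hald$haldane)
  expect_error(odds_ratio_ci(two_by_two(0, 5, 5, 0)), "undefined")
})

test_that("Benjamini-Hochberg adjustment is correct and monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.07), 0.07)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(3)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # order-preserving: adjusted values are non-decreasing in raw p rank
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("the gene spectrum recovers a planted risk gene and is order-invariant", {
  q <- allele_freq_for_carrier(0.2)
  cfg <- simulation_config(n_cancer = 250, n_control = 250, m_background = 30,
                           planted_risk = data.frame(index = 1:3, or = 3, freq = q),
                           n_genes = 2, seed = 19)
  sim <- simulate_cohort(cfg)
  gene_map <- lapply(colnames(sim$carriers$carriers), function(d)
    sub("DSV", "GENE", d))
  names(gene_map) <- colnames(sim$carriers$carriers)
  res <- dsv_gene_spectrum(sim$carriers, sim$cohort, gene_map)
  top <- top_associations(res, k = 10, direction = "risk")
  planted_genes <- sub("DSV", "GENE", sim$truth$risk_dsv_ids)
  expect_gte(sum(planted_genes %in% top$unit), 2)

  perm <- sample(nrow(sim$cohort))
  cohort_p <- sim$cohort[perm, ]
  res_p <- dsv_gene_spectrum(sim$carriers, cohort_p, gene_map)
  expect_equal(res_p[order(res_p$unit), ], res[order(res$unit), ],
               ignore_attr = TRUE)
})

test_that("genes carried by all or no samples are skipped", {
  cohort <- make_cohort(5, 5)
  X <- cbind(ALL = rep(1L, 10), NONE = rep(0L, 10),
             OK = rep(c(1L, 0L), 5))
  rownames(X) <- cohort$sample_id
  cm <- structure(list(carriers = X, dsv = data.frame(dsv_id = colnames(X))),
                  class = "carrier_matrix")
  gm <- list(ALL = "gA", NONE = "gN", OK = "gO")
  expect_message(res <- dsv_gene_spectrum(cm, cohort, gm), "skipped")
  expect_equal(res$unit, "gO")
})

test_that("FCH analysis reproduces the odds ratio implied by printed counts", {
  cohort <- data.frame(
    sample_id = sprintf("S%03d", 1:584),
    cohort_label = rep(c("cancer", "non-cancer"), c(177, 407)),
    fch = c(rep("yes", 91), rep("no", 86), rep("yes", 177), rep("no", 230)),
    stringsAsFactors = FALSE)
  res <- fch_analysis(cohort)
  expect_equal(res$or, 1.375, tolerance = 1e-3)
  expect_equal(res$p, fisher.test(matrix(c(91, 177, 86, 230), 2))$p.value,
               tolerance = 1e-12)
  expect_equal(res$n_excluded, 0)

  cohort$fch[1:10] <- "unknown"
  expect_equal(fch_analysis(cohort)$n_excluded, 10)
})

test_that("simulated FCH odds ratio is covered by its confidence interval", {
  cover <- vapply(1:30, function(r) {
    cfg <- simulation_config(n_cancer = 300, n_control = 300, m_background = 1,
                             fch_odds_ratio = 2, n_genes = 2, seed = 900 + r)
    sim <- simulate_genotypes(cfg)
    res <- fch_analysis(sim$cohort)
    res$ci_low <= 2 && 2 <= res$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.8)
})

test_that("FCH-stratified deletion tests detect a planted link and skip small strata", {
  set.seed(23)
  n <- 300
  fch <- rbinom(n, 1, 0.4)
  x <- ifelse(fch == 1, rbinom(n, 1, 0.5), rbinom(n, 1, 0.2))
  cohort <- data.frame(sample_id = sprintf("S%03d", 1:n),
                       cohort_label = "cancer",
                       fch = ifelse(fch == 1, "yes", "no"),
                       stringsAsFactors = FALSE)
  cohort$cohort_label[1:20] <- "non-cancer"  # tiny non-cancer stratum
  X <- cbind(D1 = x, D2 = rbinom(n, 1, 0.3))
  rownames(X) <- cohort$sample_id
  cm <- structure(list(carriers = X, dsv = data.frame(dsv_id = colnames(X))),
                  class = "carrier_matrix")
  expect_warning(res <- fch_stratified_dsv_tests(cm, cohort, min_stratum = 30),
                 "skipped")
  expect_named(res, "cancer")
  expect_lt(res$cancer$p_raw[res$cancer$unit == "D1"], 0.05)
  expect_gt(res$cancer$p_raw[res$cancer$unit == "D2"], 0.05)
})

test_that("the characteristics table reproduces printed tests and rules", {
  cohort <- data.frame(
    sample_id = sprintf("P%03d", 1:99),
    recurrence = rep(c("yes", "no"), c(25, 74)),
    # the published counts total 73 in the non-recurrence column; the
    # remaining subject has no KRAS call
    kras = c(rep(c("mutated", "wild"), c(12, 13)),
             rep(c("mutated", "wild", NA), c(25, 48, 1))),
    histology = c(rep(c("mucinous", "nonmucinous"), c(2, 23)),
                  rep(c("mucinous", "nonmucinous"), c(10, 64))),
    fch = c(rep(c("yes", "no"), c(11, 14)), rep(c("yes", "no"), c(32, 42))),
    onelevel = "x",
    stringsAsFactors = FALSE)
  res <- characteristics_table(cohort, c("kras", "histology", "fch", "onelevel"))
  tests <- res$tests
  expect_equal(tests$p[tests$covariate == "kras"], 0.3245, tolerance = 1e-3)
  expect_equal(tests$test[tests$covariate == "kras"], "yates_chi_square")
  # a cell with expected count < 5 switches the rule to Fisher
  expect_equal(tests$test[tests$covariate == "histology"], "fisher_exact")
  expect_gte(tests$p[tests$covariate == "fch"], 0.99)
  expect_true(is.na(tests$p[tests$covariate == "onelevel"]))
  expect_equal(sum(res$counts$n_yes[res$counts$covariate == "kras"]), 25)
})
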