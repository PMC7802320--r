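#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the simulator: cohort sizes, the number of null
#' (background) deletions, planted case-enriched deletions with their odds
#' ratios, expression couplings, per-deletion log hazard ratios for
#' recurrence-free survival, and the family-cancer-history (FCH) link.
#'
#' Defaults mirror the study design the pipeline targets: 192 cancer patients
#' versus 499 non-cancer subjects, deletions of 500-10,000 bp on autosomes,
#' and an FCH prevalence near 43% among controls.
#'
#' @param n_cancer,n_control Number of cancer / non-cancer samples.
#' @param m_background Number of null deletions (identical allele frequency in
#'   both cohorts).
#' @param planted_risk `NULL` or a data.frame with columns `index` (column
#'   position of the deletion among all `m_background + nrow(planted_risk)`
#'   deletions), `or` (case/control odds ratio on carrier status) and `freq`
#'   (control-cohort deletion allele frequency, in (0, 0.5]).
#' @param planted_expression `NULL` or a data.frame with columns `dsv`,
#'   `gene`, `beta`, `sigma`: gene `gene` gets mean shift `beta` for carriers
#'   of deletion `dsv`, with Gaussian noise sd `sigma`.
#' @param planted_hazard `NULL` or a data.frame with columns `dsv`, `loghr`:
#'   carriers of deletion `dsv` have recurrence hazard multiplied by
#'   `exp(loghr)`.
#' @param baseline_hazard Exponential baseline recurrence hazard per month.
#' @param censor_rate Exponential censoring hazard per month (0 = none).
#' @param fch_odds_ratio Odds ratio linking FCH to cancer status.
#' @param fch_baseline FCH prevalence among non-cancer subjects.
#' @param background_freq_range Range the background allele frequencies are
#'   drawn from (uniform).
#' @param n_genes Number of immune expression genes.
#' @param seed Global seed; all per-stage substreams derive from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_cancer = 192, n_control = 499,
                              m_background = 200,
                              planted_risk = NULL,
                              planted_expression = NULL,
                              planted_hazard = NULL,
                              baseline_hazard = 0.02,
                              censor_rate = 0.01,
                              fch_odds_ratio = 1.89,
                              fch_baseline = 0.435,
                              background_freq_range = c(0.10, 0.40),
                              n_genes = 50,
                              seed = 1L) {
  stopifnot_scalar_count(n_cancer, "n_cancer")
  stopifnot_scalar_count(n_control, "n_control")
  stopifnot_scalar_count(m_background, "m_background")
  stopifnot_scalar_count(n_genes, "n_genes")
  if (baseline_hazard <= 0) stop("'baseline_hazard' must be > 0")
  if (censor_rate < 0) stop("'censor_rate' must be >= 0")
  if (fch_odds_ratio <= 0) stop("'fch_odds_ratio' must be > 0")
  assert_prob(fch_baseline, "fch_baseline")
  assert_prob(background_freq_range, "background_freq_range", 0, 0.5)

  m_total <- m_background + if (is.null(planted_risk)) 0L else nrow(planted_risk)
  if (!is.null(planted_risk)) {
    stopifnot(all(c("index", "or", "freq") %in% names(planted_risk)))
    if (anyDuplicated(planted_risk$index) || any(planted_risk$index < 1) ||
        any(planted_risk$index > m_total))
      stop("planted risk indices must be unique and within 1..m_total")
    if (any(planted_risk$or <= 0)) stop("planted odds ratios must be > 0")
    assert_prob(planted_risk$freq, "planted_risk$freq", 0, 0.5)
    if (any(planted_risk$freq == 0)) stop("planted allele frequencies must be > 0")
  }
  if (!is.null(planted_expression)) {
    stopifnot(all(c("dsv", "gene", "beta", "sigma") %in% names(planted_expression)))
    if (any(planted_expression$gene < 1) || any(planted_expression$gene > n_genes))
      stop("planted gene indices must be within 1..n_genes")
    if (any(planted_expression$dsv < 1) || any(planted_expression$dsv > m_total))
      stop("planted expression dsv indices must be within 1..m_total")
    if (any(planted_expression$sigma <= 0)) stop("noise sd must be > 0")
  }
  if (!is.null(planted_hazard)) {
    stopifnot(all(c("dsv", "loghr") %in% names(planted_hazard)))
    if (any(planted_hazard$dsv < 1) || any(planted_hazard$dsv > m_total))
      stop("planted hazard dsv indices must be within 1..m_total")
  }

  structure(list(
    n_cancer = as.integer(n_cancer), n_control = as.integer(n_control),
    m_background = as.integer(m_background), m_total = as.integer(m_total),
    planted_risk = planted_risk, planted_expression = planted_expression,
    planted_hazard = planted_hazard,
    baseline_hazard = baseline_hazard, censor_rate = censor_rate,
    fch_odds_ratio = fch_odds_ratio, fch_baseline = fch_baseline,
    background_freq_range = background_freq_range,
    n_genes = as.integer(n_genes), n_categories = 6L,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# Carrier probability of an autosomal deletion at allele frequency q under
# Hardy-Weinberg equilibrium.
hwe_carrier_prob <- function(q) 1 - (1 - q)^2

# Case-cohort allele frequency realising a target carrier-status odds ratio
# given the control allele frequency. Errors when the implied case carrier
# probability is not < 1 (only reachable for non-finite odds ratios).
case_allele_freq <- function(or, q0) {
  p0 <- hwe_carrier_prob(q0)
  odds1 <- or * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  if (!is.finite(p1) || p1 >= 1)
    stop(sprintf("odds ratio %g with control allele frequency %g implies a case carrier frequency >= 1", or, q0))
  1 - sqrt(1 - p1)
}

#' Simulate deletion genotypes and a cohort table with planted risk structure
#'
#' Draws diploid deletion genotypes under Hardy-Weinberg equilibrium,
#' separately per cohort. Background deletions share one allele frequency
#' across cohorts; planted deletions have their case-cohort frequency solved
#' so the carrier-status odds ratio matches the requested value in
#' expectation. Deletion coordinates are drawn on autosomes with lengths
#' uniform in 500-10,000 bp. The FCH flag is linked to cancer status through
#' a logistic model with the configured odds ratio.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `deletions` (a `dsv_set`: coordinate table
#'   plus deletion-by-sample genotype matrix), `cohort` (per-sample table)
#'   and `truth` (planted ids and realised frequencies).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(substream_seed(config$seed, 1L))
  n <- config$n_cancer + config$n_control
  m <- config$m_total
  is_cancer <- rep(c(TRUE, FALSE), c(config$n_cancer, config$n_control))
  sample_id <- sprintf("S%04d", seq_len(n))

  q_control <- stats::runif(m, config$background_freq_range[1],
                            config$background_freq_range[2])
  q_case <- q_control
  planted_idx <- integer(0)
  if (!is.null(config$planted_risk)) {
    pr <- config$planted_risk
    planted_idx <- as.integer(pr$index)
    q_control[planted_idx] <- pr$freq
    q_case[planted_idx] <- mapply(case_allele_freq, pr$or, pr$freq)
  }

  geno <- matrix(NA_integer_, nrow = m, ncol = n)
  geno[, is_cancer] <- stats::rbinom(m * config$n_cancer, 2L, rep(q_case, config$n_cancer))
  geno[, !is_cancer] <- stats::rbinom(m * config$n_control, 2L, rep(q_control, config$n_control))
  rownames(geno) <- sprintf("DSV%04d", seq_len(m))
  colnames(geno) <- sample_id

  len <- sample(500:10000, m, replace = TRUE)
  chrom <- as.character(sample(1:22, m, replace = TRUE))
  start <- sample.int(150000000L, m, replace = TRUE)
  info <- data.frame(dsv_id = rownames(geno), chrom = chrom,
                     start = start, end = start + len,
                     stringsAsFactors = FALSE)

  # FCH | cancer via the configured odds ratio on the control baseline.
  odds0 <- config$fch_baseline / (1 - config$fch_baseline)
  p_fch <- ifelse(is_cancer, config$fch_odds_ratio * odds0 / (1 + config$fch_odds_ratio * odds0),
                  config$fch_baseline)
  fch <- ifelse(stats::rbinom(n, 1L, p_fch) == 1L, "yes", "no")

  cohort <- data.frame(
    sample_id = sample_id,
    cohort_label = ifelse(is_cancer, "cancer", "non-cancer"),
    fch = fch,
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = pmin(pmax(round(stats::rnorm(n, 60, 10)), 20), 90),
    cancer_type = ifelse(is_cancer,
                         sample(c("colorectal", "breast", "lung", "liver"), n, replace = TRUE),
                         NA_character_),
    recurrence = ifelse(is_cancer, NA_character_, "not-applicable"),
    rfs_time = NA_real_,
    rfs_event = NA_integer_,
    stringsAsFactors = FALSE
  )

  truth <- list(
    risk_dsv_ids = rownames(geno)[planted_idx],
    expression_pair_ids = if (is.null(config$planted_expression)) NULL else
      data.frame(dsv_id = rownames(geno)[config$planted_expression$dsv],
                 gene_id = sprintf("G%04d", config$planted_expression$gene),
                 beta = config$planted_expression$beta,
                 stringsAsFactors = FALSE),
    hazard_dsv_ids = if (is.null(config$planted_hazard)) NULL else
      data.frame(dsv_id = rownames(geno)[config$planted_hazard$dsv],
                 loghr = config$planted_hazard$loghr,
                 stringsAsFactors = FALSE),
    allele_freq_control = q_control, allele_freq_case = q_case
  )

  deletions <- structure(list(info = info, genotypes = geno), class = "dsv_set")
  list(deletions = deletions, cohort = cohort, truth = truth)
}

#' Simulate an immune expression matrix coupled to deletion carriers
#'
#' Every gene is standard Gaussian noise except planted (deletion, gene)
#' pairs, where expression is `beta * carrier + Normal(0, sigma^2)`. Each
#' gene is assigned exactly one of the six immune functional categories.
#'
#' @param carriers A [carrier_matrix] (samples by deletions).
#' @param config A [simulation_config()].
#' @return An [expression_matrix] (genes by samples, unnormalized).
#' @export
simulate_expression <- function(carriers, config) {
  stopifnot(inherits(carriers, "carrier_matrix"), inherits(config, "simulation_config"))
  set.seed(substream_seed(config$seed, 2L))
  n <- nrow(carriers$carriers)
  g <- config$n_genes
  values <- matrix(stats::rnorm(g * n), nrow = g, ncol = n,
                   dimnames = list(sprintf("G%04d", seq_len(g)),
                                   rownames(carriers$carriers)))
  if (!is.null(config$planted_expression)) {
    pe <- config$planted_expression
    for (k in seq_len(nrow(pe))) {
      x <- carriers$carriers[, pe$dsv[k]]
      values[pe$gene[k], ] <- pe$beta[k] * x + stats::rnorm(n, 0, pe$sigma[k])
    }
  }
  categories <- sample(rep_len(immune_categories(), g))
  names(categories) <- rownames(values)
  expression_matrix(values, categories, normalized = FALSE)
}

#' The six immune functional categories
#' @return Character vector of category names.
#' @export
immune_categories <- function() {
  c("housekeeping", "checkpoint pathways", "cytokine signaling",
    "lymphocyte markers", "lymphocyte regulation", "tumor characterization")
}

#' Simulate recurrence-free survival under proportional hazards
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(sum(loghr * carrier))`; censoring times are
#' independent exponential with rate `censor_rate`. When a cohort table is
#' supplied, survival is generated for cancer samples only and merged into
#' its RFS columns; otherwise every sample in the carrier matrix is treated
#' as a patient.
#'
#' @param carriers A [carrier_matrix].
#' @param config A [simulation_config()].
#' @param cohort Optional cohort table from [simulate_genotypes()].
#' @return The cohort table with `recurrence`, `rfs_time`, `rfs_event`
#'   filled in (or a minimal table if `cohort` is `NULL`).
#' @export
simulate_survival <- function(carriers, config, cohort = NULL) {
  stopifnot(inherits(carriers, "carrier_matrix"), inherits(config, "simulation_config"))
  set.seed(substream_seed(config$seed, 3L))
  X <- carriers$carriers
  if (is.null(cohort)) {
    cohort <- data.frame(sample_id = rownames(X),
                         cohort_label = "cancer",
                         stringsAsFactors = FALSE)
    cohort$recurrence <- NA_character_
    cohort$rfs_time <- NA_real_
    cohort$rfs_event <- NA_integer_
  }
  patients <- cohort$sample_id[cohort$cohort_label == "cancer"]
  patients <- intersect(patients, rownames(X))
  lp <- rep(0, length(patients))
  if (!is.null(config$planted_hazard)) {
    ph <- config$planted_hazard
    for (k in seq_len(nrow(ph)))
      lp <- lp + ph$loghr[k] * X[patients, ph$dsv[k]]
  }
  haz <- config$baseline_hazard * exp(lp)
  t_event <- stats::rexp(length(patients), rate = haz)
  t_cens <- if (config$censor_rate > 0)
    stats::rexp(length(patients), rate = config$censor_rate) else Inf
  obs <- pmin(t_event, t_cens)
  ev <- as.integer(t_event <= t_cens)
  i <- match(patients, cohort$sample_id)
  cohort$rfs_time[i] <- obs
  cohort$rfs_event[i] <- ev
  cohort$recurrence[i] <- ifelse(ev == 1L, "yes", "no")
  cohort
}

#' Run the full synthetic generator
#'
#' Convenience wrapper: genotypes + cohort, carrier matrix, expression and
#' survival in one call.
#'
#' @param config A [simulation_config()].
#' @return List with `deletions`, `cohort`, `carriers`, `expression`, `truth`.
#' @export
simulate_cohort <- function(config) {
  sim <- simulate_genotypes(config)
  cm <- build_carrier_matrix(sim$deletions, sim$cohort)
  expr <- simulate_expression(cm, config)
  cohort <- simulate_survival(cm, config, sim$cohort)
  list(deletions = sim$deletions, cohort = cohort, carriers = cm,
       expression = expr, truth = sim$truth)
}

#' Write a synthetic cohort to standard file formats
#'
#' Emits the deletions as a VCF 4.2 (SVTYPE=DEL with END and per-sample GT),
#' the cohort table and expression matrix as TSV, and one gene model per
#' deletion as BED (0-based half-open), so the bundle round-trips through
#' the package readers.
#'
#' @param sim Result of [simulate_cohort()] (or [simulate_genotypes()] plus
#'   the other pieces assembled into the same shape).
#' @param dir Output directory, created if needed.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_fixture_bundle <- function(sim, dir) {
  if (nrow(sim$cohort) == 0L) stop("cohort is empty; nothing to write")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "deletions.vcf"),
             cohort = file.path(dir, "cohort.tsv"),
             expression = file.path(dir, "expression.tsv"),
             categories = file.path(dir, "gene_categories.tsv"),
             bed = file.path(dir, "genes.bed"))

  info <- sim$deletions$info
  geno <- sim$deletions$genotypes
  gt_map <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(geno), ncol = ncol(geno))
  ok <- !is.na(geno)
  gt[ok] <- gt_map[geno[ok] + 1L]

  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                   "FORMAT", colnames(geno)), collapse = "\t"))
  body <- vapply(seq_len(nrow(info)), function(i) {
    paste(c(info$chrom[i], info$start[i] - 1L, info$dsv_id[i], "N", "<DEL>",
            ".", "PASS", sprintf("SVTYPE=DEL;END=%d", info$end[i] - 1L),
            "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), paths["vcf"])

  utils::write.table(sim$cohort, paths["cohort"], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  if (!is.null(sim$expression)) {
    ev <- data.frame(gene_id = rownames(sim$expression$values),
                     sim$expression$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(ev, paths["expression"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(gene_id = rownames(sim$expression$values),
                                  category = sim$expression$categories),
                       paths["categories"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  # One synthetic gene model spanning each deletion (+/- 500 bp), BED
  # 0-based half-open: internal 1-based [s, e) maps to [s - 1, e - 1).
  bed <- data.frame(chrom = info$chrom,
                    start = pmax(info$start - 501L, 0L),
                    end = info$end + 499L,
                    name = sub("^DSV", "GENE", info$dsv_id))
  utils::write.table(bed, paths["bed"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
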