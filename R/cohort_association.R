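#' Build a 2x2 contingency table
#'
#' Layout: rows are the exposure (yes/no), columns the group (e.g.
#' cancer/non-cancer, or recurrence/non-recurrence), so the odds ratio
#' `a*d / (b*c)` is > 1 when exposure is enriched in the first group.
#'
#' @param a,b,c,d Non-negative integer counts: `a` exposed/group1,
#'   `b` exposed/group2, `c` unexposed/group1, `d` unexposed/group2.
#' @return 2x2 integer matrix.
#' @export
two_by_two <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  if (sum(x) == 0) stop("empty table")
  matrix(as.integer(x), nrow = 2, byrow = TRUE,
         dimnames = list(exposure = c("yes", "no"), group = c("g1", "g2")))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p-value by the minimum-likelihood rule: the sum of hypergeometric
#' probabilities (margins fixed) of all tables at most as probable as the
#' observed one, with the customary `1 + 1e-7` tolerance factor.
#'
#' @param t 2x2 matrix of counts (see [two_by_two()]).
#' @return The p-value.
#' @export
fisher_exact_two_sided <- function(t) {
  t <- validate_2x2(t)
  if (any(rowSums(t) == 0) || any(colSums(t) == 0)) {
    warning("empty margin; p = 1")
    return(1)
  }
  stats::fisher.test(t)$p.value
}

#' Continuity-corrected (Yates) chi-square test for a 2x2 table
#'
#' `chisq = N * (max(|ad - bc| - N/2, 0))^2 / (r1 r2 c1 c2)` with p from
#' the upper tail of chi-square on 1 df.
#'
#' @param t 2x2 matrix of counts.
#' @return List with `statistic` and `p`.
#' @export
yates_chi_square <- function(t) {
  t <- validate_2x2(t)
  if (any(rowSums(t) == 0) || any(colSums(t) == 0))
    stop("zero margin; chi-square undefined")
  a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
  n <- sum(t)
  num <- max(abs(a * d - b * c) - n / 2, 0)
  stat <- n * num^2 / (prod(rowSums(t)) * prod(colSums(t)))
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Odds ratio with Woolf confidence interval
#'
#' `OR = ad / (bc)` with the log-scale Woolf interval
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is
#' zero the Haldane-Anscombe correction (+0.5 to every cell) is applied and
#' flagged. Two zero cells in a cross pattern leave the OR undefined.
#'
#' @param t 2x2 matrix of counts.
#' @param level Confidence level (default 0.95).
#' @return List with `or`, `ci_low`, `ci_high`, `haldane` flag.
#' @export
odds_ratio_ci <- function(t, level = 0.95) {
  t <- validate_2x2(t)
  a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
  if ((a == 0 && d == 0) || (b == 0 && c == 0))
    stop("odds ratio undefined: two zero cells in a cross pattern")
  haldane <- any(t == 0)
  if (haldane) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or = or, ci_low = or * exp(-z * se), ci_high = or * exp(z * se),
       haldane = haldane)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotone enforcement; order-preserving and
#' idempotent.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

validate_2x2 <- function(t) {
  if (!is.matrix(t) || !all(dim(t) == c(2, 2)))
    stop("need a 2x2 matrix of counts")
  if (any(t < 0) || any(t != round(t))) stop("counts must be non-negative integers")
  if (sum(t) == 0) stop("empty table")
  t
}

# Shared per-unit 2x2 association: exposure vector (logical, length n) vs a
# logical grouping; returns one row of counts + OR/CI/Fisher p.
assoc_row <- function(unit, exposed, in_group1) {
  a <- sum(exposed & in_group1); b <- sum(exposed & !in_group1)
  c <- sum(!exposed & in_group1); d <- sum(!exposed & !in_group1)
  t <- two_by_two(a, b, c, d)
  or <- odds_ratio_ci(t)
  data.frame(unit = unit, a = a, b = b, c = c, d = d,
             odds_ratio = or$or, ci_low = or$ci_low, ci_high = or$ci_high,
             p_raw = fisher_exact_two_sided(t),
             stringsAsFactors = FALSE)
}

finish_assoc <- function(rows) {
  if (length(rows) == 0)
    return(data.frame(unit = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), odds_ratio = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      p_raw = numeric(0), p_adjusted = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adjusted <- bh_adjust(out$p_raw)
  out$direction <- ifelse(out$odds_ratio > 1, "risk", "protective")
  out
}

#' Gene-level deletion frequency spectrum between cohorts
#'
#' A sample is exposed to a gene iff it carries at least one deletion
#' overlapping that gene. Per gene: 2x2 versus cancer status, odds ratio
#' with Woolf CI, two-sided Fisher p, and Benjamini-Hochberg adjustment
#' across genes. Genes carried by no sample or by every sample are skipped
#' (logged), as their odds ratio is undefined.
#'
#' @param carriers A `carrier_matrix`.
#' @param cohort Cohort table with `sample_id`, `cohort_label`.
#' @param gene_map [annotate_genes()] output (dsv_id -> genes).
#' @return data.frame of class `association_result` (one row per gene),
#'   sorted by odds ratio descending.
#' @export
dsv_gene_spectrum <- function(carriers, cohort, gene_map) {
  X <- carriers$carriers[cohort$sample_id, , drop = FALSE]
  is_cancer <- cohort$cohort_label == "cancer"
  genes <- unique(unlist(gene_map))
  rows <- list(); skipped <- character(0)
  for (g in genes) {
    dsvs <- names(gene_map)[vapply(gene_map, function(v) g %in% v, logical(1))]
    dsvs <- intersect(dsvs, colnames(X))
    if (length(dsvs) == 0) next
    exposed <- rowSums(X[, dsvs, drop = FALSE]) > 0
    if (all(exposed) || !any(exposed)) { skipped <- c(skipped, g); next }
    rows[[g]] <- assoc_row(g, exposed, is_cancer)
  }
  if (length(skipped) > 0)
    message(length(skipped), " gene(s) skipped (carried by all or no samples)")
  out <- finish_assoc(rows)
  out <- out[order(-out$odds_ratio), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("association_result", "data.frame")
  out
}

#' Top associations per direction
#' @param res An `association_result` table.
#' @param k How many per direction.
#' @param direction `"risk"` (OR > 1), `"protective"` (OR < 1) or `"both"`.
#' @return Subset of `res`.
#' @export
top_associations <- function(res, k = 10, direction = c("both", "risk", "protective")) {
  direction <- match.arg(direction)
  risk <- res[res$odds_ratio > 1, , drop = FALSE]
  risk <- utils::head(risk[order(-risk$odds_ratio), , drop = FALSE], k)
  prot <- res[res$odds_ratio < 1, , drop = FALSE]
  prot <- utils::head(prot[order(prot$odds_ratio), , drop = FALSE], k)
  switch(direction, risk = risk, protective = prot,
         both = rbind(risk, prot))
}

#' Family-cancer-history association with cancer status
#'
#' 2x2 of FCH (yes/no) by cohort label with odds ratio, Woolf CI and
#' two-sided Fisher p. Samples with unknown FCH are excluded and counted.
#'
#' @param cohort Cohort table with `fch` in yes/no/unknown.
#' @return List with `table`, `or`, `ci_low`, `ci_high`, `p`, `n_excluded`.
#' @export
fch_analysis <- function(cohort) {
  known <- cohort$fch %in% c("yes", "no")
  cc <- cohort[known, , drop = FALSE]
  if (sum(cc$fch == "yes" | cc$fch == "no") == 0 ||
      length(unique(cc$cohort_label)) < 2)
    stop("FCH analysis needs known FCH in both cohorts")
  for (lab in c("cancer", "non-cancer"))
    if (sum(cc$cohort_label == lab) < 2)
      stop("fewer than 2 samples with known FCH in the ", lab, " cohort")
  t <- two_by_two(sum(cc$fch == "yes" & cc$cohort_label == "cancer"),
                  sum(cc$fch == "yes" & cc$cohort_label == "non-cancer"),
                  sum(cc$fch == "no" & cc$cohort_label == "cancer"),
                  sum(cc$fch == "no" & cc$cohort_label == "non-cancer"))
  or <- odds_ratio_ci(t)
  list(table = t, or = or$or, ci_low = or$ci_low, ci_high = or$ci_high,
       p = fisher_exact_two_sided(t), n_excluded = sum(!known))
}

#' Per-gene deletion association with FCH, stratified by cancer status
#'
#' Within the cancer cohort and within the non-cancer cohort separately:
#' per gene, a 2x2 of carrier status by FCH with OR, Fisher p and BH
#' adjustment. Strata below the minimum size are skipped with a warning.
#'
#' @param carriers A `carrier_matrix`.
#' @param cohort Cohort table with `fch`.
#' @param gene_map [annotate_genes()] output; when `NULL`, tests are per
#'   deletion instead of per gene.
#' @param min_stratum Minimum samples required in each FCH cell of a
#'   stratum (default 5).
#' @return Named list of `association_result` tables (`cancer`,
#'   `non-cancer`); skipped strata are absent.
#' @export
fch_stratified_dsv_tests <- function(carriers, cohort, gene_map = NULL,
                                     min_stratum = 5) {
  known <- cohort$fch %in% c("yes", "no")
  cc <- cohort[known, , drop = FALSE]
  out <- list()
  for (lab in c("cancer", "non-cancer")) {
    sub <- cc[cc$cohort_label == lab, , drop = FALSE]
    if (sum(sub$fch == "yes") < min_stratum || sum(sub$fch == "no") < min_stratum) {
      warning("stratum '", lab, "' below minimum size; skipped")
      next
    }
    X <- carriers$carriers[sub$sample_id, , drop = FALSE]
    has_fch <- sub$fch == "yes"
    units <- if (is.null(gene_map)) colnames(X) else unique(unlist(gene_map))
    rows <- list()
    for (u in units) {
      exposed <- if (is.null(gene_map)) X[, u] > 0 else {
        dsvs <- intersect(names(gene_map)[vapply(gene_map, function(v) u %in% v, logical(1))],
                          colnames(X))
        if (length(dsvs) == 0) next
        rowSums(X[, dsvs, drop = FALSE]) > 0
      }
      if (all(exposed) || !any(exposed)) next
      rows[[u]] <- assoc_row(u, exposed, has_fch)
    }
    res <- finish_assoc(rows)
    class(res) <- c("association_result", "data.frame")
    out[[lab]] <- res
  }
  out
}

#' Cohort characteristics table with per-covariate tests
#'
#' Cross-tabulates each categorical covariate against a binary grouping
#' (default recurrence yes/no) with column percentages. Test selection per
#' covariate: Yates-corrected chi-square when the table is 2x2 and all
#' expected counts are >= 5; Pearson chi-square for larger tables with all
#' expected counts >= 5; Fisher's exact test otherwise. The rule applied is
#' recorded per row.
#'
#' @param cohort Cohort table.
#' @param covariates Character vector of column names to test.
#' @param group_var Grouping column (default `"recurrence"`), restricted to
#'   its `"yes"`/`"no"` values.
#' @return List with `counts` (long-format counts and percentages) and
#'   `tests` (covariate, test used, statistic, p; `p` is `NA` for
#'   single-level covariates).
#' @export
characteristics_table <- function(cohort, covariates, group_var = "recurrence") {
  grp <- cohort[[group_var]]
  keep <- grp %in% c("yes", "no")
  cc <- cohort[keep, , drop = FALSE]
  grp <- factor(cc[[group_var]], levels = c("yes", "no"))
  counts <- list(); tests <- list()
  for (v in covariates) {
    tab <- table(factor(cc[[v]]), grp)
    pct <- prop.table(tab, margin = 2) * 100
    counts[[v]] <- data.frame(covariate = v, level = rownames(tab),
                              n_yes = as.integer(tab[, "yes"]),
                              n_no = as.integer(tab[, "no"]),
                              pct_yes = round(pct[, "yes"], 1),
                              pct_no = round(pct[, "no"], 1),
                              stringsAsFactors = FALSE)
    if (nrow(tab) < 2 || any(colSums(tab) == 0)) {
      tests[[v]] <- data.frame(covariate = v, test = "none",
                               statistic = NA_real_, p = NA_real_,
                               stringsAsFactors = FALSE)
      next
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(expected >= 5) && all(dim(tab) == c(2, 2))) {
      yc <- yates_chi_square(unclass(unname(tab)))
      tests[[v]] <- data.frame(covariate = v, test = "yates_chi_square",
                               statistic = yc$statistic, p = yc$p,
                               stringsAsFactors = FALSE)
    } else if (all(expected >= 5)) {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      tests[[v]] <- data.frame(covariate = v, test = "pearson_chi_square",
                               statistic = unname(ct$statistic), p = ct$p.value,
                               stringsAsFactors = FALSE)
    } else {
      p <- stats::fisher.test(tab)$p.value
      tests[[v]] <- data.frame(covariate = v, test = "fisher_exact",
                               statistic = NA_real_, p = p,
                               stringsAsFactors = FALSE)
    }
  }
  list(counts = do.call(rbind, counts), tests = do.call(rbind, tests))
}
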