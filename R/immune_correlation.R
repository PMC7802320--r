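#' Construct an immune expression matrix
#'
#' @param values Numeric matrix, genes in rows, samples in columns; must
#'   have row and column names.
#' @param categories Optional per-gene functional category (one of the six
#'   returned by [immune_categories()]), named by gene or in row order.
#' @param normalized Whether values are already min-max scaled to \[0, 1\].
#' @return List of class `expression_matrix`.
#' @export
expression_matrix <- function(values, categories = NULL, normalized = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) stop("expression matrix needs gene row names")
  if (is.null(colnames(values))) stop("expression matrix needs sample column names")
  if (!is.null(categories)) {
    categories <- as.character(categories)
    if (length(categories) != nrow(values))
      stop("one category per gene required")
    bad <- setdiff(unique(categories), immune_categories())
    if (length(bad) > 0)
      stop("unknown categories: ", paste(bad, collapse = ", "))
    names(categories) <- rownames(values)
  }
  structure(list(values = values, categories = categories,
                 normalized = isTRUE(normalized), constant_genes = character(0)),
            class = "expression_matrix")
}

#' Min-max normalize expression per gene
#'
#' Rescales each gene to `(x - min) / (max - min)` across samples. A gene
#' with zero range is set to all zeros and flagged.
#'
#' @param expr An [expression_matrix].
#' @return The normalized [expression_matrix]; constant genes are listed in
#'   its `constant_genes` field.
#' @export
minmax_normalize <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (ncol(expr$values) < 2) stop("min-max normalization needs >= 2 samples")
  rng <- apply(expr$values, 1, range)
  span <- rng[2, ] - rng[1, ]
  const <- span == 0
  span[const] <- 1
  expr$values <- (expr$values - rng[1, ]) / span
  expr$values[const, ] <- 0
  if (any(const)) {
    warning(sum(const), " constant gene(s) set to zero after min-max scaling")
    expr$constant_genes <- rownames(expr$values)[const]
  }
  expr$normalized <- TRUE
  expr
}

#' Point-biserial correlation
#'
#' Correlation of a continuous variable with a dichotomous one, computed by
#' the group-means formula
#' `r = (mean(y1) - mean(y0)) / s_y * sqrt(n1 * n0 / n^2)`
#' with `s_y` the population (divide-by-n) standard deviation. Algebraically
#' identical to the Pearson correlation of `y` with 0/1-coded `x`.
#'
#' @param x Binary (0/1 or logical) vector with both values present.
#' @param y Continuous vector of the same length.
#' @return The correlation in \[-1, 1\].
#' @export
point_biserial <- function(x, y) {
  x <- as.integer(as.logical(x))
  if (length(x) != length(y)) stop("x and y must have equal length")
  n1 <- sum(x == 1L); n0 <- sum(x == 0L); n <- n1 + n0
  if (n1 == 0L || n0 == 0L) stop("x must take both values")
  s_y <- sqrt(sum((y - mean(y))^2) / n)
  if (s_y == 0) stop("y is constant; correlation undefined")
  (mean(y[x == 1L]) - mean(y[x == 0L])) / s_y * sqrt(n1 * n0 / n^2)
}

#' Screen deletions against immune expression by point-biserial correlation
#'
#' Computes the full deletion-by-gene point-biserial correlation matrix on
#' the sample intersection (vectorized group-means formula). A deletion is
#' called immune-associated when its largest absolute correlation over genes
#' exceeds the threshold (set `use_abs = FALSE` for a positive-only rule).
#'
#' @param carriers A `carrier_matrix`.
#' @param expr A normalized [expression_matrix].
#' @param threshold Correlation cutoff (default 0.3).
#' @param use_abs Apply the cutoff to `|r|` (default) or to `r`.
#' @return List of class `correlation_screen`: `r` (deletions x genes),
#'   `pairs` (selected pairs), `immune_dsv_ids`, `threshold`, `categories`.
#' @export
correlation_screen <- function(carriers, expr, threshold = 0.3, use_abs = TRUE) {
  stopifnot(inherits(carriers, "carrier_matrix"), inherits(expr, "expression_matrix"))
  samples <- intersect(rownames(carriers$carriers), colnames(expr$values))
  if (length(samples) < 10)
    stop("need >= 10 overlapping samples, got ", length(samples))
  X <- carriers$carriers[samples, , drop = FALSE]        # n x m
  Y <- expr$values[, samples, drop = FALSE]              # g x n
  n <- length(samples)
  n1 <- colSums(X); n0 <- n - n1
  usable <- n1 > 0 & n0 > 0
  if (any(!usable))
    warning(sum(!usable), " deletion(s) with constant carrier status skipped")
  mu1 <- t(Y %*% X) / n1                                  # m x g mean in carriers
  mu0 <- t(Y %*% (1 - X)) / n0
  s_y <- sqrt(rowMeans(Y^2) - rowMeans(Y)^2)              # population sd per gene
  r <- sweep(mu1 - mu0, 2, s_y, "/") * sqrt(n1 * n0 / n^2)
  r[!usable, ] <- NA_real_
  r[, s_y == 0] <- NA_real_
  dimnames(r) <- list(colnames(X), rownames(Y))

  score <- if (use_abs) abs(r) else r
  sel <- which(!is.na(score) & score > threshold, arr.ind = TRUE)
  pairs <- data.frame(dsv_id = rownames(r)[sel[, 1]],
                      gene_id = colnames(r)[sel[, 2]],
                      r = r[sel], stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$dsv_id, -abs(pairs$r)), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(r = r, pairs = pairs,
                 immune_dsv_ids = unique(pairs$dsv_id),
                 threshold = threshold, use_abs = use_abs,
                 categories = expr$categories,
                 panel_genes = rownames(Y)),
            class = "correlation_screen")
}

#' Per-deletion immune-category composition and enrichment
#'
#' For every immune-associated deletion, the fraction of its selected genes
#' falling in each of the six functional categories, with a hypergeometric
#' enrichment test (upper tail: drawing that many category genes given the
#' category size, the panel size, and the deletion's selected-gene count)
#' and Benjamini-Hochberg adjustment across all deletion-by-category cells.
#'
#' @param screen A [correlation_screen()] result built from an expression
#'   matrix with categories.
#' @return data.frame with `dsv_id`, `category`, `n_selected`, `ratio`,
#'   `p`, `p_adj`.
#' @export
category_summary <- function(screen) {
  stopifnot(inherits(screen, "correlation_screen"))
  if (is.null(screen$categories)) stop("expression matrix had no categories")
  if (nrow(screen$pairs) == 0) stop("no selected pairs in screen")
  panel <- screen$panel_genes
  cat_of <- screen$categories[panel]
  cat_sizes <- table(factor(cat_of, levels = immune_categories()))
  N <- length(panel)
  rows <- lapply(split(screen$pairs, screen$pairs$dsv_id), function(pp) {
    s <- nrow(pp)
    k <- table(factor(screen$categories[pp$gene_id], levels = immune_categories()))
    data.frame(dsv_id = pp$dsv_id[1], category = names(k),
               n_selected = as.integer(k), ratio = as.integer(k) / s,
               p = stats::phyper(as.integer(k) - 1L, as.integer(cat_sizes),
                                 N - as.integer(cat_sizes), s, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- bh_adjust(out$p)
  out
}
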