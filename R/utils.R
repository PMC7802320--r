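# Internal helpers shared across modules.

# Rank-based AUC (Mann-Whitney). `labels` is logical/0-1 with TRUE = positive.
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Derive a per-stage substream seed from a global seed, kept below 2^31.
substream_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(stage)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x != round(x))
    stop(sprintf("'%s' must be a positive integer", name), call. = FALSE)
}

assert_prob <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < lo) || any(x > hi))
    stop(sprintf("'%s' must lie in [%g, %g]", name, lo, hi), call. = FALSE)
}
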