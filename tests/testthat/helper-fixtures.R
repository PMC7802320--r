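# Fixture builders shared across test files. Everything is generated in
# code; no binary data.

# Write a minimal SV VCF. `records` is a data.frame with columns chrom, pos,
# id, svtype, end (VCF END), and optionally svlen; `gt` is a records x
# samples character matrix of GT strings (NULL for a site-only VCF with one
# dummy sample).
write_test_vcf <- function(path, records, gt = NULL) {
  if (is.null(gt)) gt <- matrix("0/1", nrow(records), 1,
                                dimnames = list(NULL, "S1"))
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(gt)), collapse = "\t"))
  body <- vapply(seq_len(nrow(records)), function(i) {
    info <- sprintf("SVTYPE=%s;END=%d", records$svtype[i], records$end[i])
    if (!is.null(records$svlen) && !is.na(records$svlen[i]))
      info <- paste0(info, sprintf(";SVLEN=%d", records$svlen[i]))
    paste(c(records$chrom[i], records$pos[i], records$id[i], "N", "<DEL>",
            ".", "PASS", info, "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# A dsv_set built directly (bypassing VCF) from coordinate rows and a
# genotype matrix (dsv x sample).
make_dsv_set <- function(info, genotypes) {
  rownames(genotypes) <- info$dsv_id
  structure(list(info = info, genotypes = genotypes), class = "dsv_set")
}

make_cohort <- function(n_cancer, n_control) {
  n <- n_cancer + n_control
  data.frame(sample_id = sprintf("S%04d", seq_len(n)),
             cohort_label = rep(c("cancer", "non-cancer"), c(n_cancer, n_control)),
             stringsAsFactors = FALSE)
}

# Independent exhaustive two-sided Fisher oracle: sum of hypergeometric
# probabilities (margins fixed) at most (1 + 1e-7) times the observed one.
fisher_enum_oracle <- function(t) {
  r1 <- sum(t[1, ]); r2 <- sum(t[2, ]); c1 <- sum(t[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(t[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Plug-in theoretical point-biserial correlation for y = beta * x + noise
# with carrier probability p and noise sd sigma.
theoretical_r_pb <- function(beta, p, sigma) {
  beta * sqrt(p * (1 - p)) / sqrt(beta^2 * p * (1 - p) + sigma^2)
}

# Carrier-status allele frequency giving carrier probability p under HWE.
allele_freq_for_carrier <- function(p) 1 - sqrt(1 - p)
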