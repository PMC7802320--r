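#' Read deletion structural variants from a VCF
#'
#' Parses SVTYPE=DEL records. Internally the first deleted base is `POS + 1`
#' (VCF anchors a deletion on the padding base before it) and the stored end
#' is exclusive, so `length = end - start = END - POS`, matching how deletion
#' lengths are conventionally reported. Non-DEL records are skipped with a
#' message; missing genotypes are preserved as `NA`.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF.
#' @return A `dsv_set`: list with `info` (dsv_id, chrom, start, end) and
#'   `genotypes` (deletion-by-sample deleted-copy counts, `NA` = missing).
#' @export
read_deletions_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  svtype <- vcfR::extract.info(vcf, "SVTYPE")
  end_info <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "END")))
  svlen <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "SVLEN")))

  is_del <- !is.na(svtype) & svtype == "DEL"
  n_skip <- sum(!is_del)
  if (n_skip > 0) message(n_skip, " non-DEL record(s) skipped")
  if (!any(is_del)) stop("no SVTYPE=DEL records in ", path)

  pos <- as.integer(fix[is_del, "POS"])
  end <- end_info[is_del]
  if (any(is.na(end)))
    stop("DEL record(s) without an END INFO key at line(s): ",
         paste(which(is.na(end)), collapse = ", "))
  bad <- end <= pos
  if (any(bad))
    stop("END <= POS for record(s) ", paste(which(bad), collapse = ", "),
         " (a deletion must span at least one base)")
  sl <- svlen[is_del]
  inconsistent <- !is.na(sl) & abs(sl) != (end - pos)
  if (any(inconsistent))
    stop("END and SVLEN disagree for record(s) ",
         paste(which(inconsistent), collapse = ", "))

  ids <- fix[is_del, "ID"]
  ids[is.na(ids) | ids == "."] <- sprintf("DSV%04d", which(is.na(ids) | ids == "."))

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[is_del, , drop = FALSE]
  geno <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = list(ids, colnames(gt)))
  clean <- gsub("\\|", "/", gt)
  geno[clean %in% c("0/0")] <- 0L
  geno[clean %in% c("0/1", "1/0")] <- 1L
  geno[clean %in% c("1/1")] <- 2L

  info <- data.frame(dsv_id = ids,
                     chrom = as.character(fix[is_del, "CHROM"]),
                     start = pos + 1L, end = end + 1L,
                     stringsAsFactors = FALSE)
  structure(list(info = info, genotypes = geno), class = "dsv_set")
}

#' Deletion length in base pairs
#'
#' `end - start` under the package convention (start = first deleted base,
#' end exclusive), i.e. `END - POS` of the VCF record.
#'
#' @param dsvs A `dsv_set`, or a data.frame with `start` and `end` columns.
#' @return Integer vector of lengths.
#' @export
deletion_length <- function(dsvs) {
  info <- if (inherits(dsvs, "dsv_set")) dsvs$info else dsvs
  as.integer(info$end - info$start)
}

#' Deletion filter parameters
#'
#' Defaults follow the study design: autosomal deletions of 500-10,000 bp,
#' minor allele frequency at least 0.05 over the combined cohort, and a
#' carrier in at least 1% of the samples of each cohort separately.
#'
#' @param min_len,max_len Length bounds in bp.
#' @param min_maf Minimum folded minor allele frequency.
#' @param min_carrier_frac_per_cohort Minimum carrier fraction required in
#'   the cancer cohort and in the non-cancer cohort.
#' @param autosomes_only Keep chromosomes 1-22 only.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(min_len = 500, max_len = 10000, min_maf = 0.05,
                          min_carrier_frac_per_cohort = 0.01,
                          autosomes_only = TRUE) {
  if (min_len <= 0 || min_len > max_len) stop("need 0 < min_len <= max_len")
  assert_prob(min_maf, "min_maf", 0, 0.5)
  assert_prob(min_carrier_frac_per_cohort, "min_carrier_frac_per_cohort")
  structure(list(min_len = min_len, max_len = max_len, min_maf = min_maf,
                 min_carrier_frac_per_cohort = min_carrier_frac_per_cohort,
                 autosomes_only = isTRUE(autosomes_only)),
            class = "filter_params")
}

#' Filter deletions on size, chromosome, MAF and per-cohort presence
#'
#' Keeps deletions that are (i) autosomal, (ii) within the length bounds,
#' (iii) at folded minor allele frequency `>= min_maf` computed over all
#' called genotypes (missing excluded from the denominator), and (iv)
#' carried by at least `min_carrier_frac_per_cohort` of the samples of the
#' cancer cohort AND of the non-cancer cohort (missing genotypes count as
#' non-carriers). Record order is preserved.
#'
#' @param dsvs A `dsv_set`.
#' @param cohort Cohort table with `sample_id` and `cohort_label`.
#' @param params A [filter_params()].
#' @return List with `dsvs` (filtered `dsv_set`), `tally` (per-criterion
#'   rejection counts; a record failing several criteria is counted under
#'   each) and `params`.
#' @export
filter_deletions <- function(dsvs, cohort, params = filter_params()) {
  stopifnot(inherits(dsvs, "dsv_set"))
  labs <- cohort$cohort_label
  if (sum(labs == "cancer") == 0L || sum(labs == "non-cancer") == 0L)
    stop("cohort must contain both cancer and non-cancer samples")
  geno <- dsvs$genotypes[, cohort$sample_id, drop = FALSE]
  info <- dsvs$info

  pass_chr <- if (params$autosomes_only)
    sub("^chr", "", info$chrom) %in% as.character(1:22) else rep(TRUE, nrow(info))
  len <- deletion_length(dsvs)
  pass_len <- len >= params$min_len & len <= params$max_len

  called <- !is.na(geno)
  alt <- rowSums(geno, na.rm = TRUE)
  f <- alt / (2 * rowSums(called))
  maf <- pmin(f, 1 - f)
  pass_maf <- !is.na(maf) & maf >= params$min_maf

  carrier <- !is.na(geno) & geno >= 1L
  frac_case <- rowSums(carrier[, labs == "cancer", drop = FALSE]) / sum(labs == "cancer")
  frac_ctrl <- rowSums(carrier[, labs == "non-cancer", drop = FALSE]) / sum(labs == "non-cancer")
  pass_cohort <- frac_case >= params$min_carrier_frac_per_cohort &
    frac_ctrl >= params$min_carrier_frac_per_cohort

  keep <- pass_chr & pass_len & pass_maf & pass_cohort
  tally <- c(non_autosomal = sum(!pass_chr), length = sum(!pass_len),
             maf = sum(!pass_maf), cohort_presence = sum(!pass_cohort))
  out <- structure(list(info = info[keep, , drop = FALSE],
                        genotypes = dsvs$genotypes[keep, , drop = FALSE]),
                   class = "dsv_set")
  list(dsvs = out, tally = tally, params = params)
}

#' Build the binary carrier matrix
#'
#' A sample carries a deletion iff its genotype has at least one deleted
#' copy; missing genotypes are encoded as non-carriers (their count is
#' reported with a message).
#'
#' @param dsvs A `dsv_set` (typically after [filter_deletions()]).
#' @param cohort Cohort table; its `sample_id` order defines the row order.
#' @return A `carrier_matrix`: list with `carriers` (samples x deletions
#'   binary matrix) and `dsv` (deletion metadata, one row per column).
#' @export
build_carrier_matrix <- function(dsvs, cohort) {
  stopifnot(inherits(dsvs, "dsv_set"))
  if (anyDuplicated(dsvs$info$dsv_id))
    stop("duplicate deletion ids: ",
         paste(unique(dsvs$info$dsv_id[duplicated(dsvs$info$dsv_id)]), collapse = ", "))
  geno <- dsvs$genotypes[, cohort$sample_id, drop = FALSE]
  n_missing <- sum(is.na(geno))
  if (n_missing > 0)
    message(n_missing, " missing genotype(s) encoded as non-carriers")
  x <- t((!is.na(geno)) & geno >= 1L) * 1L
  dimnames(x) <- list(cohort$sample_id, dsvs$info$dsv_id)
  structure(list(carriers = x, dsv = dsvs$info), class = "carrier_matrix")
}

#' @export
print.carrier_matrix <- function(x, ...) {
  cat(sprintf("carrier_matrix: %d samples x %d deletions (%.1f%% carriers)\n",
              nrow(x$carriers), ncol(x$carriers), 100 * mean(x$carriers)))
  invisible(x)
}

#' Read gene models from a BED file
#'
#' BED is 0-based half-open; intervals are converted to 1-based closed
#' coordinates internally.
#'
#' @param path BED3+name file (chrom, start, end, name).
#' @return data.frame with `chrom`, `start`, `end` (1-based closed), `name`.
#' @export
read_genes_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop("BED file needs at least 4 columns (chrom, start, end, name)")
  data.frame(chrom = as.character(bed[[1]]), start = bed[[2]] + 1L,
             end = bed[[3]], name = as.character(bed[[4]]),
             stringsAsFactors = FALSE)
}

#' Map deletions to overlapping genes
#'
#' A deletion maps to every gene whose interval overlaps the deleted bases
#' by at least 1 bp under half-open logic (a deletion whose exclusive end
#' abuts a gene start does not overlap it). Interval lookup uses an interval
#' tree via `GenomicRanges::findOverlaps()`.
#'
#' @param dsvs A `dsv_set`.
#' @param genes Gene table from [read_genes_bed()] (1-based closed coords).
#' @return Named list: `dsv_id` -> character vector of gene names (possibly
#'   empty).
#' @export
annotate_genes <- function(dsvs, genes) {
  info <- dsvs$info
  if (!any(info$chrom %in% genes$chrom))
    stop("no shared chromosome names between deletions and genes ",
         "(check 'chr' prefix consistency, e.g. chr7 vs 7)")
  d_gr <- GenomicRanges::GRanges(info$chrom,
                                 IRanges::IRanges(info$start, info$end - 1L))
  g_gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(d_gr, g_gr, minoverlap = 1L)
  out <- rep(list(character(0)), nrow(info))
  names(out) <- info$dsv_id
  if (length(hits) > 0) {
    sp <- split(genes$name[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    for (q in names(sp)) out[[as.integer(q)]] <- unique(sp[[q]])
  }
  out
}

#' Read a cohort table from TSV
#' @param path TSV with header; must contain `sample_id` and `cohort_label`.
#' @return data.frame.
#' @export
read_cohort_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "cohort_label") %in% names(tab)))
    stop("cohort table needs 'sample_id' and 'cohort_label' columns")
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample ids in cohort table")
  tab
}

#' Read an expression matrix (genes x samples) and categories from TSV
#' @param path Expression TSV: first column `gene_id`, one column per sample.
#' @param category_path Optional TSV with `gene_id` and `category` columns.
#' @return An [expression_matrix].
#' @export
read_expression_tsv <- function(path, category_path = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- tab[[1]]
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- genes
  categories <- NULL
  if (!is.null(category_path)) {
    ct <- utils::read.delim(category_path, stringsAsFactors = FALSE)
    categories <- stats::setNames(ct$category, ct$gene_id)[genes]
  }
  expression_matrix(values, categories, normalized = FALSE)
}
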