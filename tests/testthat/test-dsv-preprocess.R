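test_that("VCF deletion lengths follow the END - POS convention", {
  path <- tempfile(fileext = ".vcf")
  write_test_vcf(path, data.frame(
    chrom = c("7", "7"), pos = c(104473711, 26241421),
    id = c("del_lhfpl3", "del_cbx3"), svtype = "DEL",
    end = c(104474263, 26245980)))
  dsvs <- read_deletions_vcf(path)
  expect_equal(deletion_length(dsvs), c(552L, 4559L))
})

test_that("non-DEL records are skipped and malformed coordinates error", {
  path <- tempfile(fileext = ".vcf")
  write_test_vcf(path, data.frame(chrom = "1", pos = c(100, 200),
                                  id = c("d1", "i1"), svtype = c("DEL", "INS"),
                                  end = c(700, 300)))
  expect_message(dsvs <- read_deletions_vcf(path), "non-DEL")
  expect_equal(nrow(dsvs$info), 1L)

  path2 <- tempfile(fileext = ".vcf")
  write_test_vcf(path2, data.frame(chrom = "1", pos = 500, id = "bad",
                                   svtype = "DEL", end = 400))
  expect_error(read_deletions_vcf(path2), "END <= POS")

  path3 <- tempfile(fileext = ".vcf")
  write_test_vcf(path3, data.frame(chrom = "1", pos = 100, id = "d",
                                   svtype = "DEL", end = 700, svlen = -900))
  expect_error(read_deletions_vcf(path3), "SVLEN")
})

test_that("missing and phased genotypes are decoded correctly", {
  path <- tempfile(fileext = ".vcf")
  gt <- matrix(c("0/0", "0|1", "1/1", "./."), 1, 4,
               dimnames = list(NULL, paste0("S", 1:4)))
  write_test_vcf(path, data.frame(chrom = "2", pos = 1000, id = "d1",
                                  svtype = "DEL", end = 2000), gt)
  dsvs <- read_deletions_vcf(path)
  expect_equal(unname(dsvs$genotypes[1, ]), c(0L, 1L, 2L, NA))
})

# A 6-record fixture in which each failing record violates exactly one
# criterion: chrX; too short; too long; rare (MAF < 0.05 but carriers in
# both cohorts); absent from controls; fully passing.
make_filter_fixture <- function() {
  n <- 100  # 50 cancer + 50 control
  cohort <- make_cohort(50, 50)
  g <- function(idx_carrier) {
    v <- rep(0L, n); v[idx_carrier] <- 1L; v
  }
  geno <- rbind(
    g(c(1:20, 51:70)),   # chrX, otherwise fine
    g(c(1:20, 51:70)),   # 400 bp
    g(c(1:20, 51:70)),   # 12000 bp
    g(c(1, 51)),         # MAF = 2/200 = 0.01 < 0.05; 1 carrier per cohort
    g(1:30),             # cancer-only carriers
    g(c(1:20, 51:70))    # passes everything
  )
  colnames(geno) <- cohort$sample_id
  info <- data.frame(
    dsv_id = paste0("D", 1:6),
    chrom = c("X", "1", "2", "3", "4", "5"),
    start = rep(1000L, 6),
    end = 1000L + c(1000L, 400L, 12000L, 1000L, 1000L, 1000L))
  list(dsvs = make_dsv_set(info, geno), cohort = cohort)
}

test_that("each filter criterion rejects exactly its violating record", {
  fx <- make_filter_fixture()
  fl <- filter_deletions(fx$dsvs, fx$cohort)
  expect_equal(fl$dsvs$info$dsv_id, "D6")
  expect_equal(unname(fl$tally),
               c(1L, 2L, 1L, 1L))  # non_autosomal, length, maf, cohort_presence
  expect_equal(unname(fl$tally["maf"]), 1L)
})

test_that("vacuous filters pass everything and tightening MAF is monotone", {
  fx <- make_filter_fixture()
  auto <- fx$dsvs
  keep <- auto$info$chrom != "X" & deletion_length(auto) >= 500 &
    deletion_length(auto) <= 10000
  auto <- make_dsv_set(auto$info[keep, ], auto$genotypes[keep, , drop = FALSE])
  fl0 <- filter_deletions(auto, fx$cohort,
                          filter_params(min_maf = 0, min_carrier_frac_per_cohort = 0))
  expect_equal(nrow(fl0$dsvs$info), nrow(auto$info))

  fl05 <- filter_deletions(fx$dsvs, fx$cohort, filter_params(min_maf = 0.05))
  fl10 <- filter_deletions(fx$dsvs, fx$cohort, filter_params(min_maf = 0.10))
  expect_true(all(fl10$dsvs$info$dsv_id %in% fl05$dsvs$info$dsv_id))
})

test_that("filtering is idempotent", {
  fx <- make_filter_fixture()
  once <- filter_deletions(fx$dsvs, fx$cohort)
  twice <- filter_deletions(once$dsvs, fx$cohort)
  expect_identical(once$dsvs, twice$dsvs)
  expect_true(all(twice$tally == 0))
})

test_that("a single-label cohort is rejected", {
  fx <- make_filter_fixture()
  bad <- fx$cohort; bad$cohort_label <- "cancer"
  expect_error(filter_deletions(fx$dsvs, bad), "both")
})

test_that("carrier encoding maps genotypes 0/1/2/missing to 0/1/1/0", {
  cohort <- make_cohort(2, 2)
  geno <- matrix(c(0L, 1L, 2L, NA), 1, 4,
                 dimnames = list("D1", cohort$sample_id))
  dsvs <- make_dsv_set(data.frame(dsv_id = "D1", chrom = "1",
                                  start = 100L, end = 700L), geno)
  expect_message(cm <- build_carrier_matrix(dsvs, cohort), "missing")
  expect_equal(unname(cm$carriers[, 1]), c(0L, 1L, 1L, 0L))

  dup <- make_dsv_set(data.frame(dsv_id = c("D1", "D1"), chrom = "1",
                                 start = 100L, end = 700L),
                      rbind(geno, geno))
  expect_error(build_carrier_matrix(dup, cohort), "duplicate")
})

test_that("an empty deletion set yields a zero-column carrier matrix", {
  cohort <- make_cohort(2, 2)
  empty <- make_dsv_set(data.frame(dsv_id = character(0), chrom = character(0),
                                   start = integer(0), end = integer(0)),
                        matrix(integer(0), 0, 4,
                               dimnames = list(NULL, cohort$sample_id)))
  cm <- build_carrier_matrix(empty, cohort)
  expect_equal(dim(cm$carriers), c(4L, 0L))
})

test_that("gene annotation uses half-open overlap logic", {
  dsvs <- make_dsv_set(
    data.frame(dsv_id = c("D1", "D2", "D3"), chrom = "7",
               start = c(104473712L, 1000L, 5000L),
               end = c(104474264L, 2000L, 6000L)),
    matrix(1L, 3, 2, dimnames = list(NULL, c("S1", "S2"))))
  genes <- data.frame(chrom = "7",
                      start = c(104400001L, 2000L, 5500L, 5900L),
                      end = c(104600000L, 3000L, 5700L, 6200L),
                      name = c("LHFPL3", "ABUT", "GA", "GB"))
  ann <- annotate_genes(dsvs, genes)
  expect_equal(ann$D1, "LHFPL3")
  # D2 spans [1000, 2000); gene ABUT starts at 2000 -> abutment, no overlap
  expect_equal(ann$D2, character(0))
  # D3 spans two genes
  expect_setequal(ann$D3, c("GA", "GB"))
})

test_that("chromosome naming mismatches raise a helpful error", {
  dsvs <- make_dsv_set(data.frame(dsv_id = "D1", chrom = "chr7",
                                  start = 1000L, end = 2000L),
                       matrix(1L, 1, 1, dimnames = list(NULL, "S1")))
  genes <- data.frame(chrom = "7", start = 1L, end = 5000L, name = "G")
  expect_error(annotate_genes(dsvs, genes), "chr")
})

test_that("a written fixture bundle round-trips losslessly", {
  cfg <- simulation_config(n_cancer = 25, n_control = 30, m_background = 12,
                           planted_hazard = data.frame(dsv = 1, loghr = 0.5),
                           n_genes = 6, seed = 17)
  sim <- simulate_cohort(cfg)
  dir <- tempfile()
  paths <- write_fixture_bundle(sim, dir)

  dsvs <- read_deletions_vcf(paths["vcf"])
  cohort <- read_cohort_tsv(paths["cohort"])
  expect_equal(dsvs$info$start, sim$deletions$info$start)
  expect_equal(deletion_length(dsvs), deletion_length(sim$deletions))
  cm <- build_carrier_matrix(dsvs, cohort)
  expect_equal(cm$carriers, sim$carriers$carriers)

  expr <- read_expression_tsv(paths["expression"], paths["categories"])
  expect_equal(expr$values, sim$expression$values, tolerance = 1e-8)
  expect_equal(unname(expr$categories), unname(sim$expression$categories))

  genes <- read_genes_bed(paths["bed"])
  ann <- annotate_genes(dsvs, genes)
  # every deletion is covered by its own synthetic gene model
  expect_true(all(mapply(function(a, id) sub("DSV", "GENE", id) %in% a,
                         ann, dsvs$info$dsv_id)))
})
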