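test_that("PLINK bed/bim/fam round-trips losslessly, including missing", {
  cfg <- sim_config(n_individuals = 23, n_chromosomes = 2, snps_per_chrom = 17,
                    missing_rate = 0.05, seed = 9)
  g <- simulate_genotypes(cfg)
  expect_gt(sum(is.na(g$dosage)), 0)
  d <- withr::local_tempdir()
  sim <- simulate_phenotypes(g, cfg)
  paths <- write_fixture_set(g, sim$traits, d)
  g2 <- read_plink(file.path(d, "sim"))
  expect_identical(g$dosage, g2$dosage)
  expect_equal(g$map$bp, g2$map$bp)
  expect_equal(g$map$chrom, g2$map$chrom)
  # phenotype file readable and aligned
  ph <- utils::read.table(paths$pheno, header = TRUE, sep = "\t")
  expect_equal(ph$id, geno_ids(g))
})

test_that("bed payload size follows the 2-bit packing arithmetic", {
  g <- tiny_geno(matrix(0L, 3, 5))
  prefix <- file.path(withr::local_tempdir(), "t")
  write_plink(g, prefix)
  expect_equal(file.size(paste0(prefix, ".bed")),
               ceiling(3 / 4) * 5 + 3)
})

test_that("hand-crafted bed bytes decode to the documented dosages", {
  # 1 individual, 4 SNPs: codes 00 (hom A1 -> 2), 10 (het -> 1),
  # 11 (hom A2 -> 0), 01 (missing); one byte per SNP, code in the low bits
  d <- withr::local_tempdir()
  con <- file(file.path(d, "h.bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x00, 0x02, 0x03, 0x01)), con)
  close(con)
  writeLines(sprintf("1\tsnp%d\t0\t%d\tA\tB", 1:4, 1:4 * 100),
             file.path(d, "h.bim"))
  writeLines("fam1\tind1\t0\t0\t0\t-9", file.path(d, "h.fam"))
  g <- read_plink(file.path(d, "h"))
  expect_equal(as.vector(g$dosage), c(2L, 1L, 0L, NA))
})

test_that("corrupt bed files raise format errors", {
  d <- withr::local_tempdir()
  g <- tiny_geno(matrix(1L, 4, 3))
  write_plink(g, file.path(d, "ok"))
  # truncate the payload
  raw_all <- readBin(file.path(d, "ok.bed"), "raw", 100)
  writeBin(raw_all[1:(length(raw_all) - 1)], file.path(d, "trunc.bed"))
  file.copy(file.path(d, "ok.bim"), file.path(d, "trunc.bim"))
  file.copy(file.path(d, "ok.fam"), file.path(d, "trunc.fam"))
  expect_error(read_plink(file.path(d, "trunc")), "format error")
  # corrupt the magic
  raw_all[1] <- as.raw(0)
  writeBin(raw_all, file.path(d, "bad.bed"))
  file.copy(file.path(d, "ok.bim"), file.path(d, "bad.bim"))
  file.copy(file.path(d, "ok.fam"), file.path(d, "bad.fam"))
  expect_error(read_plink(file.path(d, "bad")), "magic")
})

test_that("allele frequencies handle missing and monomorphic markers", {
  g <- tiny_geno(cbind(c(0L, 1L, 2L), c(2L, 2L, 2L), c(0L, 1L, NA)))
  af <- allele_freq(g)
  expect_equal(af$p, c(0.5, 1, 0.25))
  expect_equal(af$maf, c(0.5, 0, 0.25))
  g_all_na <- tiny_geno(cbind(c(NA, NA, NA), c(0L, 1L, 2L)))
  af2 <- allele_freq(g_all_na)
  expect_true(af2$all_missing[1])
  expect_true(is.na(af2$p[1]))
})

test_that("Hardy-Weinberg chi-square test matches hand-computed cases", {
  expect_equal(hwe_test(25, 50, 25), 1)            # exact HWE proportions
  # complete heterozygote deficit at p = 0.5: chi2 = n
  expect_equal(hwe_test(50, 0, 50),
               pchisq(100, df = 1, lower.tail = FALSE))
  expect_lt(hwe_test(50, 0, 50), 1e-22)
  expect_equal(hwe_test(100, 0, 0), 1)             # monomorphic convention
})

test_that("QC thresholds straddle as documented", {
  # MAF 0.04 removed, 0.06 kept, at n = 50 individuals
  n <- 50
  make_col <- function(maf) {
    x <- integer(n)
    x[seq_len(round(2 * n * maf))] <- 1L
    x
  }
  g <- tiny_geno(cbind(make_col(0.04), make_col(0.06), make_col(0.3)))
  qc <- qc_filter(g)
  expect_equal(qc$report$removed_by_maf, 1)
  expect_true(all(c("s2", "s3") %in% qc$geno$map$snp_id))
  expect_false("s1" %in% qc$geno$map$snp_id)
})

test_that("planted violations are counted by the responsible filter", {
  set.seed(42)
  n <- 200
  clean <- function() rbinom(n, 2, 0.3)
  low_maf <- c(rep(1L, 2), rep(0L, n - 2))            # maf 0.005
  high_miss <- { x <- clean(); x[1:30] <- NA; x }     # 15% missing
  hwe_fail <- rep(c(0L, 2L), n / 2)                   # no heterozygotes
  # enough clean markers that no individual exceeds 10% missing calls
  g <- tiny_geno(cbind(sapply(1:12, function(i) clean()),
                       low_maf, high_miss, hwe_fail))
  qc <- qc_filter(g)
  expect_equal(qc$report$removed_by_maf, 1)
  expect_equal(qc$report$removed_by_callrate, 1)
  expect_equal(qc$report$removed_by_hwe, 1)
  # accounting identity
  rep_ <- qc$report
  expect_equal(rep_$n_snps_in - rep_$n_snps_out,
               rep_$removed_by_maf + rep_$removed_by_callrate +
                 rep_$removed_by_hwe + rep_$removed_non_autosomal)
})

test_that("QC is idempotent and a no-op on clean data", {
  s <- sim_case(n = 100, chrom = 1, m_per = 60, seed = 13)
  qc1 <- qc_filter(s$geno)
  qc2 <- qc_filter(qc1$geno)
  expect_identical(qc1$geno$dosage, qc2$geno$dosage)
  expect_equal(qc2$report$n_snps_in, qc2$report$n_snps_out)
  expect_equal(qc2$report$n_ind_in, qc2$report$n_ind_out)
})

test_that("individuals with excess missingness are removed first", {
  set.seed(1)
  d <- matrix(rbinom(40 * 20, 2, 0.4), 40, 20)
  d[1, 1:10] <- NA  # individual 1 at 50% missing
  g <- tiny_geno(d)
  qc <- qc_filter(g)
  expect_equal(qc$report$removed_ind_missing, 1)
  expect_equal(nrow(qc$geno$dosage), 39)
  # non-autosomal markers dropped
  g2 <- tiny_geno(matrix(rbinom(60, 2, 0.4), 20, 3), chrom = c(1L, 30L, 2L))
  expect_equal(qc_filter(g2)$report$removed_non_autosomal, 1)
})
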