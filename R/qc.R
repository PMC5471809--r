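#' Per-marker allele frequency
#'
#' Frequency of the A1 allele from non-missing calls:
#' `p = mean(dosage) / 2`.
#'
#' @param geno A [geno_matrix()].
#' @return Tibble with `snp_id`, `p` (A1 frequency), `maf`
#'   (`min(p, 1 - p)`), `n_called`, and `all_missing` flagging markers with
#'   no observed call (these carry `p = NA` and must be excluded
#'   downstream).
#' @examples
#' g <- geno_matrix(matrix(c(0L, 1L, 2L), 3, 1),
#'                  data.frame(snp_id = "s", chrom = 1, bp = 1))
#' allele_freq(g)$p  # 0.5
#' @export
allele_freq <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  n_called <- colSums(!is.na(geno$dosage))
  p <- colMeans(geno$dosage, na.rm = TRUE) / 2
  p[n_called == 0] <- NA_real_
  tibble::tibble(snp_id = geno$map$snp_id, p = unname(p),
                 maf = pmin(p, 1 - p), n_called = unname(n_called),
                 all_missing = n_called == 0)
}

#' Chi-square test for Hardy-Weinberg equilibrium
#'
#' Goodness-of-fit test of observed genotype counts against Hardy-Weinberg
#' expectations computed from the observed allele frequency, 1 degree of
#' freedom. Monomorphic markers return `p = 1` by convention.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (A = A1 allele).
#' @return The chi-square p-value.
#' @examples
#' hwe_test(25, 50, 25)  # exact HWE proportions -> 1
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n <= 0) stop("no genotype calls", call. = FALSE)
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((c(n_AA, n_Aa, n_aa) - expected)^2 / expected)
  pchisq(chi2, df = 1, lower.tail = FALSE)
}

hwe_pvalues <- function(geno) {
  d <- geno$dosage
  n_AA <- colSums(d == 2L, na.rm = TRUE)
  n_Aa <- colSums(d == 1L, na.rm = TRUE)
  n_aa <- colSums(d == 0L, na.rm = TRUE)
  vapply(seq_along(n_AA), function(j) {
    if (n_AA[j] + n_Aa[j] + n_aa[j] == 0) return(NA_real_)
    hwe_test(n_AA[j], n_Aa[j], n_aa[j])
  }, numeric(1))
}

#' Quality-control filtering of genotypes
#'
#' Applies the standard pre-association filters. Individuals with more than
#' `ind_missing_max` missing genotypes are removed first; marker statistics
#' (allele frequency, call rate, Hardy-Weinberg p) are then computed on the
#' retained individuals, and markers are dropped when MAF `<= maf_min`,
#' missing rate `>= snp_missing_max`, HWE p `<= hwe_p_min`, or the
#' chromosome is not an autosome (1-29). A marker failing several filters
#' is attributed to the first in that order, so the removal counts
#' partition the dropped set.
#'
#' @param geno A [geno_matrix()].
#' @param maf_min Minimum minor allele frequency (exclusive), default 0.05.
#' @param snp_missing_max Maximum per-marker missing proportion
#'   (exclusive), default 0.05.
#' @param hwe_p_min Hardy-Weinberg p-value floor (exclusive), default 1e-6.
#' @param ind_missing_max Maximum per-individual missing proportion,
#'   default 0.10.
#' @return List with `geno` (filtered [geno_matrix()]) and `report`, a
#'   `qc_report` tibble-backed summary of counts per filter.
#' @examples
#' cfg <- sim_config(n_individuals = 50, n_chromosomes = 1, snps_per_chrom = 40)
#' qc <- qc_filter(simulate_genotypes(cfg))
#' qc$report
#' @export
qc_filter <- function(geno, maf_min = 0.05, snp_missing_max = 0.05,
                      hwe_p_min = 1e-6, ind_missing_max = 0.10) {
  stopifnot(inherits(geno, "geno_matrix"))
  for (thr in c(maf_min, snp_missing_max, hwe_p_min, ind_missing_max))
    if (thr < 0 || thr > 1) stop("thresholds must lie in [0, 1]", call. = FALSE)

  n_in <- nrow(geno$dosage)
  m_in <- ncol(geno$dosage)

  ind_miss <- rowMeans(is.na(geno$dosage))
  keep_ind <- ind_miss <= ind_missing_max
  n_ind_removed <- sum(!keep_ind)
  g <- geno[keep_ind, ]
  if (nrow(g$dosage) == 0) stop("all individuals filtered", call. = FALSE)

  af <- allele_freq(g)
  snp_miss <- 1 - af$n_called / nrow(g$dosage)
  hwe_p <- hwe_pvalues(g)

  non_auto <- g$map$chrom < 1L | g$map$chrom > 29L
  fail_maf <- !non_auto & (af$all_missing | af$maf <= maf_min)
  fail_call <- !non_auto & !fail_maf & snp_miss >= snp_missing_max
  fail_hwe <- !non_auto & !fail_maf & !fail_call &
    (!is.na(hwe_p) & hwe_p <= hwe_p_min)
  keep_snp <- !(non_auto | fail_maf | fail_call | fail_hwe)
  if (!any(keep_snp)) stop("all SNPs filtered", call. = FALSE)

  report <- structure(tibble::tibble(
    n_ind_in = n_in, n_ind_out = sum(keep_ind),
    n_snps_in = m_in, n_snps_out = sum(keep_snp),
    removed_ind_missing = n_ind_removed,
    removed_by_maf = sum(fail_maf),
    removed_by_callrate = sum(fail_call),
    removed_by_hwe = sum(fail_hwe),
    removed_non_autosomal = sum(non_auto),
    maf_min = maf_min, snp_missing_max = snp_missing_max,
    hwe_p_min = hwe_p_min, ind_missing_max = ind_missing_max
  ), class = c("qc_report", class(tibble::tibble())))

  list(geno = g[, keep_snp], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> individuals ", x$n_ind_in, " -> ", x$n_ind_out,
      " | SNPs ", x$n_snps_in, " -> ", x$n_snps_out,
      " (maf ", x$removed_by_maf, ", callrate ", x$removed_by_callrate,
      ", hwe ", x$removed_by_hwe, ", non-autosomal ",
      x$removed_non_autosomal, ")\n", sep = "")
  invisible(x)
}
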