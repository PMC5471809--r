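#' Partition markers into fixed-width genomic windows
#'
#' Windows are anchored at position 1 on each chromosome and are
#' `window_bp` wide, so the marker at 1-based position `bp` falls in window
#' `floor((bp - 1) / window_bp)` (position 100,000 is still in window 0 of
#' a 100 kb grid; 100,001 starts window 1). Empty windows are omitted.
#'
#' @param geno A [geno_matrix()].
#' @param window_bp Window width in base pairs (default 100 kb).
#' @return Tibble with one row per marker: `snp_id`, `chrom`, `bp`,
#'   `window` (0-based index within chromosome), `start_bp`, `end_bp`
#'   (1-based, inclusive).
#' @examples
#' g <- geno_matrix(matrix(0L, 1, 2),
#'                  data.frame(snp_id = c("a", "b"), chrom = 1,
#'                             bp = c(100000, 100001)))
#' window_partition(g)$window  # 0 1
#' @export
window_partition <- function(geno, window_bp = 100000) {
  stopifnot(inherits(geno, "geno_matrix"), window_bp > 0)
  map <- geno$map
  win <- (map$bp - 1L) %/% as.integer(window_bp)
  tibble::tibble(snp_id = map$snp_id, chrom = map$chrom, bp = map$bp,
                 window = win,
                 start_bp = win * as.integer(window_bp) + 1L,
                 end_bp = (win + 1L) * as.integer(window_bp))
}

#' Window shares of genetic variance from a BayesB posterior
#'
#' For each retained MCMC sample, the genetic value of each window is the
#' sum of its marker contributions; the window's share is the variance
#' (over individuals) of that window genetic value divided by the variance
#' of the whole-genome genetic value. Shares are then averaged over
#' retained samples (the posterior mean proportion), and windows reaching
#' `candidate_threshold` are flagged as candidate regions. Samples whose
#' total genetic variance is zero are skipped with a warning. Note the
#' per-sample shares need not sum to 1 (window genetic values covary
#' through linkage disequilibrium); they do when windows are uncorrelated.
#'
#' @param posterior A [run_bayesb()] fit.
#' @param geno The [geno_matrix()] the fit was trained on.
#' @param assignment Optional [window_partition()] result (recomputed from
#'   `geno` when omitted).
#' @param window_bp Window width passed to [window_partition()].
#' @param candidate_threshold Posterior-mean share flagging a candidate
#'   region (default 0.01, i.e. windows explaining at least 1% of genetic
#'   variance).
#' @param denominator `"total"` (default) divides each window variance by
#'   the variance of the whole-genome genetic value; `"window_sum"`
#'   divides by the sum of window variances, making the shares sum to
#'   exactly 1 per retained sample. The two agree when windows are
#'   mutually uncorrelated.
#' @return Tibble with one row per non-empty window: `chrom`, `window`,
#'   `start_bp`, `end_bp`, `n_snp`, `var_proportion`, `candidate`.
#'   Attribute `share_sums` holds the per-retained-sample sums of shares.
#' @export
window_variance_proportions <- function(posterior, geno, assignment = NULL,
                                        window_bp = 100000,
                                        candidate_threshold = 0.01,
                                        denominator = c("total",
                                                        "window_sum")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(posterior, "bayesb_fit"), inherits(geno, "geno_matrix"))
  if (!identical(geno$map$snp_id, posterior$map$snp_id))
    stop("alignment error: marker sets differ", call. = FALSE)
  if (is.null(assignment)) assignment <- window_partition(geno, window_bp)

  Z <- ifelse(is.na(geno$dosage),
              rep(2 * posterior$freq, each = nrow(geno$dosage)), geno$dosage)
  A <- posterior$alpha_samples  # n_stored x M
  groups <- split(seq_len(nrow(assignment)),
                  paste(assignment$chrom, assignment$window, sep = ":"))
  keys <- purrr::map_dfr(groups, function(jj) {
    assignment[jj[1], c("chrom", "window", "start_bp", "end_bp")]
  })
  keys$n_snp <- lengths(groups)

  wvar <- t(vapply(groups, function(jj) {
    apply(Z[, jj, drop = FALSE] %*% t(A[, jj, drop = FALSE]), 2, var)
  }, numeric(nrow(A))))  # n_windows x n_stored
  total_var <- if (denominator == "total") {
    apply(Z %*% t(A), 2, var)
  } else {
    colSums(wvar)
  }
  ok <- total_var > 0
  if (!any(ok)) {
    warning("all retained samples carry zero genetic variance", call. = FALSE)
    out <- tibble::tibble(keys, var_proportion = 0, candidate = FALSE)
    out <- dplyr::arrange(out, .data$chrom, .data$window)
    class(out) <- c("window_result", class(out))
    return(out)
  }
  if (any(!ok))
    warning(sum(!ok), " retained sample(s) with zero genetic variance skipped",
            call. = FALSE)

  shares <- sweep(wvar[, ok, drop = FALSE], 2, total_var[ok], `/`)
  out <- tibble::tibble(keys, var_proportion = rowMeans(shares))
  out <- dplyr::arrange(out, .data$chrom, .data$window)
  out$candidate <- out$var_proportion >= candidate_threshold
  attr(out, "share_sums") <- colSums(shares)
  class(out) <- c("window_result", class(out))
  out
}

#' GRAMMAR-GC single-marker association scan
#'
#' Two-stage mixed-model association with genomic control. Stage 1 fits
#' the polygenic model `y = 1*mu + a + e`, `a ~ N(0, G sigma_a2)`, by REML
#' and forms the environmental residuals `e_hat = y - mu_hat - a_hat`
#' (BLUP of `a` subtracted). Stage 2 score-tests each marker against the
#' residuals: `chi2_j = (w_j' e_hat)^2 / (w_j' w_j * s2)` with `w_j` the
#' centred dosage and `s2` the residual variance of `e_hat`. Stage 3
#' rescales by the genomic-control inflation factor
#' `lambda = median(chi2) / 0.4549` (the chi-square(1) median), which
#' restores nominal calibration that the residual-based stage loses.
#'
#' @param y_adj An [adjust_phenotypes()] result.
#' @param geno A [geno_matrix()].
#' @param grm A [build_grm()] result (built from `geno` when omitted).
#' @param varcomp Optional [reml_univariate()] fit to reuse.
#' @return Object of class `grammar_scan`: tibble with `snp_id`, `chrom`,
#'   `bp`, `beta`, `chi2`, `p_raw`, `p_gc`; attribute `lambda`.
#' @export
grammar_gc_scan <- function(y_adj, geno, grm = NULL, varcomp = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  idx <- align_ids(y_adj$id, geno_ids(geno), "genotypes")
  if (is.null(grm)) grm <- build_grm(geno[idx, ])
  if (is.null(varcomp)) varcomp <- reml_univariate(y_adj, grm)

  ehat <- grammar_residuals(y_adj, varcomp)
  W <- center_dosage(geno)[idx, , drop = FALSE]
  n <- nrow(W)
  if (ncol(W) < 10)
    warning("fewer than 10 markers: lambda is unreliable", call. = FALSE)

  wte <- drop(crossprod(W, ehat))
  wtw <- colSums(W^2)
  s2 <- sum(ehat^2) / (n - 1)
  beta <- ifelse(wtw > 0, wte / wtw, NA_real_)
  chi2 <- ifelse(wtw > 0, wte^2 / (wtw * s2), 0)
  p_raw <- pchisq(chi2, df = 1, lower.tail = FALSE)

  lambda <- estimate_lambda(chi2, method = "median")
  chi2_gc <- chi2 / lambda
  p_gc <- pchisq(chi2_gc, df = 1, lower.tail = FALSE)

  out <- tibble::tibble(snp_id = geno$map$snp_id, chrom = geno$map$chrom,
                        bp = geno$map$bp, beta = beta, chi2 = chi2,
                        p_raw = p_raw, p_gc = p_gc)
  attr(out, "lambda") <- lambda
  # inflation remaining after correction (the quantity quoted alongside
  # "no further adjustment required"): QQ-slope of the corrected statistics
  attr(out, "lambda_gc") <- estimate_lambda(chi2_gc, method = "regression")
  class(out) <- c("grammar_scan", class(out))
  out
}

#' Genomic-control inflation factor of chi-square statistics
#'
#' `"median"`: ratio of the observed median to the chi-square(1) median
#' (0.4549). `"regression"`: slope of observed on expected order
#' statistics of the chi-square(1) distribution (QQ-plot slope through the
#' origin), which weighs the whole distribution rather than its centre.
#'
#' @param chi2 Vector of 1-df chi-square statistics.
#' @param method `"median"` or `"regression"`.
#' @return The inflation factor (1 means calibrated).
#' @export
estimate_lambda <- function(chi2, method = c("median", "regression")) {
  method <- match.arg(method)
  chi2 <- chi2[is.finite(chi2)]
  if (method == "median") {
    median(chi2) / qchisq(0.5, df = 1)
  } else {
    expected <- qchisq(stats::ppoints(length(chi2)), df = 1)
    observed <- sort(chi2)
    sum(expected * observed) / sum(expected^2)
  }
}

# environmental residuals of the polygenic model, in phenotype order
grammar_residuals <- function(y_adj, varcomp) {
  stopifnot(inherits(varcomp, "varcomp"), !inherits(varcomp, "varcomp_biv"))
  d <- varcomp$eigen$values
  U <- varcomp$eigen$vectors
  r_t <- varcomp$y_t - varcomp$x_t * varcomp$mu
  shrink <- varcomp$sigma_a2 * d /
    (varcomp$sigma_a2 * d + varcomp$sigma_e2)
  a_hat <- drop(U %*% (shrink * r_t))
  drop(U %*% r_t) - a_hat
}

#' Genome-wide and suggestive significance thresholds
#'
#' Bonferroni threshold `0.05 / n_snps` over all markers, and the
#' suggestive threshold `0.05 / n_independent` where the independent count
#' is the number of LD blocks plus interblock markers (supplied by the
#' caller).
#'
#' @param n_snps Total marker count.
#' @param n_independent Number of "independent" markers.
#' @return Tibble with `bonferroni_p` and `suggestive_p`.
#' @examples
#' significance_thresholds(595715, 163473)
#' @export
significance_thresholds <- function(n_snps, n_independent = n_snps) {
  if (n_snps <= 0 || n_independent <= 0)
    stop("counts must be positive", call. = FALSE)
  tibble::tibble(bonferroni_p = 0.05 / n_snps,
                 suggestive_p = 0.05 / n_independent)
}

# Liu moment-matched chi-square tail probability for Q = sum(lambda_i X_i),
# X_i iid chi-square(1)
liu_pvalue <- function(q, lambda) {
  lambda <- lambda[lambda > 0]
  if (length(lambda) == 0) return(1)
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2
    a <- sqrt(l)
    d <- 0
  }
  mu_q <- c1; sigma_q <- sqrt(2 * c2)
  mu_x <- l + d; sigma_x <- sqrt(2) * a
  q_std <- (q - mu_q) / sigma_q * sigma_x + mu_x
  pchisq(q_std, df = l, ncp = d, lower.tail = FALSE)
}

#' Region-based kernel score test
#'
#' SKAT-style variance-component score test of all markers in a region
#' jointly, applied to the environmental residuals of the polygenic model
#' (so relatedness is accounted for as in [grammar_gc_scan()]). The
#' statistic is `Q = sum_k w_k^2 (z_k' e_hat)^2` with centred dosages
#' `z_k` and beta(1, 25) minor-allele-frequency weights; its null
#' distribution, a weighted sum of chi-square(1) variables with weights
#' `s2 * eigenvalues(W Z'Z W)`, is evaluated by the Liu moment-matching
#' approximation. A burden variant (`type = "burden"`) collapses the
#' weighted dosages into one score before testing. Per-marker marginal
#' score-test p-values are returned alongside.
#'
#' @param y_adj An [adjust_phenotypes()] result.
#' @param geno_region A [geno_matrix()] restricted to the region's markers.
#' @param grm A [build_grm()] result for the full marker set (built from
#'   `geno_region` only as a last resort).
#' @param varcomp Optional [reml_univariate()] fit to reuse.
#' @param weights_beta Beta-density parameters for the MAF weights.
#' @param type `"kernel"` (default) or `"burden"`.
#' @return Tibble of class `region_test` with one row: `n_snp`,
#'   `statistic`, `p_value`, and a list-column `snp_p` of marginal
#'   p-values; attributes `region` (chrom:start-end) and `type`.
#' @export
region_score_test <- function(y_adj, geno_region, grm = NULL, varcomp = NULL,
                              weights_beta = c(1, 25),
                              type = c("kernel", "burden")) {
  type <- match.arg(type)
  stopifnot(inherits(geno_region, "geno_matrix"))
  idx <- align_ids(y_adj$id, geno_ids(geno_region), "genotypes")
  if (ncol(geno_region$dosage) < 1)
    stop("region has no markers", call. = FALSE)
  if (is.null(varcomp)) {
    if (is.null(grm)) grm <- build_grm(geno_region[idx, ])
    varcomp <- reml_univariate(y_adj, grm)
  }
  ehat <- grammar_residuals(y_adj, varcomp)
  n <- length(ehat)
  s2 <- sum(ehat^2) / (n - 1)

  af <- allele_freq(geno_region)
  maf <- af$maf
  Zc <- center_dosage(geno_region)[idx, , drop = FALSE]
  poly <- colSums(Zc^2) > 0
  region_label <- sprintf("%d:%d-%d", geno_region$map$chrom[1],
                          min(geno_region$map$bp), max(geno_region$map$bp))
  marg_chi2 <- unname(ifelse(poly, drop(crossprod(Zc, ehat))^2 /
                               (colSums(Zc^2) * s2), 0))
  snp_p <- ifelse(poly, pchisq(marg_chi2, 1, lower.tail = FALSE), 1)

  if (!any(poly)) {
    warning("monomorphic region: p = 1", call. = FALSE)
    out <- tibble::tibble(n_snp = ncol(Zc), statistic = 0, p_value = 1,
                          snp_p = list(snp_p))
  } else {
    w <- dbeta(maf[poly], weights_beta[1], weights_beta[2])
    Zw <- sweep(Zc[, poly, drop = FALSE], 2, w, `*`)
    if (type == "burden") {
      b <- rowSums(Zw)
      q <- sum(b * ehat)^2
      lam <- s2 * sum(b^2)
    } else {
      q <- sum(drop(crossprod(Zw, ehat))^2)
      K <- crossprod(Zw)
      lam <- s2 * eigen(K, symmetric = TRUE, only.values = TRUE)$values
    }
    out <- tibble::tibble(n_snp = ncol(Zc), statistic = q,
                          p_value = liu_pvalue(q, lam), snp_p = list(snp_p))
  }
  attr(out, "region") <- region_label
  attr(out, "type") <- type
  class(out) <- c("region_test", class(out))
  out
}

# EM estimate of two-locus haplotype frequencies from unphased dosages;
# returns r^2, or NA when EM degenerates
em_haplotype_r2 <- function(g1, g2, max_iter = 100, tol = 1e-10) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (n < 2) return(NA_real_)
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(0)
  cnt <- table(factor(g1, levels = 0:2), factor(g2, levels = 0:2))
  n_dh <- cnt["1", "1"]  # double heterozygotes: phase ambiguous
  # unambiguous haplotype counts (AB, Ab, aB, ab); A/B = allele 1 dosage
  base <- c(
    AB = 2 * cnt["2", "2"] + cnt["2", "1"] + cnt["1", "2"],
    Ab = 2 * cnt["2", "0"] + cnt["2", "1"] + cnt["1", "0"],
    aB = 2 * cnt["0", "2"] + cnt["0", "1"] + cnt["1", "2"],
    ab = 2 * cnt["0", "0"] + cnt["0", "1"] + cnt["1", "0"])
  f <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  for (i in seq_len(max_iter)) {
    denom <- f[1] * f[4] + f[2] * f[3]
    wcis <- if (denom > 0) f[1] * f[4] / denom else 0.5
    counts <- base + n_dh * c(wcis, 1 - wcis, 1 - wcis, wcis)
    f_new <- counts / (2 * n)
    if (max(abs(f_new - f)) < tol) { f <- f_new; break }
    f <- f_new
  }
  D <- f[1] - (f[1] + f[2]) * (f[1] + f[3])
  denom <- (f[1] + f[2]) * (f[3] + f[4]) * (f[1] + f[3]) * (f[2] + f[4])
  if (denom <= 0) return(NA_real_)
  unname(D^2 / denom)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared allelic correlation between marker pairs, with two-locus
#' haplotype frequencies estimated by expectation-maximization over
#' unphased genotypes (double heterozygotes are the only ambiguous class).
#' Falls back to the squared composite (genotypic) correlation if the EM
#' estimate degenerates. Pairs involving a monomorphic marker get r2 = 0.
#'
#' @param geno_region A [geno_matrix()] with at least 2 markers.
#' @return Symmetric matrix of r-squared values, unit diagonal, dimnames
#'   from the marker IDs.
#' @export
pairwise_r2 <- function(geno_region) {
  stopifnot(inherits(geno_region, "geno_matrix"))
  m <- ncol(geno_region$dosage)
  if (m < 2) stop("need at least 2 markers", call. = FALSE)
  d <- geno_region$dosage
  R <- diag(1, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      r2 <- em_haplotype_r2(d[, i], d[, j])
      if (is.na(r2)) {
        cc <- suppressWarnings(cor(d[, i], d[, j],
                                   use = "pairwise.complete.obs"))
        r2 <- if (is.na(cc)) 0 else cc^2
      }
      R[i, j] <- R[j, i] <- min(max(r2, 0), 1)
    }
  }
  dimnames(R) <- list(geno_region$map$snp_id, geno_region$map$snp_id)
  R
}
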