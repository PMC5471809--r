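test_that("window partition follows the 1-based 100 kb convention", {
  g <- tiny_geno(matrix(0L, 1, 5), chrom = c(1L, 1L, 2L, 2L, 2L),
                 bp = c(100000L, 100001L, 50000L, 150000L, 250000L))
  w <- window_partition(g)
  expect_equal(w$window, c(0L, 1L, 0L, 1L, 2L))
  expect_equal(w$start_bp[2], 100001L)
  expect_equal(w$end_bp[2], 200000L)
  # all markers within 99 kb share one window
  g2 <- tiny_geno(matrix(0L, 1, 4), bp = c(1L, 30000L, 60000L, 99000L))
  expect_equal(unique(window_partition(g2)$window), 0L)
})

test_that("a single planted QTL dominates its window's variance share", {
  s <- sim_case(n = 500, chrom = 2, m_per = 250, n_qtl = 1, h2 = 0.5,
                rho = 0, seed = 9)
  fit <- run_bayesb(s$adj, s$geno,
                    bayesb_config(pi = 0.998, n_iter = 2000, burn_in = 500,
                                  seed = 2))
  # sweeps where the sparse prior keeps every marker out carry no genetic
  # variance and are skipped with a warning
  wr <- suppressWarnings(window_variance_proportions(fit, s$geno))
  qtl <- s$truth$qtl_indices
  qtl_chr <- s$geno$map$chrom[qtl]
  qtl_bp <- s$geno$map$bp[qtl]
  hit <- wr$chrom == qtl_chr & wr$start_bp <= qtl_bp & wr$end_bp >= qtl_bp
  expect_gt(wr$var_proportion[hit], 0.9)
  expect_lt(max(wr$var_proportion[!hit]), 0.1)
  expect_true(wr$candidate[hit])
})

test_that("window shares conserve the genetic variance", {
  s <- sim_case(n = 300, chrom = 2, m_per = 150, n_qtl = 10, h2 = 0.5,
                rho = 0, seed = 19)
  fit <- run_bayesb(s$adj, s$geno,
                    bayesb_config(pi = 0.99, n_iter = 1500, burn_in = 500,
                                  seed = 4))
  # window_sum denominator: shares sum to exactly 1 per retained sample
  wr_ws <- window_variance_proportions(fit, s$geno,
                                       denominator = "window_sum")
  expect_true(all(abs(attr(wr_ws, "share_sums") - 1) < 1e-6))
  # whole-genome denominator: near 1 without cross-window LD
  wr_tot <- window_variance_proportions(fit, s$geno)
  expect_lt(max(abs(attr(wr_tot, "share_sums") - 1)), 0.25)
  expect_lt(abs(mean(attr(wr_tot, "share_sums")) - 1), 0.1)
})

test_that("two equal independent QTL split the variance share evenly", {
  cfg <- sim_config(n_individuals = 800, n_chromosomes = 2,
                    snps_per_chrom = 200, ld_decay_rho = 0,
                    maf_range = c(0.4, 0.5), seed = 23)
  g <- simulate_genotypes(cfg)
  W <- center_dosage(g)
  j1 <- 50; j2 <- 250  # different chromosomes
  bv <- W[, j1] / sd(W[, j1]) + W[, j2] / sd(W[, j2])
  y <- bv + rnorm(800, sd = sd(bv))
  fit <- run_bayesb(adj_tbl(geno_ids(g), y), g,
                    bayesb_config(pi = 0.99, n_iter = 2000, burn_in = 500,
                                  seed = 3))
  wr <- window_variance_proportions(fit, g)
  top2 <- dplyr::arrange(wr, dplyr::desc(var_proportion))[1:2, ]
  expect_lt(max(abs(top2$var_proportion - 0.5)), 0.1)
  expect_equal(sort(top2$chrom), c(1L, 2L))
})

test_that("with identity kinship the scan reduces to simple regression", {
  set.seed(5)
  n <- 400
  g <- tiny_geno(matrix(rbinom(n * 50, 2, 0.3), n, 50),
                 bp = seq(1000L, by = 5000L, length.out = 50L))
  y <- rnorm(n)
  grm_i <- structure(list(G = diag(1, n) |>
                            `dimnames<-`(list(geno_ids(g), geno_ids(g))),
                          ids = geno_ids(g), denom = 1),
                     class = "grm_matrix")
  sc <- grammar_gc_scan(adj_tbl(geno_ids(g), y), g, grm_i)
  # independent oracle: score test of y itself, marker by marker
  W <- center_dosage(g)
  yc <- y - mean(y)
  s2 <- sum(yc^2) / (n - 1)
  chi2_oracle <- drop(crossprod(W, yc))^2 / (colSums(W^2) * s2)
  p_oracle <- pchisq(chi2_oracle, 1, lower.tail = FALSE)
  expect_equal(sc$p_raw, p_oracle, tolerance = 1e-6)
})

test_that("genomic control preserves ranks and the documented monotonicity", {
  s <- sim_case(n = 300, chrom = 1, m_per = 200, n_qtl = 20, h2 = 0.4,
                seed = 33)
  sc <- grammar_gc_scan(s$adj, s$geno)
  expect_true(all(sc$p_raw > 0 & sc$p_raw <= 1))
  expect_equal(order(sc$p_gc), order(sc$p_raw))
  lambda <- attr(sc, "lambda")
  if (lambda > 1) expect_true(all(sc$p_gc >= sc$p_raw - 1e-12))
  if (lambda < 1) expect_true(all(sc$p_gc <= sc$p_raw + 1e-12))
})

test_that("significance thresholds reproduce the published arithmetic", {
  th <- significance_thresholds(595715, 163473)
  expect_equal(signif(th$bonferroni_p, 3), 8.39e-08)
  expect_equal(signif(th$suggestive_p, 3), 3.06e-07)
  expect_equal(significance_thresholds(1)$bonferroni_p, 0.05)
  expect_error(significance_thresholds(0), "positive")
})

test_that("the region test detects a planted QTL region", {
  s <- sim_case(n = 1000, chrom = 2, m_per = 250, n_qtl = 1, h2 = 0.3,
                rho = 0.5, seed = 55)
  grm <- build_grm(s$geno)
  vc <- reml_univariate(s$adj, grm)
  qtl <- s$truth$qtl_indices
  win <- window_partition(s$geno)
  in_region <- win$chrom == win$chrom[qtl] & win$window == win$window[qtl]
  # flat weights: the panel is common-variant (post-QC MAF > 0.05), where
  # the rare-variant beta(1,25) weighting suppresses the causal signal
  res <- region_score_test(s$adj, s$geno[, in_region], grm, vc,
                           weights_beta = c(1, 1))
  expect_lt(res$p_value, 1e-4)
  # the beta(1,25) weighting changes the statistic but stays a valid test
  res_w <- region_score_test(s$adj, s$geno[, in_region], grm, vc)
  expect_true(res_w$p_value > 0 && res_w$p_value <= 1)
  expect_false(isTRUE(all.equal(res_w$statistic, res$statistic)))
  # a one-marker region agrees with its marginal score test
  res1 <- region_score_test(s$adj, s$geno[, qtl], grm, vc)
  expect_equal(res1$p_value, unname(res1$snp_p[[1]]), tolerance = 0.1)
})

test_that("region test p-values are uniform under the null", {
  cfg <- sim_config(n_individuals = 200, n_chromosomes = 2,
                    snps_per_chrom = 100, seed = 1)
  g <- simulate_genotypes(cfg)
  grm <- build_grm(g)
  region <- g[, 150:170]
  ps <- vapply(1:40, function(s) {
    set.seed(900 + s)
    y <- rnorm(200)
    vc <- reml_univariate(adj_tbl(geno_ids(g), y), grm)
    region_score_test(adj_tbl(geno_ids(g), y), region, grm, vc)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  # monomorphic region: p = 1 with a warning (identity-kinship stand-in
  # variance components, since no polymorphic marker can build a GRM)
  set.seed(99)
  y0 <- rnorm(50)
  mono <- tiny_geno(matrix(2L, 50, 2))
  vc0 <- structure(list(eigen = list(values = rep(0, 50),
                                     vectors = diag(50)),
                        y_t = y0, x_t = rep(1, 50), mu = mean(y0),
                        sigma_a2 = 0, sigma_e2 = 1),
                   class = "varcomp")
  expect_warning(
    res <- region_score_test(adj_tbl(geno_ids(mono), y0), mono,
                             varcomp = vc0),
    "monomorphic")
  expect_equal(res$p_value, 1)
})

test_that("LD r-squared matches haplotype-frequency identities", {
  set.seed(2)
  # duplicated marker: perfect LD
  x <- rbinom(500, 2, 0.5)
  g_dup <- tiny_geno(cbind(x, x))
  expect_equal(pairwise_r2(g_dup)[1, 2], 1, tolerance = 1e-6)
  # independent markers at n = 2000: mean off-diagonal near the 1/n null
  cfg <- sim_config(n_individuals = 2000, n_chromosomes = 1,
                    snps_per_chrom = 12, ld_decay_rho = 0, seed = 3)
  g_ind <- simulate_genotypes(cfg)
  R <- pairwise_r2(g_ind)
  expect_lt(mean(R[upper.tri(R)]), 0.01)
  expect_true(isSymmetric(R))
  expect_true(all(R >= 0 & R <= 1))
  # monomorphic marker: r2 defined as 0
  g_mono <- tiny_geno(cbind(rbinom(100, 2, 0.4), rep(2L, 100)))
  expect_equal(pairwise_r2(g_mono)[1, 2], 0)
})
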