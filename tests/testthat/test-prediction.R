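test_that("fold assignment is balanced, exhaustive and deterministic", {
  f1 <- make_folds(letters[1:10], k = 5, seed = 2)
  expect_equal(unname(table(f1$fold)), rep(2L, 5), ignore_attr = TRUE)
  f2 <- make_folds(letters[1:11], k = 5, seed = 2)
  expect_equal(sort(unname(table(f2$fold))), c(2L, 2L, 2L, 2L, 3L),
               ignore_attr = TRUE)
  expect_setequal(f2$id, letters[1:11])
  expect_identical(f2, make_folds(letters[1:11], k = 5, seed = 2))
  expect_false(identical(f2$fold, make_folds(letters[1:11], 5, 3)$fold))
  expect_error(make_folds(letters[1:3], k = 5), "exceeds")
})

test_that("GBLUP interpolates the training data as residual variance vanishes", {
  s <- sim_case(n = 80, chrom = 1, m_per = 120, n_qtl = 10, h2 = 0.5,
                seed = 18)
  grm <- build_grm(s$geno)
  pred <- gblup_predict(s$adj, grm, list(sigma_a2 = 1, sigma_e2 = 1e-10))
  expect_equal(pred$gebv, unname(s$adj$y_adj) - attr(pred, "mu"),
               tolerance = 1e-4)
})

test_that("GBLUP equals SNP-BLUP ridge regression on the same markers", {
  s <- sim_case(n = 200, chrom = 2, m_per = 250, n_qtl = 25, h2 = 0.4,
                seed = 28)
  grm <- build_grm(s$geno)
  vc <- reml_univariate(s$adj, grm)
  pred <- gblup_predict(s$adj, grm, vc)
  # independent route: ridge on centred dosages, lambda = ve / (va / denom)
  W <- center_dosage(s$geno)
  y <- s$adj$y_adj
  V <- vc$sigma_a2 * grm$G + diag(vc$sigma_e2, nrow(W))
  mu <- sum(solve(V, y)) / sum(solve(V, rep(1, length(y))))
  lam <- vc$sigma_e2 / (vc$sigma_a2 / grm$denom)
  alpha <- solve(crossprod(W) + diag(lam, ncol(W)), crossprod(W, y - mu))
  expect_equal(pred$gebv, unname(drop(W %*% alpha)), tolerance = 1e-6)
})

test_that("accuracy and bias follow their defining identities", {
  x <- rnorm(50)
  out <- accuracy_and_bias(x, x, h2 = 1)
  expect_equal(out$r, 1)
  expect_equal(out$b, 1)
  expect_equal(out$b_reverse, 1)
  # independent noise: near-zero accuracy
  set.seed(4)
  out0 <- accuracy_and_bias(rnorm(2000), rnorm(2000), h2 = 0.5)
  expect_lt(abs(out0$r), 0.1)
  expect_warning(out_flat <- accuracy_and_bias(rep(1, 10), rnorm(10), 0.5),
                 "zero-variance")
  expect_true(is.na(out_flat$r))
  expect_error(accuracy_and_bias(1:5, 1:5, h2 = 0), "positive")
})

test_that("true breeding values correlate with phenotype at the square root of h2", {
  # identity: cor(bv, bv + e) = sqrt(h2); report the raw correlation
  # (h2 = 1 denominator) since the scaled accuracy is ~1 by construction
  rs <- vapply(1:8, function(s) {
    cc <- sim_case(n = 200, chrom = 1, m_per = 200, n_qtl = 40, h2 = 0.5,
                   seed = 80 + s)
    accuracy_and_bias(cc$truth$true_bv, cc$adj$y_adj, h2 = 1)$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - sqrt(0.5)), 0.05)
})

test_that("cross-validation is deterministic and leak-free", {
  s <- sim_case(n = 150, chrom = 1, m_per = 150, n_qtl = 15, h2 = 0.5,
                seed = 36)
  grm <- build_grm(s$geno)
  cv1 <- crossvalidate(s$adj, s$geno, grm, "gblup", seed = 5)
  cv2 <- crossvalidate(s$adj, s$geno, grm, "gblup", seed = 5)
  expect_identical(cv1$r, cv2$r)
  # shuffling test phenotypes changes accuracy but not the predictions:
  # fold 1 GEBV from the training records only
  folds <- make_folds(s$adj$id, 5, 5)
  test_ids <- folds$id[folds$fold == 1]
  train <- s$adj[!(s$adj$id %in% test_ids), ]
  vc <- reml_univariate(train,
                        build_grm(s$geno[match(train$id, geno_ids(s$geno)), ]))
  p1 <- gblup_predict(train, grm, vc)
  shuffled <- s$adj
  shuffled$y_adj[match(test_ids, shuffled$id)] <-
    sample(shuffled$y_adj[match(test_ids, shuffled$id)])
  train2 <- shuffled[!(shuffled$id %in% test_ids), ]
  p2 <- gblup_predict(train2, grm, vc)
  expect_equal(p1$gebv, p2$gebv)
})

test_that("a heritability-zero trait predicts at chance level", {
  s <- sim_case(n = 300, chrom = 1, m_per = 200, n_qtl = 0, h2 = 0, seed = 47)
  grm <- build_grm(s$geno)
  cv <- crossvalidate(s$adj, s$geno, grm, "gblup", seed = 2, h2 = 0.25)
  expect_lt(abs(glance(cv)$mean_r), 0.15)
})

test_that("accuracy increases with heritability", {
  mean_r <- vapply(c(0.1, 0.3, 0.5), function(h2) {
    rs <- vapply(1:2, function(s) {
      cc <- sim_case(n = 400, chrom = 2, m_per = 200, n_qtl = 100, h2 = h2,
                     seed = 90 + s)
      glance(crossvalidate(cc$adj, cc$geno, build_grm(cc$geno), "gblup",
                           seed = s, h2 = h2))$mean_r
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
})

test_that("BayesB prediction is a linear marker score", {
  s <- sim_case(n = 100, chrom = 1, m_per = 60, n_qtl = 5, seed = 58)
  fit <- run_bayesb(s$adj, s$geno,
                    bayesb_config(pi = 0.9, n_iter = 400, burn_in = 100,
                                  seed = 1))
  pred <- bayesb_predict(fit, s$geno)
  fit2 <- fit
  fit2$alpha_hat <- 2 * fit$alpha_hat
  expect_equal(bayesb_predict(fit2, s$geno)$gebv, 2 * pred$gebv)
  fit0 <- fit
  fit0$alpha_hat <- rep(0, length(fit$alpha_hat))
  expect_true(all(bayesb_predict(fit0, s$geno)$gebv == 0))
})
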