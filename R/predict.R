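#' Random k-fold partition of individuals
#'
#' @param ids Individual identifiers.
#' @param k Number of folds (default 5).
#' @param seed Integer seed; the assignment is deterministic given the
#'   seed.
#' @return Tibble with `id` and `fold` (1..k); fold sizes differ by at
#'   most 1 and every individual appears in exactly one fold.
#' @examples
#' table(make_folds(letters[1:11], k = 5, seed = 1)$fold)
#' @export
make_folds <- function(ids, k = 5, seed = 1L) {
  n <- length(ids)
  if (k > n) stop("k exceeds number of individuals", call. = FALSE)
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  tibble::tibble(id = ids, fold = fold)
}

#' GBLUP breeding values for all individuals from training phenotypes
#'
#' Solves the animal model `y = 1*mu + a + e` with `V(a) = G sigma_a2`,
#' `V(e) = I sigma_e2` on the training records and propagates the BLUP of
#' `a` to every individual in the relationship matrix through
#' `a_hat = sigma_a2 * G[, train] V_train^{-1} (y_train - mu_hat)`;
#' individuals without records get predictions purely through their
#' genomic relationships. Equivalent to ridge regression on centred
#' markers (SNP-BLUP) when `G` is the VanRaden matrix.
#'
#' @param y_adj_train An [adjust_phenotypes()] result for the training
#'   individuals (must all be in `grm`).
#' @param grm A [build_grm()] result over training and test individuals.
#' @param varcomp A [reml_univariate()] fit (or any list with `sigma_a2`,
#'   `sigma_e2`).
#' @return Tibble with `id` (all GRM individuals) and `gebv`; attribute
#'   `mu` is the GLS mean.
#' @export
gblup_predict <- function(y_adj_train, grm, varcomp) {
  stopifnot(inherits(grm, "grm_matrix"))
  idx <- align_ids(y_adj_train$id, grm$ids, "GRM")
  y <- y_adj_train$y_adj
  va <- varcomp$sigma_a2
  ve <- varcomp$sigma_e2
  n_t <- length(y)

  V <- va * grm$G[idx, idx, drop = FALSE] + diag(ve, n_t)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    warning("singular training system: adding ridge", call. = FALSE)
    ch <- chol(V + diag(1e-6 * mean(diag(V)), n_t))
  }
  Vinv_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vinv_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n_t)))
  mu <- sum(Vinv_y) / sum(Vinv_1)
  r <- y - mu
  Vinv_r <- backsolve(ch, forwardsolve(t(ch), r))
  a_hat <- unname(va * drop(grm$G[, idx, drop = FALSE] %*% Vinv_r))

  out <- tibble::tibble(id = grm$ids, gebv = a_hat)
  attr(out, "mu") <- mu
  out
}

#' Score test-set genotypes with a trained BayesB posterior
#'
#' `GEBV_i = sum_j Z_ij alpha_hat_j` on the held-out genotypes; the
#' posterior must have been trained without the test phenotypes.
#'
#' @param posterior A [run_bayesb()] fit trained on the training fold.
#' @param geno_test A [geno_matrix()] for the test individuals with the
#'   training marker set.
#' @return Tibble with `id` and `gebv`.
#' @export
bayesb_predict <- function(posterior, geno_test) {
  posterior_genetic_values(posterior, geno_test)
}

#' Predictive accuracy and dispersion bias
#'
#' Accuracy is the correlation between genomic estimated breeding values
#' and adjusted phenotypes divided by the square root of heritability,
#' `r = cor(GEBV, y_adj) / sqrt(h2)`. The headline bias coefficient `b`
#' is the slope of the regression of GEBV on adjusted phenotype; the
#' conventional reverse slope (adjusted phenotype on GEBV, unity meaning
#' no dispersion bias) is reported as `b_reverse`.
#'
#' @param gebv_test,y_adj_test Numeric vectors over the same test
#'   individuals (at least 3).
#' @param h2 Heritability used in the denominator (> 0).
#' @return Tibble with `r`, `b`, `b_reverse`.
#' @examples
#' accuracy_and_bias(1:5, 1:5, h2 = 1)  # r = 1, b = 1
#' @export
accuracy_and_bias <- function(gebv_test, y_adj_test, h2) {
  if (h2 <= 0) stop("h2 must be positive", call. = FALSE)
  if (length(gebv_test) < 3 || length(gebv_test) != length(y_adj_test))
    stop("need at least 3 aligned test individuals", call. = FALSE)
  if (var(gebv_test) == 0) {
    warning("zero-variance GEBV: accuracy undefined", call. = FALSE)
    return(tibble::tibble(r = NA_real_, b = NA_real_, b_reverse = NA_real_))
  }
  r <- cor(gebv_test, y_adj_test) / sqrt(h2)
  b <- cov(gebv_test, y_adj_test) / var(y_adj_test)
  b_rev <- cov(gebv_test, y_adj_test) / var(gebv_test)
  tibble::tibble(r = r, b = b, b_reverse = b_rev)
}

#' Cross-validated genomic prediction
#'
#' k-fold cross-validation of GBLUP or BayesB. Per fold, variance
#' components are re-estimated by REML on the training individuals only
#' (no leakage), the model is fitted on the training records, the held-out
#' individuals are scored, and accuracy/bias are computed against their
#' adjusted phenotypes. The heritability in the accuracy denominator is
#' the whole-data REML estimate, fixed across folds, matching the
#' convention of reporting one heritability per trait.
#'
#' @param y_adj An [adjust_phenotypes()] result for all individuals.
#' @param geno A [geno_matrix()] covering the phenotyped IDs.
#' @param grm Optional [build_grm()] result (built from `geno` when
#'   omitted).
#' @param method `"gblup"` or `"bayesb"`.
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold assignment and the per-fold chains.
#' @param h2 Heritability for the accuracy denominator; estimated on the
#'   whole data when omitted.
#' @param config A [bayesb_config()] for `method = "bayesb"` (per-fold
#'   chain seeds are derived from `seed`).
#' @return Object of class `cv_result`: tibble with one row per fold
#'   (`fold`, `n_test`, `r`, `b`, `b_reverse`); attributes `method`,
#'   `h2`, `seed`. Summarise with [glance.cv_result()].
#' @export
crossvalidate <- function(y_adj, geno, grm = NULL,
                          method = c("gblup", "bayesb"), k = 5, seed = 1L,
                          h2 = NULL, config = bayesb_config()) {
  method <- match.arg(method)
  stopifnot(inherits(geno, "geno_matrix"))
  idx <- align_ids(y_adj$id, geno_ids(geno), "genotypes")
  geno <- geno[idx, ]
  if (is.null(grm)) grm <- build_grm(geno)

  if (is.null(h2)) {
    h2 <- reml_univariate(y_adj, grm)$h2
    if (h2 <= 0) h2 <- 1e-4
  }

  folds <- make_folds(y_adj$id, k = k, seed = seed)
  rows <- purrr::map_dfr(seq_len(k), function(f) {
    test_ids <- folds$id[folds$fold == f]
    train <- y_adj[!(y_adj$id %in% test_ids), ]
    attr(train, "trait") <- attr(y_adj, "trait")
    test <- y_adj[y_adj$id %in% test_ids, ]

    train_idx <- match(train$id, geno_ids(geno))
    vc <- reml_univariate(train, build_grm(geno[train_idx, ]))

    if (method == "gblup") {
      pred <- gblup_predict(train, grm, vc)
    } else {
      cfg <- config
      cfg$seed <- as.integer((seed * 131L + f * 7919L) %% .Machine$integer.max)
      cfg <- derive_scale_params(vc$sigma_a2, vc$sigma_e2,
                                 geno = geno[train_idx, ], config = cfg)
      fit <- run_bayesb(train, geno[train_idx, ], cfg)
      pred <- bayesb_predict(fit, geno[match(test$id, geno_ids(geno)), ])
    }
    gebv_test <- pred$gebv[match(test$id, pred$id)]
    ab <- accuracy_and_bias(gebv_test, test$y_adj, h2)
    tibble::tibble(fold = f, n_test = length(test_ids), ab)
  })
  attr(rows, "method") <- method
  attr(rows, "h2") <- h2
  attr(rows, "seed") <- seed
  class(rows) <- c("cv_result", class(rows))
  rows
}

#' Summarise a cross-validation result
#'
#' @param x A [crossvalidate()] result.
#' @param ... Unused.
#' @return One-row tibble with the fold means and standard errors of
#'   accuracy and bias (`mean_r`, `se_r`, `mean_b`, `se_b`,
#'   `mean_b_reverse`), plus `method` and `h2`.
#' @export
glance.cv_result <- function(x, ...) {
  se <- function(v) sd(v) / sqrt(sum(!is.na(v)))
  tibble::tibble(method = attr(x, "method"),
                 mean_r = mean(x$r, na.rm = TRUE), se_r = se(x$r),
                 mean_b = mean(x$b, na.rm = TRUE), se_b = se(x$b),
                 mean_b_reverse = mean(x$b_reverse, na.rm = TRUE),
                 h2 = attr(x, "h2"), k = nrow(x))
}

#' @export
print.cv_result <- function(x, ...) {
  g <- glance.cv_result(x)
  cat("<cv_result> ", g$method, ", ", g$k, " folds: r = ",
      round(g$mean_r, 3), " +/- ", round(g$se_r, 3), ", b = ",
      round(g$mean_b, 3), " +/- ", round(g$se_b, 3), "\n", sep = "")
  invisible(x)
}
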