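#' BayesB sampler configuration
#'
#' Priors and chain schedule for [run_bayesb()]. The defaults follow the
#' whole-genome-regression convention for high-density panels: prior
#' exclusion probability `pi = 0.9998` (so the expected number of fitted
#' markers per sweep is `(1 - pi) * M`), scaled inverse chi-square priors
#' with `nu_alpha = 4` for locus variances and `nu_e = 10` for the
#' residual, and scales derived from external variance-component estimates
#' via [derive_scale_params()]. The default chain is a desk-scale
#' 5,000-sweep run with 1,000 burn-in; the full-length schedule used for
#' production association scans is `n_iter = 50000`, `burn_in = 10000`.
#'
#' @param pi Prior probability a marker has zero effect, in `[0, 1]`.
#' @param nu_alpha,nu_e Prior degrees of freedom (locus / residual).
#' @param s2_alpha,s2_e Prior scales; usually set by
#'   [derive_scale_params()].
#' @param n_iter,burn_in Chain length and discarded sweeps.
#' @param sample_every Keep every `sample_every`-th post-burn-in effect
#'   vector for window-variance computation (posterior means always use
#'   every retained sweep).
#' @param fixed_effect_var If positive, every locus variance is frozen at
#'   this value (with `pi = 0` this is the conjugate ridge limit used as a
#'   correctness oracle).
#' @param fixed_sigma_e2 If positive, the residual variance is frozen.
#' @param seed Integer seed for the chain.
#' @return Object of class `bayesb_config`.
#' @export
bayesb_config <- function(pi = 0.9998, nu_alpha = 4, nu_e = 10,
                          s2_alpha = NA_real_, s2_e = NA_real_,
                          n_iter = 5000, burn_in = 1000, sample_every = 10,
                          fixed_effect_var = 0, fixed_sigma_e2 = 0,
                          seed = 1L) {
  if (pi < 0 || pi > 1) stop("pi must be in [0, 1]", call. = FALSE)
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in", call. = FALSE)
  if (nu_alpha <= 2 || nu_e <= 2)
    stop("prior degrees of freedom must exceed 2 for a finite prior mean",
         call. = FALSE)
  structure(list(pi = pi, nu_alpha = nu_alpha, nu_e = nu_e,
                 s2_alpha = s2_alpha, s2_e = s2_e,
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 sample_every = as.integer(sample_every),
                 fixed_effect_var = fixed_effect_var,
                 fixed_sigma_e2 = fixed_sigma_e2,
                 seed = as.integer(seed)),
            class = "bayesb_config")
}

#' Derive BayesB prior scales from variance-component estimates
#'
#' Sets the scaled inverse chi-square scales so the prior means match
#' externally estimated variances:
#' `s2_alpha = sigma_a2 * (nu_alpha - 2) / nu_alpha /
#' ((1 - pi) * 2 * sum p_j (1 - p_j))` — the per-marker effect variance
#' that reproduces the additive variance when `(1 - pi)` of markers
#' segregate — and `s2_e = sigma_e2 * (nu_e - 2) / nu_e`.
#'
#' @param sigma_a2_hat,sigma_e2_hat Additive and residual variance
#'   estimates (e.g. from [reml_univariate()]).
#' @param geno The [geno_matrix()] the sampler will run on (supplies
#'   `2 * sum p(1-p)`); alternatively pass `denom` directly.
#' @param config A [bayesb_config()].
#' @param denom Optional override for `2 * sum p_j (1 - p_j)`.
#' @return The config with `s2_alpha`, `s2_e` filled in.
#' @examples
#' cfg <- bayesb_config(pi = 0.5, nu_alpha = 4)
#' cfg <- derive_scale_params(1, 1, config = cfg, denom = 10)
#' cfg$s2_alpha  # 0.1
#' @export
derive_scale_params <- function(sigma_a2_hat, sigma_e2_hat, geno = NULL,
                                config = bayesb_config(), denom = NULL) {
  stopifnot(inherits(config, "bayesb_config"))
  if (config$pi >= 1)
    stop("zero expected QTL: pi = 1 leaves no markers in the model",
         call. = FALSE)
  if (is.null(denom)) {
    stopifnot(inherits(geno, "geno_matrix"))
    af <- allele_freq(geno)
    p <- af$p[!af$all_missing]
    denom <- 2 * sum(p * (1 - p))
  }
  config$s2_alpha <- sigma_a2_hat * (config$nu_alpha - 2) / config$nu_alpha /
    ((1 - config$pi) * denom)
  config$s2_e <- sigma_e2_hat * (config$nu_e - 2) / config$nu_e
  config
}

#' Run the BayesB MCMC sampler
#'
#' Fits the marker-effect model
#' `y_i = u + sum_j Z_ij alpha_j delta_j + e_i` where each marker effect
#' `alpha_j ~ N(0, sigma_j^2)` carries its own variance, `delta_j` is a
#' 0/1 inclusion indicator with prior `P(delta_j = 0) = pi`, and the locus
#' variances and residual variance have scaled inverse chi-square priors.
#' Each sweep updates the mean by Gibbs; each locus by a joint
#' Metropolis-Hastings move on `(delta_j, sigma_j^2)` with the effect
#' integrated out analytically (proposal drawn from the prior), followed by
#' a Gibbs draw of the effect when included; and the residual variance from
#' its full conditional. Genotypes are centred by twice the allele
#' frequency, consistent with the relationship matrix, and the centring
#' constant is absorbed by the mean.
#'
#' @param y_adj An [adjust_phenotypes()] result.
#' @param geno A [geno_matrix()] covering the phenotyped IDs.
#' @param config A [bayesb_config()]; if `s2_alpha`/`s2_e` are `NA` they
#'   are derived internally from a REML fit on a [build_grm()] of `geno`.
#' @return Object of class `bayesb_fit`: per-marker posterior means
#'   `alpha_hat`, inclusion frequencies `delta_freq`, thinned effect-vector
#'   samples `alpha_samples`, per-individual genetic-value samples
#'   `gv_samples`, traces (`sigma_e2_chain`, `loglik_chain`,
#'   `n_fitted_chain`), MH `accept_rate`, the marker map, and the training
#'   allele frequencies used for centring.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_individuals = 150, n_chromosomes = 1,
#'                   snps_per_chrom = 100, n_qtl = 3, target_h2 = 0.5)
#' g <- simulate_genotypes(cfg)
#' sim <- simulate_phenotypes(g, cfg)
#' fit <- run_bayesb(adjust_phenotypes(sim$traits, "y"), g,
#'                   bayesb_config(pi = 0.95, n_iter = 1000, burn_in = 200))
#' head(tidy(fit))
#' }
#' @export
run_bayesb <- function(y_adj, geno, config = bayesb_config()) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(config, "bayesb_config"))
  idx <- align_ids(y_adj$id, geno_ids(geno), "genotypes")
  y <- y_adj$y_adj
  if (var(y) == 0) stop("zero-variance trait", call. = FALSE)

  W_all <- center_dosage(geno)
  p <- attr(W_all, "p")
  W <- W_all[idx, , drop = FALSE]

  cfg <- config
  if (is.na(cfg$s2_alpha) || is.na(cfg$s2_e)) {
    vc <- reml_univariate(y_adj, build_grm(geno[idx, ]))
    cfg <- derive_scale_params(vc$sigma_a2, vc$sigma_e2, config = cfg,
                               denom = 2 * sum(p * (1 - p), na.rm = TRUE))
  }

  set.seed(cfg$seed)
  res <- .bayesb_mcmc(W, y, cfg$pi, cfg$nu_alpha, cfg$s2_alpha, cfg$nu_e,
                      cfg$s2_e, cfg$n_iter, cfg$burn_in, cfg$sample_every,
                      cfg$fixed_effect_var, cfg$fixed_sigma_e2)
  alpha_samples <- res$alpha_samples
  # genetic values on the raw dosage scale (GEBV_i = sum_j Z_ij alpha_j);
  # the centring constant only shifts the mean, never variances
  Z_imp <- ifelse(is.na(geno$dosage), rep(2 * p, each = nrow(geno$dosage)),
                  geno$dosage)[idx, , drop = FALSE]
  gv_samples <- tcrossprod(Z_imp, alpha_samples)  # n x n_stored

  structure(list(
    alpha_hat = drop(res$alpha_hat),
    delta_freq = drop(res$delta_freq),
    mu_hat = res$mu_hat,
    alpha_samples = alpha_samples,
    gv_samples = gv_samples,
    sigma_e2_chain = drop(res$sigma_e2_chain),
    loglik_chain = drop(res$loglik_chain),
    n_fitted_chain = drop(res$n_fitted_chain),
    accept_rate = res$accept_rate,
    map = geno$map,
    freq = p,
    ids = y_adj$id,
    config = cfg
  ), class = "bayesb_fit")
}

#' @export
print.bayesb_fit <- function(x, ...) {
  cat("<bayesb_fit> ", length(x$alpha_hat), " markers, ", length(x$ids),
      " individuals; pi = ", x$config$pi, ", chain ", x$config$n_iter, "/",
      x$config$burn_in, " (mean fitted markers/sweep ",
      round(mean(x$n_fitted_chain), 1), ")\n", sep = "")
  invisible(x)
}

#' Tidy a BayesB fit
#'
#' @param x A `bayesb_fit`.
#' @param ... Unused.
#' @return Tibble with one row per marker: `snp_id`, `chrom`, `bp`,
#'   `alpha_hat`, `delta_freq`.
#' @export
tidy.bayesb_fit <- function(x, ...) {
  tibble::tibble(snp_id = x$map$snp_id, chrom = x$map$chrom, bp = x$map$bp,
                 alpha_hat = x$alpha_hat, delta_freq = x$delta_freq)
}

#' @export
glance.bayesb_fit <- function(x, ...) {
  tibble::tibble(n = length(x$ids), n_snp = length(x$alpha_hat),
                 pi = x$config$pi, n_iter = x$config$n_iter,
                 burn_in = x$config$burn_in,
                 mean_fitted = mean(x$n_fitted_chain),
                 accept_rate = x$accept_rate,
                 sigma_e2 = mean(x$sigma_e2_chain[-seq_len(x$config$burn_in)]))
}

#' Genomic estimated breeding values from a BayesB posterior
#'
#' `GEBV_i = sum_j Z_ij * alpha_hat_j`, scoring (possibly new) genotypes by
#' the posterior-mean allele-substitution effects. Missing calls are
#' imputed with the training-sample allele frequencies.
#'
#' @param posterior A [run_bayesb()] fit.
#' @param geno A [geno_matrix()] with exactly the training marker set.
#' @return Tibble with `id` and `gebv`.
#' @export
posterior_genetic_values <- function(posterior, geno) {
  stopifnot(inherits(posterior, "bayesb_fit"), inherits(geno, "geno_matrix"))
  if (!identical(geno$map$snp_id, posterior$map$snp_id))
    stop("alignment error: marker sets differ", call. = FALSE)
  Z <- ifelse(is.na(geno$dosage),
              rep(2 * posterior$freq, each = nrow(geno$dosage)), geno$dosage)
  tibble::tibble(id = geno_ids(geno),
                 gebv = unname(drop(Z %*% posterior$alpha_hat)))
}
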