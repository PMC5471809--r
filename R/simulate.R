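#' Simulate LD-structured genotypes
#'
#' Builds haplotypes by a first-order Markov copying process: each haplotype
#' carries a latent uniform variable along the chromosome that is copied
#' from the previous marker with probability `ld_decay_rho` and redrawn
#' otherwise; the allele at marker `j` is the indicator that the latent
#' variable falls below the allele frequency `p_j`. Adjacent markers that
#' share the latent variable are in perfect LD, so pairwise correlation
#' decays geometrically with marker lag (approximately `rho^lag` when
#' frequencies are equal). Genotypes are sums of two independent haplotypes,
#' so loci are in Hardy-Weinberg proportions marginally.
#'
#' @param config A [sim_config()].
#' @return A [geno_matrix()] with per-chromosome positions strictly
#'   increasing in `[1, chrom_length_bp]`.
#' @examples
#' g <- simulate_genotypes(sim_config(n_individuals = 20, n_chromosomes = 1,
#'                                    snps_per_chrom = 50))
#' dim(g)
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  maps <- vector("list", config$n_chromosomes)
  blocks <- vector("list", config$n_chromosomes)
  for (c_idx in seq_len(config$n_chromosomes)) {
    m <- config$snps_per_chrom
    bp <- sort(sample.int(config$chrom_length_bp, m, replace = FALSE))
    p <- runif(m, config$maf_range[1], config$maf_range[2])
    hap <- matrix(0L, 2L * n, m)
    u <- runif(2L * n)
    hap[, 1] <- as.integer(u < p[1])
    if (m > 1) {
      for (j in 2:m) {
        redraw <- runif(2L * n) >= config$ld_decay_rho
        u[redraw] <- runif(sum(redraw))
        hap[, j] <- as.integer(u < p[j])
      }
    }
    blocks[[c_idx]] <- hap[seq_len(n), , drop = FALSE] +
      hap[n + seq_len(n), , drop = FALSE]
    maps[[c_idx]] <- tibble::tibble(
      snp_id = sprintf("snp%d_%d", c_idx, seq_len(m)),
      chrom = c_idx, bp = bp, a1 = "A", a2 = "B")
  }
  dosage <- do.call(cbind, blocks)
  if (config$missing_rate > 0) {
    drop <- runif(length(dosage)) < config$missing_rate
    dosage[drop] <- NA_integer_
  }
  rownames(dosage) <- sprintf("ind%04d", seq_len(n))
  geno_matrix(dosage, dplyr::bind_rows(maps))
}

#' Simulate phenotypes with a known genetic architecture
#'
#' Draws `n_qtl` causal loci uniformly among the markers, samples
#' allele-substitution effects from the configured distribution, and
#' calibrates the architecture deterministically: residuals are rescaled so
#' that the realized sample heritability
#' `var(bv) / (var(bv) + var(e))` equals `target_h2` exactly (to floating
#' precision). Categorical fixed effects and numeric covariates are then
#' added on top, so the phenotype decomposes as
#' `y = mean + fixed + covariates + bv + e` with every component stored in
#' the returned truth object.
#'
#' @param geno A [geno_matrix()] (missing calls are mean-imputed for the
#'   breeding values).
#' @param config The [sim_config()] used to generate `geno` (its seed,
#'   offset internally, governs the phenotype draws).
#' @return A list with elements
#'   * `traits`: tibble with `id`, the trait column `y`, factor columns and
#'     covariate columns — the phenotype/covariate table consumed by
#'     [adjust_phenotypes()];
#'   * `truth`: `sim_truth` list with `qtl_indices`, `qtl_effects` (zero for
#'     non-QTL markers in `all_effects`), `true_bv`, `realized_h2`,
#'     `sigma_e2`, and `fixed_effect_values`.
#' @examples
#' cfg <- sim_config(n_individuals = 100, n_chromosomes = 1,
#'                   snps_per_chrom = 50, n_qtl = 5, target_h2 = 0.5)
#' sim <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
#' sim$truth$realized_h2
#' @export
simulate_phenotypes <- function(geno, config) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(config, "sim_config"))
  n <- nrow(geno$dosage)
  if (n < 2) stop("need at least 2 individuals", call. = FALSE)
  M <- ncol(geno$dosage)
  set.seed(config$seed + 104729L)  # offset so genotype and phenotype draws differ

  h2 <- config$target_h2
  if (h2 > 0 && config$n_qtl == 0)
    stop("architecture error: positive heritability needs QTL", call. = FALSE)

  qtl <- if (config$n_qtl > 0) sort(sample.int(M, config$n_qtl)) else integer(0)
  effects <- numeric(length(qtl))
  if (length(qtl) > 0 && h2 > 0) {
    effects <- switch(config$effect_dist,
      "gaussian" = rnorm(length(qtl)),
      "gamma-signed" = rgamma(length(qtl), shape = 0.4, rate = 1.66) *
        sample(c(-1, 1), length(qtl), replace = TRUE))
    if (all(effects == 0)) effects[1] <- 1  # degenerate gamma draw guard
  }

  W <- center_dosage(geno)
  bv <- if (length(qtl) > 0) drop(W[, qtl, drop = FALSE] %*% effects) else numeric(n)
  e <- rnorm(n)
  e <- e - mean(e)

  # deterministic calibration: scale bv and e to hit target_h2 exactly
  if (h2 == 0) {
    effects <- numeric(length(qtl))
    bv <- numeric(n)
    sd_e <- 1
  } else if (h2 == 1) {
    e[] <- 0
    sd_e <- 0
  } else {
    v_bv <- var(bv)
    if (v_bv <= 0)
      stop("architecture error: QTL carry no variance (monomorphic?)", call. = FALSE)
    target_ve <- v_bv * (1 - h2) / h2
    sd_e <- sqrt(target_ve / var(e))
  }
  e <- e * sd_e
  sigma_e2 <- var(e)
  realized_h2 <- if (h2 == 0) 0 else var(bv) / (var(bv) + sigma_e2)

  # fixed effects and covariates
  fixed <- numeric(n)
  factors <- list()
  for (f in names(config$fixed_effect_levels)) {
    k <- config$fixed_effect_levels[[f]]
    lev <- sample.int(k, n, replace = TRUE)
    eff <- rnorm(k, sd = if (h2 > 0) sqrt(var(bv) + sigma_e2) * 0.3 else 0.3)
    fixed <- fixed + eff[lev]
    factors[[f]] <- factor(paste0(f, lev))
  }
  covs <- list()
  for (cv in names(config$covariate_specs)) {
    sp <- config$covariate_specs[[cv]]
    x <- rnorm(n, sp[["mean"]], sp[["sd"]])
    fixed <- fixed + sp[["slope"]] * x
    covs[[cv]] <- x
  }

  mu <- if (h2 > 0) abs(mean(bv)) + 10 else 10
  y <- mu + fixed + bv + e

  all_effects <- numeric(M)
  all_effects[qtl] <- effects
  traits <- tibble::tibble(id = geno_ids(geno), y = y)
  traits <- dplyr::bind_cols(traits, tibble::as_tibble(factors),
                             tibble::as_tibble(covs))
  truth <- structure(list(
    qtl_indices = qtl,
    qtl_effects = effects,
    all_effects = all_effects,
    true_bv = bv,
    realized_h2 = realized_h2,
    sigma_e2 = sigma_e2,
    fixed_effect_values = fixed
  ), class = "sim_truth")
  list(traits = traits, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> ", length(x$qtl_indices), " QTL, realized h2 = ",
      round(x$realized_h2, 4), "\n", sep = "")
  invisible(x)
}

#' Simulate a pair of genetically correlated traits
#'
#' Draws a shared set of QTL and per-QTL effect pairs from a bivariate
#' normal with correlation `r_g`, producing two phenotypes whose breeding
#' values are correlated at (approximately, up to effect-sampling noise)
#' `r_g`; each trait is calibrated to its own heritability exactly as in
#' [simulate_phenotypes()]. Residuals are independent between traits, so
#' the phenotypic correlation is `r_g * sqrt(h2_1 * h2_2)` in expectation.
#'
#' @param geno A [geno_matrix()].
#' @param n_qtl Number of shared causal loci.
#' @param h2 Length-2 vector of target heritabilities.
#' @param r_g Genetic correlation of the effect pairs in `[-1, 1]`
#'   (`r_g = 0` draws independent architectures).
#' @param seed Integer seed.
#' @return List with `traits` (tibble: `id`, `y1`, `y2`) and `truth`
#'   (list: `qtl_indices`, `true_bv1`, `true_bv2`, `realized_r_g` — the
#'   sample correlation of the two breeding values — and realized
#'   heritabilities).
#' @export
simulate_trait_pair <- function(geno, n_qtl = 50, h2 = c(0.4, 0.4),
                                r_g = 0.8, seed = 1L) {
  stopifnot(inherits(geno, "geno_matrix"), abs(r_g) <= 1,
            all(h2 > 0), all(h2 < 1))
  set.seed(seed)
  n <- nrow(geno$dosage)
  M <- ncol(geno$dosage)
  qtl <- sort(sample.int(M, n_qtl))
  z1 <- rnorm(n_qtl)
  z2 <- r_g * z1 + sqrt(1 - r_g^2) * rnorm(n_qtl)
  W <- center_dosage(geno)[, qtl, drop = FALSE]
  bv1 <- drop(W %*% z1)
  bv2 <- drop(W %*% z2)
  scale_resid <- function(bv, h2_t) {
    e <- rnorm(n); e <- e - mean(e)
    e * sqrt(var(bv) * (1 - h2_t) / h2_t / var(e))
  }
  e1 <- scale_resid(bv1, h2[1])
  e2 <- scale_resid(bv2, h2[2])
  traits <- tibble::tibble(id = geno_ids(geno),
                           y1 = 10 + bv1 + e1, y2 = 10 + bv2 + e2)
  truth <- list(qtl_indices = qtl, true_bv1 = bv1, true_bv2 = bv2,
                realized_r_g = cor(bv1, bv2),
                realized_h2 = c(var(bv1) / (var(bv1) + var(e1)),
                                var(bv2) / (var(bv2) + var(e2))))
  list(traits = traits, truth = truth)
}
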