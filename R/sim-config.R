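#' Configuration for the genotype/phenotype simulator
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the structure of a Chinese Simmental beef-cattle study
#' population at desk scale: ~700 animals, LD-blocked autosomal SNPs, a
#' sparse QTL architecture, fixed effects of gender, farm and year, and
#' slaughter-related covariates.
#'
#' @param n_individuals Number of individuals.
#' @param n_chromosomes Number of autosomes simulated (cattle have 29; desk
#'   runs typically use 2-5).
#' @param snps_per_chrom Markers per chromosome.
#' @param chrom_length_bp Chromosome length in base pairs; marker positions
#'   are drawn uniformly in `[1, chrom_length_bp]`.
#' @param ld_decay_rho Per-adjacent-marker haplotype copying probability in
#'   `[0, 1]`. 0 gives independent loci; values near 1 give long-range LD
#'   that decays with marker distance (first-order Markov haplotypes).
#' @param maf_range Length-2 numeric in `(0, 0.5]`; allele frequencies are
#'   drawn uniformly from this interval.
#' @param n_qtl Number of causal loci (drawn uniformly among markers).
#' @param target_h2 Narrow-sense heritability the phenotype is calibrated
#'   to, in `[0, 1]`. Calibration is deterministic: realized sample
#'   heritability equals the target exactly (see [simulate_phenotypes()]).
#' @param effect_dist QTL allele-substitution effect distribution:
#'   `"gaussian"` or `"gamma-signed"` (gamma magnitudes with random signs, a
#'   heavier-tailed architecture).
#' @param fixed_effect_levels Named integer vector: number of levels per
#'   categorical fixed effect. Defaults mirror the study design (2 genders,
#'   3 farms, 4 birth years).
#' @param covariate_specs Named list of `c(mean, sd, slope)` per numeric
#'   covariate. Defaults: slaughter age (months), days from slaughter to
#'   fatty-acid extraction, hot carcass weight (kg), marbling score.
#' @param missing_rate Proportion of genotype calls set to missing
#'   (default 0; QC tests inject positive rates explicitly).
#' @param seed Integer seed governing every draw.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_individuals = 50, snps_per_chrom = 20, n_qtl = 2)
#' cfg$target_h2
#' @export
sim_config <- function(n_individuals = 700,
                       n_chromosomes = 3,
                       snps_per_chrom = 400,
                       chrom_length_bp = 2e6,
                       ld_decay_rho = 0.9,
                       maf_range = c(0.05, 0.5),
                       n_qtl = 10,
                       target_h2 = 0.3,
                       effect_dist = c("gaussian", "gamma-signed"),
                       fixed_effect_levels = c(gender = 2L, farm = 3L, year = 4L),
                       covariate_specs = list(
                         slaughter_age     = c(mean = 20,  sd = 2,  slope = 0.05),
                         days_to_extraction = c(mean = 30, sd = 10, slope = 0.01),
                         hot_carcass_weight = c(mean = 280, sd = 30, slope = 0.002),
                         marbling_score    = c(mean = 5,  sd = 1.5, slope = 0.1)
                       ),
                       missing_rate = 0,
                       seed = 1L) {
  effect_dist <- match.arg(effect_dist)
  if (n_individuals < 1 || n_chromosomes < 1 || snps_per_chrom < 1)
    stop("config error: dimensions must be positive", call. = FALSE)
  if (chrom_length_bp < snps_per_chrom)
    stop("config error: chrom_length_bp must allow distinct positions", call. = FALSE)
  if (ld_decay_rho < 0 || ld_decay_rho > 1)
    stop("config error: ld_decay_rho must be in [0, 1]", call. = FALSE)
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("config error: maf_range must be within (0, 0.5]", call. = FALSE)
  total_snps <- n_chromosomes * snps_per_chrom
  if (n_qtl > total_snps)
    stop("config error: n_qtl exceeds total number of SNPs", call. = FALSE)
  if (target_h2 < 0 || target_h2 > 1)
    stop("config error: target_h2 must be in [0, 1]", call. = FALSE)
  if (target_h2 > 0 && n_qtl == 0)
    stop("architecture error: target_h2 > 0 requires at least one QTL", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("config error: missing_rate must be in [0, 1)", call. = FALSE)

  structure(list(
    n_individuals = as.integer(n_individuals),
    n_chromosomes = as.integer(n_chromosomes),
    snps_per_chrom = as.integer(snps_per_chrom),
    chrom_length_bp = as.integer(chrom_length_bp),
    ld_decay_rho = ld_decay_rho,
    maf_range = maf_range,
    n_qtl = as.integer(n_qtl),
    target_h2 = target_h2,
    effect_dist = effect_dist,
    fixed_effect_levels = fixed_effect_levels,
    covariate_specs = covariate_specs,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_individuals, " individuals x ",
      x$n_chromosomes * x$snps_per_chrom, " SNPs (",
      x$n_chromosomes, " chromosomes), ", x$n_qtl, " QTL, target h2 = ",
      x$target_h2, ", rho = ", x$ld_decay_rho, "\n", sep = "")
  invisible(x)
}
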