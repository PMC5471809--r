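# fattygs

Genomic evaluation of fatty-acid composition in beef cattle: a tested R
pipeline covering trait construction, quality control, heritability and
genetic-correlation estimation, Bayesian and single-marker genome-wide
association, region-based tests, and cross-validated genomic prediction.

## Who this is for

Animal-breeding and livestock-genomics researchers working with
medium-density to high-density SNP panels and carcass-quality phenotypes —
here, 21 individual fatty acids measured by gas chromatography as
percentages of total fatty acid methyl esters, plus their group sums
(SFA, MUFA, PUFA, omega-3, omega-6) and derived indices. Every stage is
driven by plain data frames and matrix-backed genotype containers, and a
synthetic-data generator with known genetic architecture lets each method
be validated against ground truth before it touches real data.

## The models at the package's core

**Marker-effect model (BayesB).** For adjusted phenotypes `y`,

    y_i = u + sum_j Z_ij alpha_j delta_j + e_i

where `Z_ij` counts copies of an allele at marker `j`, `alpha_j ~ N(0,
sigma_j^2)` is a locus-specific allele-substitution effect, `delta_j` is a
0/1 inclusion indicator with prior exclusion probability `pi` (0.9998 for a
600K panel, so ~100–150 markers are fitted per MCMC sweep), and
`sigma_j^2`, `sigma_e^2` carry scaled inverse chi-square priors
(`nu_alpha = 4`, `nu_e = 10`, scales derived from REML variance
components). The sampler (C++ core) updates each locus by a joint
Metropolis–Hastings move on `(delta_j, sigma_j^2)` with the effect
integrated out, then Gibbs draws. Associations are summarised per 100 kb
window as the posterior mean share of whole-genome breeding-value variance;
windows carrying ≥ 1% are candidate regions.

**Animal model (GBLUP / REML).** `y = 1u + a + e` with `V(a) = G sigma_a2`
built from the VanRaden genomic relationship matrix
`G = W W' / (2 sum p_j (1 - p_j))`. Univariate REML (exact, via
eigendecomposition of `G`) gives `h2 = sigma_a2 / (sigma_a2 + sigma_e2)`;
pairwise bivariate REML gives genetic correlations
`r_g = sigma_a12 / sqrt(sigma_a1^2 sigma_a2^2)`.

**GRAMMAR-GC.** Single-marker score tests on the environmental residuals of
the animal model, rescaled by the genomic-control inflation factor
`lambda = median(chi2) / 0.4549`, with Bonferroni (`0.05 / n_snps`) and
suggestive (`0.05 / n_independent`) thresholds.

**Genomic prediction.** GBLUP and BayesB under 5-fold cross-validation;
accuracy is `cor(GEBV, y_adj) / sqrt(h2)` and dispersion bias the
GEBV-phenotype regression slope.

## Worked example

```r
library(fattygs)

# simulate a 700-animal cohort: 3 chromosomes x 400 SNPs, 10 QTL, h2 = 0.3
cfg  <- sim_config(seed = 42)
geno <- simulate_genotypes(cfg)
sim  <- simulate_phenotypes(geno, cfg)

qc   <- qc_filter(geno)
qc$report
#> <qc_report> individuals 700 -> 700 | SNPs 1200 -> 1188 (maf 12, callrate 0, hwe 0, non-autosomal 0)

adj  <- adjust_phenotypes(sim$traits, "y")      # OLS fixed-effect adjustment
grm  <- build_grm(qc$geno)
vc   <- reml_univariate(adj, grm)
vc
#> <varcomp> trait y: sigma_a2 = 3.253, sigma_e2 = 7.243, h2 = 0.31

fit  <- run_bayesb(adj, qc$geno, bayesb_config(pi = 0.998, seed = 1))
head(dplyr::arrange(window_variance_proportions(fit, qc$geno),
                    dplyr::desc(var_proportion)), 3)
#> # A tibble: 3 x 7
#>   chrom window start_bp  end_bp n_snp var_proportion candidate
#>   <int>  <int>    <int>   <int> <int>          <dbl> <lgl>
#> 1     3     11  1100001 1200000    17        0.683   TRUE
#> 2     3     14  1400001 1500000    29        0.283   TRUE
#> 3     2     13  1300001 1400000    18        0.00695 FALSE

scan <- grammar_gc_scan(adj, qc$geno, grm, vc)
attr(scan, "lambda")
#> [1] 0.4136664

cv   <- crossvalidate(adj, qc$geno, grm, method = "gblup", seed = 1)
cv
#> <cv_result> gblup, 5 folds: r = 0.606 +/- 0.048, b = 0.12 +/- 0.008
```

The top window's `var_proportion` of 0.68 says that markers in one 100 kb
bin carry ~68% of the posterior genetic variance — a candidate region
(threshold 1%), while the third window falls below it. The REML `h2` of
0.31 recovers the simulated 0.3 within sampling error, and the
cross-validated accuracy `r` of 0.61 is the fold mean of
`cor(GEBV, y_adj)/sqrt(h2)`. The raw inflation factor below 1
reflects the deflation of residual-based association tests at desk scale
(see the methods vignette); corrected p-values (`p_gc`) restore nominal
calibration. Each result type has `tidy()`/`glance()` and `autoplot()`
methods for tables and Manhattan/window/fold plots.

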