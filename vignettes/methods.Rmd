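---
title: "Models and methods for fatty-acid genomic evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for fatty-acid genomic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery:
the models, their assumptions, the parameters that matter, and the design
choices made where several defensible options existed. The companion README
shows the code path; here we explain why each piece looks the way it does.

## Traits and adjustment

The phenotypes are 21 individual fatty acids expressed as percentages of
total fatty acid methyl esters, plus eight derived group traits built by
`compute_groups()`: the class sums SFA, MUFA and PUFA; the omega subsets
n-3 and n-6; the ratios PUFA/SFA and n-6/n-3; and the health index
`HI = (MUFA + PUFA) / (4 * C14:0 + C16:0)`, in which myristic acid is
weighted four-fold for its hypercholesterolemic effect. Ratios with a zero
denominator are recorded as missing rather than raising an error, because
synthetic extremes (all-zero components) are legitimate test inputs.

`adjust_phenotypes()` removes gender, farm and year (categorical) and
slaughter age, days to fatty-acid extraction, hot carcass weight and
marbling score (numeric) by ordinary least squares, then re-centres the
residual at the grand mean. A mixed model with a polygenic term could be
used at this step instead; we deliberately use fixed-effects-only OLS
because every downstream model (REML animal model, BayesB, GRAMMAR) carries
its own genomic covariance term, and absorbing part of the genetic signal
into the adjustment would count it twice. Re-centring keeps the
marker-model intercept interpretable as the trait mean after fixed-effect
removal. Single-level factors are aliased with the intercept and are
dropped; rank-deficient designs drop aliased columns with a warning rather
than failing.

## The synthetic-data generator

Every method in the package is validated against simulated data with known
truth, so the generator is first-class, tested code.

*Genotypes* (`simulate_genotypes()`): haplotypes follow a first-order
Markov copying process. Each haplotype carries a latent uniform variate
along the chromosome, copied from the previous marker with probability
`ld_decay_rho` and redrawn otherwise; the allele is the indicator that the
variate falls below the marker's frequency (drawn uniformly from
`maf_range`, default 0.05–0.5). Adjacent markers sharing the latent
variate are in complete LD, so correlation decays geometrically with
marker lag — enough block structure to exercise 100 kb-window methods
without a coalescent dependency. Genotypes are sums of two independent
haplotypes and are therefore in Hardy–Weinberg proportions marginally.
The default configuration emulates a Simmental beef-cattle cohort at desk scale:
700 individuals, a few chromosomes of a few hundred markers each, gender
(2), farm (3) and year (4) fixed effects, and slaughter-related
covariates with modest slopes. The copying parameter is a free parameter
of the generator — the real population's LD is not quantified — so
analyses that depend on LD strength state their choice explicitly.

*Phenotypes* (`simulate_phenotypes()`): `n_qtl` causal loci are drawn
uniformly, effects are Gaussian or signed-gamma (`gamma-signed` gives the
heavy-tailed, few-large-effects architecture under which variable-selection
methods outperform ridge-type methods), and the residual vector is rescaled
deterministically so the realized sample heritability equals the target
exactly. We calibrate by scaling rather than by solving per-QTL variances a
priori because it gives exact control at any `n` and any effect
distribution. The truth object stores QTL positions, effects, breeding
values and the realized heritability for recovery tests.
`simulate_trait_pair()` extends this to two traits sharing QTL with
effect pairs drawn at a chosen correlation, for bivariate-REML validation.

What the generator does **not** emulate: mutation/recombination realism,
multi-breed or family structure, selection, genotyping error, and the
empirical site-frequency spectrum. Passing tests therefore demonstrate
correctness of the algorithms under their own assumptions, not robustness
to every artefact of real data.

## Genotype input and quality control

PLINK 1 binary triplets (bed/bim/fam) are read and written natively: the
codec is part of the tested surface, with byte-level unit tests (magic
bytes `6c 1b 01`, SNP-major, four 2-bit calls per byte, lowest-order pair
first). QC follows the pre-association convention: individuals with more
than 10% missing calls are removed first (so marker statistics reflect the
analyzed sample), then markers failing MAF > 0.05, per-marker missingness
< 0.05, Hardy–Weinberg `P` > 1e-6 (1-df chi-square goodness of fit;
monomorphic markers get `P = 1` by convention), or lying off the 29
autosomes. A marker failing several filters is attributed to the first in
that order, so the QC report's counts partition the dropped set. Missing
dosages are kept as missing in storage and imputed as twice the allele
frequency only where matrices are built (relationship matrix, regressions).

## Relationship matrix and REML

`build_grm()` implements the first VanRaden method,
`G = W W' / (2 sum p_j (1 - p_j))` with `W` the dosage matrix centred by
`2 p_j` and frequencies taken from the analyzed sample. Under
Hardy–Weinberg sampling the diagonal averages ~1 (a tested property).

Univariate REML exploits that `V = sigma_a2 G + sigma_e2 I` is
simultaneously diagonalized by the eigendecomposition of `G`: after one
`O(n^3)` setup, each likelihood evaluation is `O(n)`. The restricted
likelihood is profiled over the variance ratio and maximized exactly
(coarse grid bracketing, then golden-section refinement on the log-ratio in
[-10, 10]), which cannot leave the parameter space and has no convergence
tuning — the reason we preferred it to iterative AI-REML at these problem
sizes. Variance components are floored at `1e-8` of the phenotypic
variance so boundary estimates never produce negative heritability;
standard errors come from the observed information (finite differences)
with the delta method for `h2`.

Bivariate REML shares the eigenbasis: per eigenvalue the two transformed
observations have a 2x2 covariance `d_i A + E`, with `A` and `E` the
genetic and residual trait-covariance matrices. The restricted likelihood
is maximized by Nelder–Mead over log-Cholesky factors of `A` and `E`
(guaranteeing positive semi-definiteness), started from the univariate
fits with a mild initial genetic correlation. The genetic correlation is
clamped to [-1, 1] with a warning on small overshoot; fits of effectively
identical traits sit at that boundary by construction.

## BayesB

The sampler implements the mixture prior with a point mass at zero:
exclusion probability `pi` (default 0.9998; at desk scale tests typically
use 0.99–0.998 so that the expected `(1 - pi) * M` fitted markers is a
few), locus variances `sigma_j^2 ~` scaled-inv-chi-square(`nu_alpha = 4`,
`S_alpha^2`), residual variance scaled-inv-chi-square(`nu_e = 10`,
`S_e^2`). `derive_scale_params()` sets the scales so the prior *means*
reproduce externally estimated variance components:
`S_alpha^2 = sigma_a2 (nu_alpha - 2) / nu_alpha / ((1 - pi) 2 sum p q)`
and `S_e^2 = sigma_e2 (nu_e - 2) / nu_e`.

Because `sigma_j^2` has no closed-form conditional when the effect is
mixed over a point mass, each locus is updated by a joint
Metropolis–Hastings move on `(delta_j, sigma_j^2)` with the effect
integrated out analytically and the proposal drawn from the prior
(Meuwissen-style); the effect is then Gibbs-sampled given inclusion, the
mean by Gibbs, and the residual variance from its full conditional after
all loci (systematic scan). Genotypes are centred by `2 p_j` inside the
sampler for numerical stability — the intercept absorbs the constant — but
genetic values and GEBVs are reported on the raw dosage scale
(`GEBV_i = sum_j Z_ij alpha_hat_j`), which differs only by a constant.
The core is C++ (RcppArmadillo) and draws from R's RNG, so `set.seed()`
makes whole chains reproducible.

Chain schedule: the production convention for a 600K panel is 50,000
sweeps with 10,000 burn-in. The package default is a desk-scale 5,000/1,000
chain — at a few hundred markers the posterior is far cheaper to traverse —
and all tests state their chain lengths; passing `n_iter = 50000,
burn_in = 10000` restores the production schedule. Thinned effect vectors
(every 10th retained sweep by default) are stored for window-variance
computation; posterior means use every retained sweep.

Two sampler switches exist purely for verification: `fixed_effect_var`
freezes every locus variance and `fixed_sigma_e2` the residual variance,
so that with `pi = 0` the model collapses to Bayesian ridge regression
whose posterior mean is available in closed form — the package's core
correctness gate for the sampler.

## Window-based association

Markers are binned into 100 kb windows anchored at position 1 per
chromosome (`floor((bp - 1)/1e5)`, 1-based inclusive bounds). For each
retained MCMC sample the window's genetic value is the sum of its marker
contributions, and its share is the variance over individuals of that
window value divided by the variance of the whole-genome value; shares are
averaged over samples, and windows with a posterior-mean share of at least
1% are candidate regions. Note the per-sample shares sum to 1 only when
window values are uncorrelated; under LD leaking across window boundaries
the covariance terms make the sum deviate. The
`denominator = "window_sum"` option divides by the sum of window variances
instead, which enforces exact conservation at the cost of departing from
the whole-genome-variance definition; the default keeps the standard
definition. Samples in which the sparse prior keeps every marker out of
the model carry zero genetic variance and are skipped with a warning.

## GRAMMAR-GC and the inflation factor

The two-stage scan fits the polygenic animal model once, forms the
environmental residuals `e_hat = y - mu_hat - a_hat` (BLUP subtracted),
and score-tests every marker against them; genomic control then divides
the statistics by `lambda = median(chi2) / 0.4549`. The residual stage is
deliberately cheap — `O(nM)` across markers — which is the method's point,
and it is *mis*calibrated by construction: subtracting the BLUP removes
variance preferentially along genotype-spanned directions, deflating the
raw statistics (`lambda < 1`). The deflation grows with the eigenvalue
spread of `G`; with markers only a small multiple of the sample size
(desk scale) it is clearly visible, while at hundreds of thousands of
markers `G` concentrates and raw `lambda` approaches 1. The GC step exists
precisely to absorb this: the quantity to quote after correction is the
remaining inflation of the corrected statistics, which the scan exposes as
`lambda_gc` (QQ-regression slope of the corrected chi-squares — not
identically 1, unlike the median of median-corrected statistics). The
calibration tests accordingly simulate the model-faithful null — every
marker causal with Gaussian effects, i.e. breeding values distributed
exactly as `N(0, G sigma_a2)`, on unlinked markers — and check that
`lambda_gc` is close to one and corrected p-values hold their nominal
size. Strong desk-scale LD would additionally deflate the raw stage
through proximal contamination; this is a reduced-scale artefact, noted as
a limitation rather than corrected for.

Significance uses the Bonferroni threshold `0.05 / n_snps` and a
suggestive threshold `0.05 / n_independent`, where the independent count
(LD blocks plus interblock markers) is supplied by the caller — block
counting is deliberately out of scope, so the package does not invent a
block algorithm.

## Region-based test and LD

`region_score_test()` is a SKAT-style variance-component score test on the
GRAMMAR residuals: `Q = sum_k w_k^2 (z_k' e_hat)^2` with centred dosages
and beta(1, 25) MAF weights by default, p-values from the Liu
moment-matching chi-square approximation to the weighted chi-square null
(implemented directly; a one-marker region reduces exactly to the marginal
score test). The beta(1, 25) default follows rare-variant convention, but
on post-QC panels every marker has MAF > 0.05, where that weighting spans
orders of magnitude and can bury a common causal variant; power analyses
on such panels should pass `weights_beta = c(1, 1)` (flat), and the tests
do exactly that. A burden variant (`type = "burden"`) collapses the
weighted dosages before testing.

`pairwise_r2()` estimates two-locus haplotype frequencies by
expectation–maximization over unphased genotypes (double heterozygotes are
the only ambiguous class) and returns `r^2 = D^2 / (p q (1-p)(1-q))`,
falling back to the squared genotypic correlation if EM degenerates;
monomorphic pairs are defined as 0.

## Genomic prediction

`crossvalidate()` runs k-fold (default 5) cross-validation for GBLUP or
BayesB. Variance components are re-estimated on each training fold, so no
test-set information leaks into the fit, while the heritability
in the accuracy denominator is the whole-data REML estimate, fixed across
folds, matching the convention of one reported heritability per trait.
GBLUP solves the training mixed model and propagates BLUPs to unphenotyped
individuals through their genomic relationships; it is algebraically
identical to SNP-BLUP ridge regression on the same centred markers (a
tested equivalence). Accuracy is `cor(GEBV, y_adj) / sqrt(h2)`; the
headline bias coefficient `b` is the slope of GEBV on adjusted phenotype
as stated, with the conventional reverse slope (`b_reverse`, unity = no
dispersion bias) reported alongside because the two directions answer
different questions and the stated direction shrinks with prediction
error even for unbiased predictors.

## Problem sizes and numerical choices

Test and acceptance runs use desk-scale sizes chosen to make each
property measurable with comfortable margins: conjugate-limit and
equivalence oracles at n = 200, M = 500; heritability recovery over 20
replicates at n = 1000, M = 2000; genetic-correlation recovery at n = 600,
M = 1500; calibration runs at n = 1000, M = 2000 over 10 seeds; and
cross-validation orderings at n = 500, M = 1000 over 10 seeds. Other
numerical choices collected in one place: GRM ridge of 1e-6 only if the
matrix is numerically indefinite; REML variance floor 1e-8 of phenotypic
variance; variance-ratio search on log scale in [-10, 10]; genetic
correlations clamped to [-1, 1]; EM for haplotype frequencies capped at
100 iterations with 1e-10 tolerance; chi-square HWE rather than the exact
test (the 1e-6 screening threshold makes the difference immaterial, and
the function is isolated should an exact test be preferred).

## Known limitations

- Raw GRAMMAR `lambda` is below 1 at desk scale by construction (see
  above); only the post-correction calibration is meaningful there.
- Bivariate REML can sit at the `|r_g| = 1` boundary for small samples or
  near-identical traits; estimates are clamped, and standard errors near
  the boundary are unreliable.
- The region test's default weights target rare variants; use flat
  weights on common-variant panels.
- The generator's LD model produces geometric decay only; it cannot
  reproduce long-range admixture LD or ascertainment effects.
- Sex chromosomes, duplicate-sample detection and relatedness pruning are
  out of scope for QC.
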