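#' Fatty-acid component names
#'
#' The 21 individual fatty acids measured by gas chromatography, expressed
#' as percentages of total fatty acid methyl esters, grouped by saturation
#' class. Used to validate trait tables and to build the group traits.
#'
#' @return Named list of character vectors: `sfa` (6 saturated), `mufa`
#'   (4 monounsaturated), `pufa` (11 polyunsaturated), and the omega
#'   subsets `n3`, `n6` of `pufa`.
#' @export
fatty_acid_components <- function() {
  list(
    sfa = c("C14:0", "C16:0", "C18:0", "C20:0", "C22:0", "C24:0"),
    mufa = c("C14:1 cis-9", "C16:1 cis-9", "C18:1 cis-9", "C20:1 cis-11"),
    pufa = c("C18:2 n-6", "C18:2 t-9c-11", "C18:2 t-12c-10", "C18:3 n-6",
             "C18:3 n-3", "C20:2 n-6", "C20:3 n-3", "C20:4 n-6",
             "C20:5 n-3", "C22:5 n-3", "C22:6 n-3"),
    n3 = c("C18:3 n-3", "C20:3 n-3", "C20:5 n-3", "C22:5 n-3", "C22:6 n-3"),
    n6 = c("C18:2 n-6", "C18:3 n-6", "C20:2 n-6", "C20:4 n-6")
  )
}

#' Compute fatty-acid group traits
#'
#' Augments a trait table with the eight group traits:
#' `SFA`, `MUFA`, `PUFA` (class sums), `PUFA/SFA`, `n-3`, `n-6` (omega
#' sums), `n-6/n-3`, and the health index
#' `HI = (MUFA + PUFA) / (4 * C14:0 + C16:0)`. Ratios with a zero
#' denominator are recorded as `NA`.
#'
#' @param traits Data frame with all 21 fatty-acid component columns (see
#'   [fatty_acid_components()]); any other columns are carried through.
#' @return The input as a tibble with the eight group columns appended.
#' @examples
#' tab <- tibble::tibble(!!!setNames(as.list(rep(1, 21)),
#'                                   unlist(fatty_acid_components()[1:3])))
#' compute_groups(tab)$SFA  # 6
#' @export
compute_groups <- function(traits) {
  fa <- fatty_acid_components()
  needed <- c(fa$sfa, fa$mufa, fa$pufa)
  missing_cols <- setdiff(needed, names(traits))
  if (length(missing_cols) > 0)
    stop("schema error: missing fatty-acid columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- tibble::as_tibble(traits)
  row_sum <- function(cols) rowSums(out[cols])
  safe_ratio <- function(num, den) ifelse(den == 0, NA_real_, num / den)

  out$SFA <- row_sum(fa$sfa)
  out$MUFA <- row_sum(fa$mufa)
  out$PUFA <- row_sum(fa$pufa)
  out$`PUFA/SFA` <- safe_ratio(out$PUFA, out$SFA)
  out$`n-3` <- row_sum(fa$n3)
  out$`n-6` <- row_sum(fa$n6)
  out$`n-6/n-3` <- safe_ratio(out$`n-6`, out$`n-3`)
  out$HI <- safe_ratio(out$MUFA + out$PUFA, 4 * out$`C14:0` + out$`C16:0`)
  out
}

#' Mean, SD and coefficient of variation of a trait
#'
#' @param values Numeric vector; missing values dropped. At least two
#'   non-missing observations are required.
#' @return Tibble with `mean`, `sd` (n-1 denominator), and `cv_percent`
#'   (`100 * sd / mean`, `NA` when the mean is zero).
#' @examples
#' summarize_trait(c(1.2, 1.5, 2.0))
#' @export
summarize_trait <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2)
    stop("need at least 2 non-missing values", call. = FALSE)
  m <- mean(values)
  s <- sd(values)
  tibble::tibble(mean = m, sd = s,
                 cv_percent = if (m == 0) NA_real_ else 100 * s / m)
}

#' Adjust a phenotype for fixed effects and covariates
#'
#' Ordinary least-squares regression of the trait on the categorical fixed
#' effects (dummy-coded) and numeric covariates; the adjusted phenotype is
#' the residual re-centred at the grand mean, so the overall mean of the
#' downstream marker-effect model stays interpretable. Individuals with a
#' missing trait value are dropped; aliased (rank-deficient) design columns
#' are dropped with a warning.
#'
#' @param traits Data frame with an `id` column, the trait column, and the
#'   adjustment columns.
#' @param trait Name of the trait column.
#' @param factors Character vector of categorical fixed-effect columns
#'   (default `gender`, `farm`, `year`, intersected with what is present).
#' @param covariates Character vector of numeric covariate columns
#'   (defaults to the slaughter-related covariates present in the table).
#' @return Tibble of class `adjusted_phenotype` with `id`, `y_adj`, and
#'   attribute `trait`.
#' @examples
#' cfg <- sim_config(n_individuals = 60, n_chromosomes = 1, snps_per_chrom = 30)
#' sim <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
#' adj <- adjust_phenotypes(sim$traits, "y")
#' head(adj)
#' @export
adjust_phenotypes <- function(traits, trait,
                              factors = c("gender", "farm", "year"),
                              covariates = c("slaughter_age",
                                             "days_to_extraction",
                                             "hot_carcass_weight",
                                             "marbling_score")) {
  stopifnot("id" %in% names(traits))
  if (!trait %in% names(traits))
    stop("schema error: trait column not found: ", trait, call. = FALSE)
  factors <- intersect(factors, names(traits))
  covariates <- intersect(covariates, names(traits))

  dat <- tibble::as_tibble(traits)
  keep <- !is.na(dat[[trait]])
  adjust_cols <- c(factors, covariates)
  if (length(adjust_cols) > 0)
    keep <- keep & complete.cases(dat[adjust_cols])
  dat <- dat[keep, ]
  # single-level factors are aliased with the intercept; drop them
  factors <- factors[vapply(factors, function(f) {
    length(unique(dat[[f]])) >= 2
  }, logical(1))]
  adjust_cols <- c(factors, covariates)

  y <- dat[[trait]]
  if (length(adjust_cols) == 0) {
    y_adj <- y
  } else {
    form <- stats::reformulate(sprintf("`%s`", adjust_cols), response = NULL)
    X <- model.matrix(form, data = dat)
    fit <- stats::lm.fit(X, y)
    if (any(is.na(fit$coefficients)))
      warning("rank-deficient design: dropped aliased columns", call. = FALSE)
    y_adj <- unname(fit$residuals) + mean(y)
  }
  out <- tibble::tibble(id = dat$id, y_adj = y_adj)
  attr(out, "trait") <- trait
  class(out) <- c("adjusted_phenotype", class(out))
  out
}
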