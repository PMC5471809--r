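#' VanRaden genomic relationship matrix
#'
#' First-method VanRaden matrix `G = W W' / (2 * sum p_j (1 - p_j))` where
#' `W` is the dosage matrix centred by twice the allele frequency of the
#' analyzed sample and missing calls are mean-imputed. For a sample in
#' Hardy-Weinberg proportions the diagonal averages ~1.
#'
#' @param geno A [geno_matrix()] of QC-passed genotypes.
#' @return Object of class `grm_matrix`: list with `G` (n x n symmetric
#'   matrix, dimnames = IDs), `ids`, and `denom` (`2 * sum p(1-p)`, also the
#'   marker-variance sum that scales marker effects to genetic variance).
#' @examples
#' cfg <- sim_config(n_individuals = 30, n_chromosomes = 1, snps_per_chrom = 50)
#' g <- build_grm(simulate_genotypes(cfg))
#' mean(diag(g$G))
#' @export
build_grm <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  W <- center_dosage(geno)
  p <- attr(W, "p")
  ok <- !is.na(p)
  denom <- 2 * sum(p[ok] * (1 - p[ok]))
  if (denom <= 0)
    stop("zero denominator: all markers monomorphic", call. = FALSE)
  G <- tcrossprod(W[, ok, drop = FALSE]) / denom
  dimnames(G) <- list(geno_ids(geno), geno_ids(geno))
  structure(list(G = G, ids = geno_ids(geno), denom = denom),
            class = "grm_matrix")
}

#' @export
print.grm_matrix <- function(x, ...) {
  cat("<grm_matrix> ", length(x$ids), " individuals, mean diagonal ",
      round(mean(diag(x$G)), 3), ", denom ", round(x$denom, 2), "\n", sep = "")
  invisible(x)
}

# eigendecomposition of a (sub)matrix of G with a small ridge if
# numerically indefinite
grm_eigen <- function(G) {
  ev <- eigen(G, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    warning("G not positive semi-definite; adding ridge 1e-6", call. = FALSE)
    ev <- eigen(G + diag(1e-6, nrow(G)), symmetric = TRUE)
  }
  ev$values <- pmax(ev$values, 0)
  ev
}
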