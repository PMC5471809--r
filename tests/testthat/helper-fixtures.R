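# published summary means of the 21 fatty-acid components (percent of total
# fatty acid methyl esters), used as a single pseudo-individual to check the
# group-trait identities
table1_means <- function() {
  tibble::tibble(
    id = "pseudo",
    `C14:0` = 1.58, `C16:0` = 23.79, `C18:0` = 20.23, `C20:0` = 0.38,
    `C22:0` = 0.13, `C24:0` = 0.36,
    `C14:1 cis-9` = 0.41, `C16:1 cis-9` = 2.08, `C18:1 cis-9` = 31.98,
    `C20:1 cis-11` = 0.26,
    `C18:2 n-6` = 12.93, `C18:2 t-9c-11` = 0.42, `C18:2 t-12c-10` = 0.16,
    `C18:3 n-6` = 0.41, `C18:3 n-3` = 0.68, `C20:2 n-6` = 0.17,
    `C20:3 n-3` = 2.75, `C20:4 n-6` = 0.03, `C20:5 n-3` = 0.32,
    `C22:5 n-3` = 0.73, `C22:6 n-3` = 0.20)
}

# small genotype container built by hand
tiny_geno <- function(dosage, chrom = NULL, bp = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  geno_matrix(dosage, tibble::tibble(
    snp_id = paste0("s", seq_len(m)),
    chrom = chrom %||% rep(1L, m),
    bp = bp %||% seq(1000L, by = 1000L, length.out = m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# phenotype tibble from bare vectors (ids default to genotype row order)
adj_tbl <- function(ids, y) {
  out <- tibble::tibble(id = ids, y_adj = y)
  class(out) <- c("adjusted_phenotype", class(out))
  out
}

# simulate genotypes + single calibrated trait, returning all the pieces
sim_case <- function(n = 300, chrom = 2, m_per = 150, n_qtl = 5, h2 = 0.5,
                     rho = 0.9, seed = 1, ...) {
  cfg <- sim_config(n_individuals = n, n_chromosomes = chrom,
                    snps_per_chrom = m_per, n_qtl = n_qtl, target_h2 = h2,
                    ld_decay_rho = rho, seed = seed, ...)
  g <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(g, cfg)
  list(cfg = cfg, geno = g, traits = sim$traits, truth = sim$truth,
       adj = adjust_phenotypes(sim$traits, "y"))
}
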