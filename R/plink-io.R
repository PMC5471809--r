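#' Read a PLINK bed/bim/fam file set
#'
#' Decodes the PLINK 1 binary genotype format (magic bytes `0x6c 0x1b`,
#' third byte `0x01` for SNP-major order). Each marker occupies
#' `ceiling(n/4)` bytes; each byte packs four individuals, two bits each,
#' lowest-order pair first. Two-bit codes: `00` homozygous A1 (dosage 2),
#' `10` heterozygous (1), `11` homozygous A2 (0), `01` missing (`NA`).
#'
#' @param prefix Path prefix; `prefix.bed`, `prefix.bim` and `prefix.fam`
#'   must exist.
#' @return A [geno_matrix()]; dosages count A1 alleles.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_individuals = 10, n_chromosomes = 1, snps_per_chrom = 5)
#' sim <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
#' d <- tempfile(); dir.create(d)
#' write_fixture_set(simulate_genotypes(cfg), sim$traits, d)
#' g <- read_plink(file.path(d, "sim"))
#' }
#' @export
read_plink <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  bim_path <- paste0(prefix, ".bim")
  fam_path <- paste0(prefix, ".fam")
  for (f in c(bed_path, bim_path, fam_path))
    if (!file.exists(f)) stop("missing PLINK file: ", f, call. = FALSE)

  bim <- utils::read.table(bim_path, header = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "bp", "a1", "a2"),
                           colClasses = c("integer", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(fam_path, header = FALSE, colClasses = "character")
  n <- nrow(fam)
  m <- nrow(bim)

  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("format error: bad PLINK bed magic bytes", call. = FALSE)
  if (raw[3] != as.raw(0x01))
    stop("format error: only SNP-major bed files are supported", call. = FALSE)
  bytes_per_snp <- ceiling(n / 4)
  if (length(raw) - 3L != bytes_per_snp * m)
    stop("format error: bed payload is ", length(raw) - 3L,
         " bytes, expected ", bytes_per_snp * m, call. = FALSE)

  # decode per 2-bit code: 0 -> 2, 1 -> NA, 2 -> 1, 3 -> 0 (A1 dosage)
  lookup <- c(2L, NA_integer_, 1L, 0L)
  payload <- as.integer(raw[-(1:3)])
  codes <- matrix(0L, nrow = 4L * bytes_per_snp, ncol = m)
  block <- matrix(payload, nrow = bytes_per_snp, ncol = m)
  for (shift in 0:3) {
    codes[seq.int(shift + 1L, by = 4L, length.out = bytes_per_snp), ] <-
      block %% 4L
    block <- block %/% 4L
  }
  dosage <- matrix(lookup[codes[seq_len(n), , drop = FALSE] + 1L], nrow = n)
  rownames(dosage) <- fam[[2]]

  geno_matrix(dosage, tibble::tibble(
    snp_id = bim$snp_id, chrom = bim$chrom, bp = bim$bp,
    a1 = bim$a1, a2 = bim$a2))
}

#' Write a PLINK bed/bim/fam file set
#'
#' Inverse of [read_plink()]; emits a SNP-major PLINK 1 binary triplet.
#'
#' @param geno A [geno_matrix()].
#' @param prefix Output path prefix.
#' @return Invisibly, the prefix.
#' @export
write_plink <- function(geno, prefix) {
  stopifnot(inherits(geno, "geno_matrix"))
  n <- nrow(geno$dosage)
  m <- ncol(geno$dosage)
  # dosage -> 2-bit code: 2 -> 0, NA -> 1, 1 -> 2, 0 -> 3
  code <- matrix(3L, n, m)
  code[geno$dosage == 1L] <- 2L
  code[geno$dosage == 2L] <- 0L
  code[is.na(geno$dosage)] <- 1L
  bytes_per_snp <- ceiling(n / 4)
  padded <- matrix(0L, 4L * bytes_per_snp, m)
  padded[seq_len(n), ] <- code
  weights <- c(1L, 4L, 16L, 64L)
  byte_mat <- matrix(0L, bytes_per_snp, m)
  for (shift in 0:3) {
    byte_mat <- byte_mat +
      weights[shift + 1L] *
      padded[seq.int(shift + 1L, by = 4L, length.out = bytes_per_snp), ,
             drop = FALSE]
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(byte_mat), con)

  map <- geno$map
  utils::write.table(
    data.frame(map$chrom, map$snp_id, 0, map$bp, map$a1, map$a2),
    paste0(prefix, ".bim"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  ids <- geno_ids(geno)
  utils::write.table(
    data.frame(ids, ids, 0, 0, 0, -9),
    paste0(prefix, ".fam"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Write a genotype + phenotype fixture set
#'
#' Emits PLINK bed/bim/fam under `dir/sim.*` plus a tab-delimited
#' phenotype/covariate table `dir/pheno.tsv` (header row, `id` column
#' matching the fam file). Round-trips losslessly through [read_plink()].
#'
#' @param geno A [geno_matrix()].
#' @param traits Phenotype tibble with an `id` column, as produced by
#'   [simulate_phenotypes()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
write_fixture_set <- function(geno, traits, dir) {
  stopifnot(inherits(geno, "geno_matrix"), "id" %in% names(traits))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0)
    stop("filesystem error: directory not writable: ", dir, call. = FALSE)
  prefix <- file.path(dir, "sim")
  write_plink(geno, prefix)
  pheno_path <- file.path(dir, "pheno.tsv")
  utils::write.table(traits, pheno_path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(list(bed = paste0(prefix, ".bed"), bim = paste0(prefix, ".bim"),
                 fam = paste0(prefix, ".fam"), pheno = pheno_path))
}
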