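#' Genotype container
#'
#' A light S3 container pairing an individuals-by-markers dosage matrix with
#' its marker map. Dosages count copies of the A1 allele (0, 1, 2) with `NA`
#' for missing calls; this is the `Z` matrix of the marker-effect and
#' animal models used throughout the package.
#'
#' @param dosage Integer matrix, individuals x markers, entries in
#'   `{0, 1, 2, NA}`. Row names are individual IDs (generated if absent).
#' @param map Data frame with one row per marker: `snp_id`, `chrom`
#'   (autosome number), `bp` (1-based physical position), and allele columns
#'   `a1`, `a2` (filled with `"A"`/`"B"` if absent).
#'
#' @return An object of class `geno_matrix` with elements `dosage` and
#'   `map` (a tibble).
#' @examples
#' g <- geno_matrix(matrix(c(0L, 1L, 2L, 1L), 2, 2),
#'                  data.frame(snp_id = c("s1", "s2"), chrom = 1, bp = c(100, 200)))
#' dim(g)
#' @export
geno_matrix <- function(dosage, map) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (!all(dosage %in% c(0L, 1L, 2L, NA)))
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  map <- tibble::as_tibble(map)
  if (!all(c("snp_id", "chrom", "bp") %in% names(map)))
    stop("map needs columns snp_id, chrom, bp", call. = FALSE)
  if (nrow(map) != ncol(dosage))
    stop("map rows must match dosage columns", call. = FALSE)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("ind", seq_len(nrow(dosage)))
  colnames(dosage) <- map$snp_id
  if (!"a1" %in% names(map)) map$a1 <- "A"
  if (!"a2" %in% names(map)) map$a2 <- "B"
  map$chrom <- as.integer(map$chrom)
  map$bp <- as.integer(map$bp)
  structure(list(dosage = dosage, map = map), class = "geno_matrix")
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' @export
print.geno_matrix <- function(x, ...) {
  n_miss <- sum(is.na(x$dosage))
  cat("<geno_matrix> ", nrow(x$dosage), " individuals x ", ncol(x$dosage),
      " SNPs on ", length(unique(x$map$chrom)), " chromosome(s)",
      if (n_miss > 0) paste0(", ", n_miss, " missing calls"), "\n", sep = "")
  invisible(x)
}

#' Subset a genotype container
#'
#' @param x A [geno_matrix()].
#' @param i Individual index (rows), any matrix-style index.
#' @param j Marker index (columns).
#' @param ... Unused.
#' @return A `geno_matrix` restricted to the selected individuals/markers.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  geno_matrix(x$dosage[i, j, drop = FALSE], x$map[j, , drop = FALSE])
}

#' Individual IDs of a genotype container
#' @param geno A [geno_matrix()].
#' @return Character vector of individual IDs.
#' @export
geno_ids <- function(geno) rownames(geno$dosage)

#' Mean-impute and centre a dosage matrix
#'
#' Missing dosages are replaced by twice the sample allele frequency
#' (the column mean of observed calls) and every column is centred by the
#' same quantity, the coding used for both the relationship matrix and the
#' regression models.
#'
#' @param geno A [geno_matrix()].
#' @return Numeric matrix `W = Z - 2p` with no missing values, plus
#'   attribute `p` (per-marker allele frequency).
#' @export
center_dosage <- function(geno) {
  p <- allele_freq(geno)$p
  W <- sweep(ifelse(is.na(geno$dosage), rep(2 * p, each = nrow(geno$dosage)),
                    geno$dosage),
             2, 2 * p)
  attr(W, "p") <- p
  W
}
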