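#' Sample-by-site genotype dosage matrix
#'
#' The central container for all population-genetic and association
#' computations: an `n_samples x n_sites` integer matrix of alternate-allele
#' dosages (0, 1, 2 or `NA` for missing) plus per-site records (chromosome,
#' 1-based position, ref/alt alleles, quality) and sample identifiers.
#'
#' @param dosage integer matrix, samples in rows, sites in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param sites data.frame with columns `chrom`, `pos` (1-based, strictly
#'   increasing within each chromosome), `ref`, `alt`, `qual`.
#' @param samples character vector of sample ids, one per dosage row.
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, sites, samples) {
  dosage <- as.matrix(dosage)
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt", "qual") %in% names(sites)),
            nrow(sites) == ncol(dosage),
            length(samples) == nrow(dosage))
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) stop("dosage entries must be 0, 1, 2 or NA")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("site positions must be strictly increasing within chromosome ", ch)
  }
  rownames(dosage) <- samples
  structure(list(dosage = dosage, sites = sites, samples = as.character(samples)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d sites (%d chromosome(s), %.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$sites$chrom)),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Keep a subset of sites of a geno_matrix
#'
#' @param g a [geno_matrix].
#' @param idx integer or logical index over sites (columns).
#' @return a [geno_matrix] restricted to those sites.
#' @export
subset_sites <- function(g, idx) {
  stopifnot(inherits(g, "geno_matrix"))
  geno_matrix(g$dosage[, idx, drop = FALSE], g$sites[idx, , drop = FALSE],
              g$samples)
}

#' Per-site minor allele frequency
#'
#' Computed from non-missing dosages; `NaN` for all-missing sites.
#'
#' @param g a [geno_matrix].
#' @return numeric vector, one MAF per site.
#' @export
site_maf <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  p <- colMeans(g$dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Per-site fraction of missing genotypes
#' @param g a [geno_matrix].
#' @return numeric vector in `[0, 1]`, one value per site.
#' @export
site_missing <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  colMeans(is.na(g$dosage))
}
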