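#' Exact test for Hardy-Weinberg equilibrium
#'
#' The standard exact conditional test: given the observed allele counts,
#' the p-value is the total probability of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#' Probabilities are computed directly from log-factorials and normalised,
#' so the test is stable for any sample size used here.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, sum >= 1).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotype required")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  rare <- min(nA, na)
  if (rare == 0L) return(1)
  # heterozygote counts compatible with the allele counts (parity of rare)
  h <- seq.int(rare %% 2L, rare, by = 2L)
  logp <- h * log(2) + lgamma(n + 1) -
    lgamma((rare - h) / 2 + 1) - lgamma(h + 1) -
    lgamma(n - (rare + h) / 2 + 1) +
    lgamma(rare + 1) + lgamma(2L * n - rare + 1) - lgamma(2L * n + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, h)]
  sum(p[p <= obs * (1 + 1e-12)])
}

#' Filter variant sites on quality, missingness, Hardy-Weinberg and MAF
#'
#' Sites are tested in a fixed order -- quality, missingness, Hardy-Weinberg,
#' MAF -- and the number removed by each rule is reported, so filter reports
#' are reproducible. A site is kept iff QUAL >= `min_q`, its missing fraction
#' is <= `max_missing`, the exact HWE p-value exceeds `hwe_p`, and (when
#' `maf` is given) its minor allele frequency is >= `maf`.
#'
#' @param g a [geno_matrix].
#' @param min_q minimum QUAL (sites with missing QUAL fail this rule).
#' @param hwe_p sites with exact HWE p-value <= this are removed.
#' @param max_missing maximum tolerated fraction of missing genotypes.
#' @param maf optional minor-allele-frequency floor.
#' @return list with `geno` (the filtered [geno_matrix]) and `counts`
#'   (named vector of sites removed per rule, in application order, plus
#'   `kept`).
#' @export
filter_variants <- function(g, min_q = 30, hwe_p = 1e-4, max_missing = 0.20,
                            maf = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  if (ncol(g$dosage) == 0L) stop("empty genotype matrix")
  keep <- rep(TRUE, ncol(g$dosage))
  qual_ok <- !is.na(g$sites$qual) & g$sites$qual >= min_q
  n_q <- sum(keep & !qual_ok); keep <- keep & qual_ok
  miss_ok <- site_missing(g) <= max_missing
  n_miss <- sum(keep & !miss_ok); keep <- keep & miss_ok
  hwe_ok <- rep(TRUE, ncol(g$dosage))
  for (j in which(keep)) {
    d <- g$dosage[, j]
    d <- d[!is.na(d)]
    pval <- hwe_exact_test(sum(d == 0L), sum(d == 1L), sum(d == 2L))
    hwe_ok[j] <- pval > hwe_p
  }
  n_hwe <- sum(keep & !hwe_ok); keep <- keep & hwe_ok
  n_maf <- 0L
  if (!is.null(maf)) {
    maf_ok <- !is.na(site_maf(g)) & site_maf(g) >= maf
    n_maf <- sum(keep & !maf_ok); keep <- keep & maf_ok
  }
  list(geno = subset_sites(g, keep),
       counts = c(qual = n_q, missing = n_miss, hwe = n_hwe, maf = n_maf,
                  kept = sum(keep)))
}
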