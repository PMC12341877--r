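# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the whole suite stays fast.

# tiny genotype matrix with fixed content
toy_geno <- function(dosage, pos = NULL, chrom = "chr1", qual = 60) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  geno_matrix(dosage,
              data.frame(chrom = chrom, pos = pos,
                         ref = rep("A", m), alt = rep("T", m), qual = qual,
                         stringsAsFactors = FALSE),
              sprintf("s%02d", seq_len(nrow(dosage))))
}

random_geno <- function(n, m, miss = 0, seed = 1) {
  set.seed(seed)
  d <- matrix(sample(0:2, n * m, replace = TRUE, prob = c(0.45, 0.35, 0.2)),
              n, m)
  if (miss > 0) d[sample(length(d), round(miss * length(d)))] <- NA
  toy_geno(d, pos = sort(sample.int(1e6, m)))
}

# independent brute-force oracles -------------------------------------------

# per-site mean pairwise allele difference by explicit enumeration of copies
# (all ordered pairs via outer, halved)
oracle_pi_site <- function(d) {
  alleles <- unlist(lapply(d[!is.na(d)], function(x) c(rep(1L, x), rep(0L, 2L - x))))
  N <- length(alleles)
  if (N < 2) return(0)
  diffs <- sum(outer(alleles, alleles, "!=")) / 2
  diffs / choose(N, 2)
}

# Tajima's D from literal textbook constants
oracle_tajima_d <- function(theta_pi, S, n) {
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (theta_pi - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# exact HWE p by direct enumeration over all compatible heterozygote counts
oracle_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  pr <- vapply(hs, function(h) {
    aa <- (nA - h) / 2; bb <- n - aa - h
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2) +
          lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n))
  }, numeric(1))
  obs <- pr[match(nAa, hs)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# join-candidate key for precision/recall bookkeeping
join_key <- function(d) paste(d$contig_a, d$end_a, d$contig_b, d$end_b)

# non-N sequence bytes in a contig set
non_n_bytes <- function(contigs) sum(nchar(gsub("N", "", contigs, fixed = TRUE)))
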