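#' Describe a demographic scenario for the Wright-Fisher simulator
#'
#' Bundles everything [simulate_wright_fisher()] needs to know about the
#' population: the effective-size trajectory, the per-bp recombination rate,
#' the number of diploid individuals to sample at the end, and the seed.
#'
#' @param ne_epochs data.frame with columns `ne` (diploid effective size) and
#'   `gens` (number of generations spent at that size), ordered from the most
#'   ancient epoch to the present. A single row gives a constant-size
#'   population.
#' @param recomb_rate_per_bp recombination rate in Morgans per bp (e.g. `1e-8`
#'   for 1 cM/Mb).
#' @param sample_size number of diploid individuals sampled (without
#'   replacement) from the final generation. Must not exceed the final `ne`.
#' @param seed integer seed; every random draw in the simulation derives from
#'   it.
#' @return an object of class `sim_pop_truth`.
#' @export
sim_pop_truth <- function(ne_epochs, recomb_rate_per_bp = 1e-8,
                          sample_size = 40, seed = 1L) {
  ne_epochs <- as.data.frame(ne_epochs)
  stopifnot(all(c("ne", "gens") %in% names(ne_epochs)), nrow(ne_epochs) >= 1)
  if (any(ne_epochs$ne < 2)) stop("every epoch must have ne >= 2")
  if (any(ne_epochs$gens < 0)) stop("epoch durations must be >= 0")
  if (recomb_rate_per_bp < 0) stop("recomb_rate_per_bp must be >= 0")
  structure(
    list(ne_epochs = ne_epochs,
         recomb_rate_per_bp = recomb_rate_per_bp,
         infinite_sites = TRUE,
         sample_size = as.integer(sample_size),
         seed = as.integer(seed)),
    class = "sim_pop_truth")
}

#' @export
print.sim_pop_truth <- function(x, ...) {
  cat("Wright-Fisher scenario:", nrow(x$ne_epochs), "epoch(s), Ne",
      paste(x$ne_epochs$ne, collapse = " -> "),
      sprintf("| c = %g M/bp | n = %d | seed = %d\n",
              x$recomb_rate_per_bp, x$sample_size, x$seed))
  invisible(x)
}

# One gamete from a diploid parent. hapA/hapB are integer vectors of mutated
# positions (unsorted); n_xo crossovers at uniform positions, random phase.
.wf_gamete <- function(hapA, hapB, n_xo, seq_len) {
  if (n_xo == 0L) {
    if (stats::runif(1) < 0.5) return(hapA) else return(hapB)
  }
  bp <- sort.int(stats::runif(n_xo, min = 0, max = seq_len))
  phase <- if (stats::runif(1) < 0.5) 0L else 1L
  keepA <- findInterval(hapA, bp) %% 2L == phase
  keepB <- findInterval(hapB, bp) %% 2L != phase
  c(hapA[keepA], hapB[keepB])
}

# Generation loop. state: list of 2N integer vectors (haps of individual i at
# 2i-1, 2i). sizes: diploid N for each generation to run. Mutation is
# infinite-sites on integer coordinates: candidate positions colliding with a
# live (segregating or recently arisen) position are redrawn.
.wf_run <- function(state, sizes, u_gamete, c_per_bp, seq_len) {
  used <- unique(unlist(state, use.names = FALSE))
  xo_mean <- seq_len * c_per_bp
  for (g in seq_along(sizes)) {
    n_new <- sizes[g]
    n_old <- length(state) %/% 2L
    parents <- integer(2L * n_new)
    parents[seq(1L, 2L * n_new, by = 2L)] <- sample.int(n_old, n_new, TRUE)
    parents[seq(2L, 2L * n_new, by = 2L)] <- sample.int(n_old, n_new, TRUE)
    n_xo <- stats::rpois(2L * n_new, xo_mean)
    nxt <- vector("list", 2L * n_new)
    for (j in seq_len(2L * n_new)) {
      p <- parents[j]
      nxt[[j]] <- .wf_gamete(state[[2L * p - 1L]], state[[2L * p]],
                             n_xo[j], seq_len)
    }
    m <- stats::rpois(1L, 2 * n_new * u_gamete)
    if (m > 0L) {
      pos <- integer(0)
      while (length(pos) < m) {
        cand <- sample.int(seq_len, m - length(pos), replace = TRUE)
        cand <- setdiff(unique(cand), c(used, pos))
        pos <- c(pos, cand)
      }
      who <- sample.int(2L * n_new, m, replace = TRUE)
      for (k in seq_len(m)) nxt[[who[k]]] <- c(nxt[[who[k]]], pos[k])
      used <- c(used, pos)
    }
    state <- nxt
    # periodically drop lost positions so the live set stays small
    if (g %% 64L == 0L) used <- unique(unlist(state, use.names = FALSE))
  }
  state
}

#' Forward-in-time diploid Wright-Fisher simulation with recombination
#'
#' Simulates a diploid population forward in time under the demographic
#' scenario in `pop`: random union of gametes each generation, crossover
#' counts Poisson(`seq_len` x c) with uniform breakpoints, and infinite-sites
#' mutation on integer coordinates (positions colliding with a segregating
#' site are redrawn). The run starts from a mutation-free population, is
#' burnt in for `burn_in` x Ne generations at the oldest epoch size, then
#' steps through the remaining epochs. At the end, `sample_size` individuals
#' are drawn without replacement and sites monomorphic in the sample are
#' dropped.
#'
#' The per-gamete mutation rate is calibrated from `n_sites_target` via
#' Watterson's formula, so the realised number of segregating sites in the
#' sample fluctuates around the target.
#'
#' @param pop a [sim_pop_truth()] scenario.
#' @param n_sites_target desired number of segregating sites in the sample.
#' @param seq_len simulated sequence length in bp.
#' @param burn_in burn-in length in multiples of the oldest-epoch Ne.
#' @param vcf optional path; if given, the sample is also written as a plain
#'   VCF 4.2 via [write_vcf()].
#' @param chrom chromosome name used for the site records.
#' @return a [geno_matrix] (samples x sites dosage matrix plus site records).
#' @export
simulate_wright_fisher <- function(pop, n_sites_target = 1000, seq_len = 1e6,
                                   burn_in = 6, vcf = NULL, chrom = "chr1") {
  stopifnot(inherits(pop, "sim_pop_truth"))
  if (n_sites_target < 1) stop("n_sites_target must be >= 1")
  set.seed(pop$seed)
  ep <- pop$ne_epochs
  n_samp <- pop$sample_size
  if (n_samp > ep$ne[nrow(ep)])
    stop("sample_size exceeds the final-epoch population size")
  # Watterson calibration: E[S] = 4 Ne u_gamete * H(2n-1) with Ne of the
  # final epoch (the one the sample coalesces through most recently).
  harm <- sum(1 / seq_len(2L * n_samp - 1L))
  u_gamete <- n_sites_target / (4 * ep$ne[nrow(ep)] * harm)

  sizes <- c(rep.int(ep$ne[1L], max(1L, round(burn_in * ep$ne[1L]))),
             rep.int(ep$ne, ep$gens))
  state <- rep(list(integer(0)), 2L * sizes[1L])
  state <- .wf_run(state, sizes, u_gamete, pop$recomb_rate_per_bp, seq_len)

  idx <- sample.int(sizes[length(sizes)], n_samp)
  haps <- state[c(2L * idx - 1L, 2L * idx)]
  .wf_sample_to_geno(haps, n_samp, seq_len, chrom = chrom,
                     sample_ids = sprintf("ind%03d", seq_len(n_samp)),
                     vcf = vcf)
}

# Convert 2n sampled haplotypes (list of position vectors; individual i owns
# haps i and n+i) into a geno_matrix, dropping sites monomorphic in the sample.
.wf_sample_to_geno <- function(haps, n_samp, seq_len, chrom, sample_ids,
                               vcf = NULL) {
  all_pos <- unlist(haps, use.names = FALSE)
  tab <- table(all_pos)
  keep <- sort.int(as.integer(names(tab))[tab > 0L & tab < 2L * n_samp])
  dos <- matrix(0L, nrow = n_samp, ncol = length(keep))
  if (length(keep)) {
    for (i in seq_len(n_samp)) {
      h <- c(haps[[i]], haps[[n_samp + i]])
      cnt <- tabulate(match(h, keep), nbins = length(keep))
      dos[i, ] <- cnt
    }
  }
  ref_alt <- .sim_ref_alt(length(keep))
  g <- geno_matrix(
    dosage = dos,
    sites = data.frame(chrom = rep(chrom, length(keep)), pos = keep,
                       ref = ref_alt$ref, alt = ref_alt$alt,
                       qual = rep(60, length(keep)),
                       stringsAsFactors = FALSE),
    samples = sample_ids)
  if (!is.null(vcf)) write_vcf(g, vcf)
  g
}

# deterministic ref/alt labels for simulated biallelic SNPs
.sim_ref_alt <- function(n) {
  bases <- c("A", "C", "G", "T")
  list(ref = bases[(seq_len(n) - 1L) %% 4L + 1L],
       alt = bases[seq_len(n) %% 4L + 1L])
}

#' Simulate a structured sample: one ancestral population split in two
#'
#' Runs a single Wright-Fisher population to mutation-drift equilibrium,
#' copies it into two descendant populations that evolve independently for
#' `split_gens` generations (accumulating drift divergence), then samples
#' half the individuals from each side. Useful for exercising population
#' structure in PCA and mixed-model association.
#'
#' @param pop a [sim_pop_truth()] scenario; its final-epoch `ne` is the size
#'   of each descendant population and `sample_size` the total sample (half
#'   per population).
#' @param split_gens generations of independent drift after the split.
#' @param n_chrom number of independent chromosomes: the whole
#'   burn-in/split/sampling process is replicated per chromosome and sites
#'   are concatenated, so population labels are shared but genealogies are
#'   independent across chromosomes (as across real chromosomes).
#' @inheritParams simulate_wright_fisher
#' @return a [geno_matrix] with an extra `population` attribute (factor of
#'   length `sample_size`).
#' @export
simulate_structured_pop <- function(pop, split_gens = 50, n_sites_target = 1000,
                                    seq_len = 1e6, burn_in = 6, n_chrom = 1L) {
  stopifnot(inherits(pop, "sim_pop_truth"))
  if (pop$sample_size %% 2L != 0L)
    stop("sample_size must be even (half per population)")
  set.seed(pop$seed)
  ne <- pop$ne_epochs$ne[nrow(pop$ne_epochs)]
  n_half <- pop$sample_size %/% 2L
  if (n_half > ne) stop("each population must hold sample_size/2 individuals")
  n_tot <- pop$sample_size
  harm <- sum(1 / seq_len(2L * n_tot - 1L))
  u_gamete <- (n_sites_target / n_chrom) / (4 * ne * harm)
  c_bp <- pop$recomb_rate_per_bp
  per_chrom <- vector("list", n_chrom)
  for (k in seq_len(n_chrom)) {
    anc <- .wf_run(rep(list(integer(0)), 2L * ne),
                   rep.int(ne, max(1L, round(burn_in * ne))),
                   u_gamete, c_bp, seq_len)
    split_sizes <- rep.int(ne, max(1L, split_gens))
    pop1 <- .wf_run(anc, split_sizes, u_gamete, c_bp, seq_len)
    pop2 <- .wf_run(anc, split_sizes, u_gamete, c_bp, seq_len)
    i1 <- sample.int(ne, n_half)
    i2 <- sample.int(ne, n_half)
    haps <- c(pop1[2L * i1 - 1L], pop2[2L * i2 - 1L],
              pop1[2L * i1], pop2[2L * i2])
    per_chrom[[k]] <- .wf_sample_to_geno(
      haps, n_tot, seq_len, chrom = sprintf("chr%d", k),
      sample_ids = sprintf("ind%03d", seq_len(n_tot)))
  }
  g <- geno_matrix(
    do.call(cbind, lapply(per_chrom, function(x) x$dosage)),
    do.call(rbind, lapply(per_chrom, function(x) x$sites)),
    per_chrom[[1L]]$samples)
  attr(g, "population") <- factor(rep(c("pop1", "pop2"), each = n_half))
  g
}
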