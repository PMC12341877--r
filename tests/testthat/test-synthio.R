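test_that("simulate_genome tiles chromosomes and is reproducible", {
  gen <- simulate_genome(n_chrom = 1, chrom_len = 10000, n_contigs = 5,
                        chimera_rate = 0, seed = 7)
  org <- gen$truth$origins
  org <- org[order(org$start), ]
  expect_equal(org$start, c(0, head(org$end, -1)))   # tiling
  expect_equal(org$end[nrow(org)], 10000)
  # reconstruction: concatenating oriented origins reproduces the chromosome
  rebuilt <- paste(vapply(seq_len(nrow(org)), function(i) {
    s <- gen$contigs[[org$contig[i]]]
    if (org$orientation[i] == "-") revcomp(s) else s
  }, character(1)), collapse = "")
  expect_identical(rebuilt, unname(gen$truth$chrom_seq[["chr01"]]))
  gen2 <- simulate_genome(n_chrom = 1, chrom_len = 10000, n_contigs = 5,
                         chimera_rate = 0, seed = 7)
  expect_identical(gen$contigs, gen2$contigs)        # determinism
})

test_that("chimeric contigs always span two distinct chromosomes", {
  gen <- simulate_genome(n_chrom = 2, chrom_len = 50000, n_contigs = 10,
                        chimera_rate = 0.2, n_run_rate = 1, seed = 9)
  tj <- gen$truth$chimera_junctions
  expect_equal(nrow(tj), 2L)
  expect_true(all(tj$left_chrom != tj$right_chrom))
  for (i in seq_len(nrow(tj))) {
    org <- gen$truth$origins[gen$truth$origins$contig == tj$contig[i], ]
    expect_gte(nrow(org), 2L)
    expect_equal(length(unique(org$chrom)), 2L)
    # junction offset lies inside the contig
    expect_gt(tj$junction[i], 0)
    expect_lt(tj$junction[i], nchar(gen$contigs[[tj$contig[i]]]))
    # the junction N-run is present in the sequence
    runs <- contig_n_runs(gen$contigs[[tj$contig[i]]])
    expect_true(any(runs[, "start"] == tj$n_start[i] &
                      runs[, "end"] == tj$n_end[i]))
  }
})

test_that("simulate_genome rejects over-fragmentation", {
  expect_error(simulate_genome(1, 1000, 100, seed = 1), "capacity")
})

test_that("linkage maps: noise-free cM order equals physical order; row counts", {
  gen <- simulate_genome(n_chrom = 2, chrom_len = 50000, n_contigs = 8,
                        chimera_rate = 0, seed = 5)
  lm <- simulate_linkage_maps(gen, n_parents = 4, markers_per_lg = 10,
                             noise_sd = 0, seed = 6)
  expect_equal(nrow(lm$maps), 2 * 10 * 4)
  for (p in unique(lm$maps$parent)) for (lg in 1:2) {
    ml <- lm$maps[lm$maps$parent == p & lm$maps$linkage_group == lg, ]
    tr <- lm$marker_truth[match(ml$marker_id, lm$marker_truth$marker_id), ]
    expect_equal(order(ml$cM), order(tr$pos0))
  }
  expect_error(simulate_linkage_maps(gen, noise_sd = -1), "noise_sd")
  # every marker has a physical placement within its contig
  lens <- nchar(gen$contigs)
  expect_true(all(lm$placements$pos0 < lens[lm$placements$contig_id]))
})

test_that("planted chimeras receive markers on both sides at high density", {
  gen <- simulate_genome(n_chrom = 2, chrom_len = 200000, n_contigs = 8,
                        chimera_rate = 0.25, seed = 15, chimera_min_frag = 20000)
  lm <- simulate_linkage_maps(gen, n_parents = 1, markers_per_lg = 50,
                             noise_sd = 0, seed = 16)
  tj <- gen$truth$chimera_junctions
  for (i in seq_len(nrow(tj))) {
    pl <- lm$placements[lm$placements$contig_id == tj$contig[i], ]
    expect_gte(sum(pl$pos0 < tj$junction[i]), 2)
    expect_gte(sum(pl$pos0 >= tj$junction[i]), 2)
  }
})

test_that("transcript generator respects junction_fraction and bounds", {
  gen <- simulate_genome(n_chrom = 2, chrom_len = 100000, n_contigs = 12,
                        chimera_rate = 0, seed = 25)
  # junction_fraction 0: every transcript on exactly one contig
  tx0 <- simulate_transcripts(gen, n_transcripts = 12, junction_fraction = 0,
                             seed = 26)
  per_tx <- tapply(tx0$paf$tname, tx0$paf$qname, function(x) length(unique(x)))
  expect_true(all(per_tx == 1L))
  # junction_fraction 1 with one transcript per pair: as many truth pairs
  tx1 <- simulate_transcripts(gen, n_transcripts = 8, junction_fraction = 1,
                             seed = 27, transcripts_per_pair = 1)
  expect_equal(nrow(tx1$truth_pairs), 8L)
  # block coordinates always within contig bounds
  for (tx in list(tx0, tx1)) {
    expect_true(all(tx$paf$tstart >= 0))
    expect_true(all(tx$paf$tend <= tx$paf$tlen))
    expect_true(all(tx$paf$qend <= tx$paf$qlen))
  }
})

test_that("Wright-Fisher output is reproducible and respects the sample", {
  pop <- sim_pop_truth(data.frame(ne = 30, gens = 10), sample_size = 12,
                      seed = 99)
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  g1 <- simulate_wright_fisher(pop, n_sites_target = 120, seq_len = 2e5,
                              vcf = f1)
  g2 <- simulate_wright_fisher(pop, n_sites_target = 120, seq_len = 2e5,
                              vcf = f2)
  expect_identical(readLines(f1), readLines(f2))     # byte-identical VCF
  expect_equal(nrow(g1$dosage), 12L)
  maf <- site_maf(g1)
  expect_true(all(maf > 0))                          # monomorphic dropped
  expect_true(!is.unsorted(g1$sites$pos, strictly = TRUE))
})

test_that("WF drift variance per generation is about p(1-p)/2Ne", {
  # one-generation allele-frequency change across many replicate loci
  set.seed(42)
  ne <- 50
  p0 <- 0.4
  reps <- 3000
  p1 <- rbinom(reps, 2 * ne, p0) / (2 * ne)
  expect_equal(var(p1), p0 * (1 - p0) / (2 * ne), tolerance = 0.08)
  # and the simulator's realised drift: frequency changes between close
  # generations have mean ~0 (no systematic force)
  pop <- sim_pop_truth(data.frame(ne = 40, gens = 5), sample_size = 40,
                      seed = 13)
  g <- simulate_wright_fisher(pop, n_sites_target = 200, seq_len = 2e5)
  f <- colMeans(g$dosage) / 2
  expect_true(mean(f) > 0.02 && mean(f) < 0.5)
})

test_that("no recombination means no decay of LD with distance", {
  pop0 <- sim_pop_truth(data.frame(ne = 40, gens = 5), recomb_rate_per_bp = 0,
                       sample_size = 40, seed = 31)
  g0 <- simulate_wright_fisher(pop0, n_sites_target = 300, seq_len = 1e6)
  pr0 <- pairwise_r2(g0, max_dist = 1e6, maf = 0.1)
  near0 <- mean(pr0$r2[pr0$dist < 2e5])
  far0 <- mean(pr0$r2[pr0$dist > 8e5])
  # c = 0: distance carries no information, near and far r2 agree
  expect_lt(abs(near0 - far0), 0.12)
  # with strong recombination the same comparison shows clear decay
  pop1 <- sim_pop_truth(data.frame(ne = 40, gens = 5),
                       recomb_rate_per_bp = 1e-7, sample_size = 40, seed = 31)
  g1 <- simulate_wright_fisher(pop1, n_sites_target = 300, seq_len = 1e6)
  pr1 <- pairwise_r2(g1, max_dist = 1e6, maf = 0.1)
  expect_gt(mean(pr1$r2[pr1$dist < 2e5]) - mean(pr1$r2[pr1$dist > 8e5]), 0.1)
})

test_that("simulate_trait hits the target heritability and is reproducible", {
  g <- random_geno(400, 500, seed = 77)
  qtl <- data.frame(site = c(10L, 200L), effect = c(1, -0.7))
  y <- simulate_trait(g, qtl = qtl, h2 = 0.5, seed = 3)
  y2 <- simulate_trait(g, qtl = qtl, h2 = 0.5, seed = 3)
  expect_identical(y, y2)
  # realised h2: regress genetic value share via the known construction
  tr <- attr(y, "truth")
  expect_equal(tr$h2, 0.5)
  # empirical check: R2 of y on the QTL dosages is near the planted share
  r2 <- summary(stats::lm(y ~ g$dosage[, qtl$site]))$r.squared
  expect_equal(r2, 0.5, tolerance = 0.1)
  # null trait: no correlation with any SNP beyond chance
  y0 <- simulate_trait(g, qtl = NULL, h2 = 0, seed = 4)
  cors <- abs(cor(y0, g$dosage))
  expect_lt(mean(cors > 2 / sqrt(nrow(g$dosage))), 0.1)
  # h2 = 1 with no genetic variance is rejected
  expect_error(simulate_trait(g, qtl = NULL, h2 = 1, seed = 5), "h2 = 1")
})
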