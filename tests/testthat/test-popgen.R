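test_that("window pi, S and Tajima's D match the brute-force oracle", {
  set.seed(11)
  for (rep in 1:20) {
    g <- random_geno(10, 30, seed = 100 + rep)
    g$sites$pos <- sort(sample.int(9999, 30))
    ws <- window_stats(g, window = 10000)
    pi_o <- sum(apply(g$dosage, 2, oracle_pi_site))
    n_al <- 2 * colSums(!is.na(g$dosage))
    n_alt <- colSums(g$dosage, na.rm = TRUE)
    S_o <- sum(n_alt > 0 & n_alt < n_al)
    expect_equal(ws$pi, pi_o / 10000, tolerance = 1e-10)
    expect_equal(ws$S, S_o)
    D_o <- oracle_tajima_d(pi_o, S_o, 20L)
    expect_equal(ws$tajima_d, D_o, tolerance = 1e-10)
  }
})

test_that("one hand-computed window: pi for ref=2/alt=2 at n=4 alleles", {
  g <- toy_geno(matrix(c(0L, 2L), ncol = 1), pos = 5000L)
  ws <- window_stats(g, window = 10000)
  expect_equal(ws$pi, (8 / 12) / 10000, tolerance = 1e-12)
  expect_equal(ws$S, 1L)
  # S = 0: pi = 0, D missing
  g0 <- toy_geno(matrix(c(2L, 2L), ncol = 1), pos = 5000L)
  ws0 <- window_stats(g0, window = 10000)
  expect_equal(ws0$pi, 0)
  expect_true(is.na(ws0$tajima_d))
})

test_that("HWE exact test equals full enumeration for n <= 50", {
  for (n in c(5L, 17L, 40L, 50L)) {
    for (nAA in seq(0L, n, by = max(1L, n %/% 7L))) {
      for (nAa in seq(0L, n - nAA, by = max(1L, (n - nAA) %/% 5L + 1L))) {
        naa <- n - nAA - nAa
        expect_equal(hwe_exact_test(nAA, nAa, naa),
                     oracle_hwe(nAA, nAa, naa), tolerance = 1e-12,
                     info = sprintf("(%d,%d,%d)", nAA, nAa, naa))
      }
    }
  }
  expect_equal(hwe_exact_test(40, 0, 0), 1)
  expect_equal(hwe_exact_test(5, 10, 15), hwe_exact_test(15, 10, 5))
})

test_that("HWE exact p-values are valid (conservative) under equilibrium", {
  set.seed(77)
  n <- 40L
  p <- 0.35
  ps <- replicate(5000, {
    a <- rbinom(2 * n, 1, p)
    gt <- a[1:n] + a[(n + 1):(2 * n)]
    hwe_exact_test(sum(gt == 0), sum(gt == 1), sum(gt == 2))
  })
  # the exact test is discrete, hence super-uniform: P(p <= a) <= a holds
  # for every level (allowing Monte-Carlo slack), and p is never tiny in
  # the bulk of equilibrium samples
  for (a in c(0.001, 0.01, 0.05, 0.1, 0.25)) {
    mc <- 3 * sqrt(a * (1 - a) / length(ps))
    expect_lte(mean(ps <= a), a + mc)
  }
  expect_gt(mean(ps), 0.45)
})

test_that("filter_variants applies Q, missing, HWE, MAF rules in order", {
  d <- rbind(matrix(1L, 25, 3), matrix(0L, 15, 3))
  d[, 2] <- c(rep(0L, 25), rep(2L, 15))     # (25,0,15): gross HWE violation
  d[1:9, 3] <- NA                            # 22.5% missing
  g <- toy_geno(d, qual = c(29, 60, 60))
  out <- filter_variants(g, maf = NULL)
  expect_equal(unname(out$counts),
               c(1L, 1L, 1L, 0L, 0L))        # qual, missing, hwe, maf, kept
  expect_lt(hwe_exact_test(25, 0, 15), 1e-4)
  # boundary: Q = 30 passes
  g2 <- toy_geno(matrix(c(0L, 1L, 2L, 1L), 4, 1), qual = 30)
  expect_equal(unname(filter_variants(g2)$counts[["kept"]]), 1L)
  expect_error(filter_variants(subset_sites(g, integer(0))), "empty")
})

test_that("pairwise r2 equals direct Pearson squared, with invariances", {
  # hand case
  x <- c(0L, 1L, 2L, 0L); y <- c(0L, 1L, 2L, 2L)
  g <- toy_geno(cbind(x, y), pos = c(100L, 200L))
  expect_equal(pairwise_r2(g)$r2, cor(x, y)^2, tolerance = 1e-12)
  # perfect correlation and perfect anti-correlation both give 1
  g1 <- toy_geno(cbind(x, x), pos = c(100L, 200L))
  expect_equal(pairwise_r2(g1)$r2, 1)
  g2 <- toy_geno(cbind(x, 2L - x), pos = c(100L, 200L))
  expect_equal(pairwise_r2(g2)$r2, 1)
  # random matrix vs direct oracle (pairwise complete)
  g3 <- random_geno(15, 40, miss = 0.1, seed = 202)
  pr <- pairwise_r2(g3, max_dist = 1e6)
  for (k in sample(nrow(pr), 50)) {
    xi <- g3$dosage[, pr$i[k]]; yj <- g3$dosage[, pr$j[k]]
    cc <- stats::complete.cases(xi, yj)
    expect_equal(pr$r2[k], cor(xi[cc], yj[cc])^2, tolerance = 1e-10)
  }
  # pairs with < 4 complete samples are skipped
  xm <- c(0L, 1L, 2L, NA, NA); ym <- c(NA, 1L, 2L, 0L, NA)
  gm <- toy_geno(cbind(xm, ym), pos = c(100L, 200L))
  expect_equal(nrow(pairwise_r2(gm)), 0L)
  # distance window respected
  g4 <- random_geno(10, 50, seed = 203)
  pr4 <- pairwise_r2(g4, max_dist = 5e4)
  expect_true(all(pr4$dist <= 5e4))
})

test_that("bin_ld and ld_extent interpolate as specified", {
  bins <- data.frame(lo = 0:3 * 1000, hi = 1:4 * 1000,
                     mid = 0:3 * 1000 + 500,
                     mean_r2 = c(0.5, 0.3, 0.2, 0.1), n_pairs = 10L)
  ext <- ld_extent(bins, threshold = 0.2)
  # first bin below 0.2 is the 4th (0.1 < 0.2; 0.2 is not < 0.2):
  # interpolate between mids 2500 (0.2) and 3500 (0.1) - exactly at 2500
  expect_equal(ext$extent, 2500)
  expect_false(ext$censored)
  bins2 <- bins; bins2$mean_r2 <- c(0.5, 0.3, 0.25, 0.1)
  expect_equal(ld_extent(bins2, 0.2)$extent,
               2500 + (0.25 - 0.2) / (0.25 - 0.1) * 1000)
  # all above threshold: censored at max distance
  bins3 <- bins; bins3$mean_r2 <- rep(0.5, 4)
  expect_true(ld_extent(bins3, 0.2)$censored)
  expect_equal(ld_extent(bins3, 0.2)$extent, 3500)
  # all below: first midpoint
  bins4 <- bins; bins4$mean_r2 <- rep(0.05, 4)
  expect_equal(ld_extent(bins4, 0.2)$extent, 500)
  # binning arithmetic
  pairs <- data.frame(dist = c(100, 900, 1500), r2 = c(0.4, 0.6, 0.2))
  b <- bin_ld(pairs, bin = 1000)
  expect_equal(b$mean_r2, c(0.5, 0.2))
  expect_equal(b$mid, c(500, 1500))
})

test_that("estimate_ne closed form and boundary handling", {
  bins <- data.frame(mid = 10000, mean_r2 = 0.25 + 1 / 40, n_pairs = 100L)
  ne <- estimate_ne(bins, c_rate = 1e-9, a = 2.2, n_ind = 40)
  # c = 1e-5, Ne = (1/(4e-5)) * (4 - 2.2) = 45,000; t = 1/(2e-5)
  expect_equal(ne$ne, 45000, tolerance = 1e-9)
  expect_equal(ne$t, 50000, tolerance = 1e-9)
  # adjusted r2 at the 1/a boundary is dropped
  bins2 <- data.frame(mid = 10000, mean_r2 = 1 / 2.2 + 1 / 40, n_pairs = 10L)
  ne2 <- estimate_ne(bins2, c_rate = 1e-9, a = 2.2, n_ind = 40)
  expect_equal(nrow(ne2), 0L)
  expect_equal(attr(ne2, "dropped"), 1L)
})

test_that("smooth_trajectory: constants pass through, outliers are removed", {
  pts <- data.frame(t = seq(100, 5000, length.out = 30), ne = 1000)
  tr <- smooth_trajectory(pts, window = 11)
  expect_equal(tr$ne_trend, rep(1000, nrow(tr)))
  # single outlier inside a window vanishes under the rolling median
  pts2 <- pts; pts2$ne[15] <- 1e6
  tr2 <- smooth_trajectory(pts2, window = 11)
  expect_true(all(abs(tr2$ne_trend - 1000) < 1))
  # median of a sorted 11-window is the 6th order statistic
  v <- sort(rnorm(11))
  expect_equal(zoo::rollmedian(v, 11), v[6])
})

test_that("ld_prune postcondition: no surviving close pair above threshold", {
  # duplicate adjacent columns: exactly one survives
  x <- c(0L, 1L, 2L, 0L, 1L, 2L, 1L, 0L)
  g <- toy_geno(cbind(x, x), pos = c(100L, 200L))
  expect_equal(ld_prune(g), 1L)
  # independent sites all survive
  set.seed(5)
  gi <- random_geno(60, 20, seed = 301)
  kept <- ld_prune(gi, window = 1e6, r2_max = 0.99)
  expect_equal(kept, seq_len(20))
  # random matrix: assert the postcondition directly
  gr <- random_geno(25, 60, seed = 302)
  kept2 <- ld_prune(gr, window = 1e5, r2_max = 0.2)
  gs <- subset_sites(gr, kept2)
  pr <- pairwise_r2(gs, max_dist = 1e5)
  expect_true(all(pr$r2 <= 0.2 + 1e-12))
})

test_that("genotype PCA separates two drifted populations", {
  pop <- sim_pop_truth(data.frame(ne = 80, gens = 1), sample_size = 40,
                      seed = 401)
  g <- simulate_structured_pop(pop, split_gens = 100, n_sites_target = 900,
                              seq_len = 5e5, burn_in = 5, n_chrom = 3)
  pc <- pca_genotypes(g, n_pc = 4)
  lab <- attr(g, "population")
  s1 <- pc$scores[lab == "pop1", 1]
  s2 <- pc$scores[lab == "pop2", 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))  # PC1 separates
  expect_true(all(diff(pc$percent) <= 1e-9))
  expect_lte(sum(pc$percent), 100 + 1e-9)
  # duplicated sample gets identical scores
  g2 <- geno_matrix(rbind(g$dosage, g$dosage[1, , drop = FALSE]),
                    g$sites, c(g$samples, "dup"))
  pc2 <- pca_genotypes(g2, n_pc = 2)
  expect_equal(pc2$scores["dup", ], pc2$scores[1, ], tolerance = 1e-8)
})
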