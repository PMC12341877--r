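test_that("filter_markers applies exclusions then the multi-LG rule", {
  maps <- data.frame(
    parent = c("pA", "pB", "pA", "pB", "pX", "pX"),
    linkage_group = c(1L, 2L, 1L, 1L, 8L, 3L),
    marker_id = c("m1", "m1", "m2", "m2", "m3", "m4"),
    cM = c(0, 0, 5, 5.2, 1, 2))
  out <- filter_markers(maps,
                        exclusions = data.frame(parent = "pX",
                                                linkage_group = 8L))
  # m1 spans LG1/LG2 -> dropped whole; (pX, LG8) row gone; m2, m4 kept
  expect_setequal(unique(out$maps$marker_id), c("m2", "m4"))
  expect_equal(unname(out$report[["excluded_rows"]]), 1L)
  expect_equal(unname(out$report[["multi_lg_markers"]]), 1L)
  expect_equal(unname(out$report[["kept_rows"]]), 3L)
})

test_that("assign_markers tie-breaking: size, matched-state, cM adjacency", {
  lens <- c(big = 10000L, small = 5000L, other = 8000L)
  maps <- data.frame(parent = "pA", linkage_group = 1L,
                     marker_id = c("m1", "m2", "m3"), cM = c(0, 1, 2))
  w <- c(pA = 3L)
  # identical hits on big and small, both unmatched -> big
  pl <- data.frame(marker_id = "m1", contig_id = c("big", "small"),
                   pos0 = c(10L, 10L), strand = "+")
  a <- assign_markers(pl, lens, maps, w)
  expect_equal(a$assignments$contig_id, "big")
  # previous marker in cM order sits on small -> adjacency override
  pl2 <- rbind(
    data.frame(marker_id = "m1", contig_id = "small", pos0 = 1L, strand = "+"),
    data.frame(marker_id = "m2", contig_id = c("big", "small"),
               pos0 = c(10L, 100L), strand = "+"))
  a2 <- assign_markers(pl2, lens, maps, w)
  got <- a2$assignments
  expect_equal(got$contig_id[got$marker_id == "m2"], "small")
  # big already matched by an earlier marker -> small chosen for the next
  pl3 <- rbind(
    data.frame(marker_id = "m1", contig_id = "big", pos0 = 1L, strand = "+"),
    data.frame(marker_id = "m3", contig_id = c("big", "other"),
               pos0 = c(10L, 10L), strand = "+"))
  a3 <- assign_markers(pl3, lens, maps, w)
  got3 <- a3$assignments
  expect_equal(got3$contig_id[got3$marker_id == "m3"], "other")
  # marker with zero placements is unanchorable, not an error
  a4 <- assign_markers(pl, lens, maps, w)
  expect_setequal(a4$unanchorable, c("m2", "m3"))
})

test_that("detect_chimeras block-scans linkage-group patterns", {
  mk <- function(lgs) data.frame(
    marker_id = sprintf("m%d", seq_along(lgs)), contig_id = "c",
    pos0 = seq_along(lgs) * 100L, strand = "+", lg = lgs)
  expect_equal(nrow(detect_chimeras(mk(c(1, 1, 2, 2)))), 1L)
  d <- detect_chimeras(mk(c(1, 1, 2, 2)))
  expect_equal(d$left_offset, 200L)
  expect_equal(d$right_offset, 300L)
  expect_equal(nrow(detect_chimeras(mk(c(1, 1, 2)))), 0L)   # block < chunk
  expect_equal(nrow(detect_chimeras(mk(c(1, 1, 2, 2, 1, 1)))), 2L)
  # same-LG blocks separated by a sub-chunk run: no split
  expect_equal(nrow(detect_chimeras(mk(c(1, 1, 2, 1, 1)))), 0L)
})

test_that("locate_split picks the largest in-between N-run, leftmost on ties", {
  runs <- cbind(start = c(400L, 600L), end = c(450L, 610L))
  expect_equal(locate_split(runs, 200, 900), c(start = 400L, end = 450L))
  # no N-runs: zero-width cut directly after the final left marker
  none <- contig_n_runs("ACGT")
  expect_equal(locate_split(none, 200, 900), c(start = 201, end = 201))
  # tie between equal runs: leftmost
  ties <- cbind(start = c(300L, 500L), end = c(350L, 550L))
  expect_equal(locate_split(ties, 100, 900), c(start = 300L, end = 350L))
  # runs outside the flanked interval are ignored
  expect_equal(locate_split(runs, 500, 900), c(start = 600L, end = 610L))
})

test_that("split_contigs cuts, renames, re-offsets and conserves sequence", {
  ctg <- c(parent = paste0(strrep("A", 400), strrep("N", 50), strrep("G", 550)))
  cuts <- data.frame(contig = "parent", start = 400L, end = 450L)
  pl <- data.frame(marker_id = c("mL", "mR"), contig_id = "parent",
                   pos0 = c(100L, 900L), strand = "+")
  sp <- split_contigs(ctg, cuts, pl)
  expect_equal(nchar(sp$contigs), c(parent.1 = 400L, parent.2 = 550L))
  expect_equal(non_n_bytes(sp$contigs), non_n_bytes(ctg))
  got <- sp$placements
  expect_equal(got$contig_id, c("parent.1", "parent.2"))
  expect_equal(got$pos0, c(100L, 450L))
  # zero-width cut
  sp2 <- split_contigs(c(p = strrep("A", 1000)),
                       data.frame(contig = "p", start = 201L, end = 201L))
  expect_equal(unname(nchar(sp2$contigs)), c(201L, 799L))
})

test_that("order_and_orient recovers order/orientation and honours weights", {
  gen <- simulate_genome(n_chrom = 2, chrom_len = 100000, n_contigs = 14,
                        chimera_rate = 0, seed = 41)
  lm <- simulate_linkage_maps(gen, n_parents = 4, markers_per_lg = 30,
                             noise_sd = 0, seed = 42)
  fm <- filter_markers(lm$maps)
  asg <- assign_markers(lm$placements, nchar(gen$contigs), fm$maps, lm$weights)
  lay <- order_and_orient(asg$assignments, fm$maps, lm$weights)
  org <- gen$truth$origins
  for (k in 1:2) {
    l <- lay[lay$object == sprintf("LG%d", k), ]
    tru <- org[org$chrom == sprintf("chr%02d", k), ]
    tru <- tru[order(tru$start), ]
    placed <- intersect(tru$contig, l$contig)
    expect_equal(l$contig[l$contig %in% placed],
                 tru$contig[tru$contig %in% placed])
    # orientation: every multi-marker contig matches its true orientation
    multi <- names(which(table(asg$assignments$contig_id) >= 2))
    cmp <- merge(l[l$contig %in% multi, c("contig", "orientation")],
                 tru[, c("contig", "orientation")], by = "contig")
    expect_true(all(cmp$orientation.x == cmp$orientation.y))
  }
  cs <- collinearity_stats(lay, nchar(gen$contigs), asg$assignments, fm$maps,
                           lm$weights)
  expect_equal(cs$mean_rho, 1.0, tolerance = 1e-12)
  # the highest-weight parent wins a disagreement over pair order
  maps2 <- data.frame(
    parent = rep(c("pHi", "pLo"), each = 4),
    linkage_group = 1L,
    marker_id = rep(c("a1", "a2", "b1", "b2"), 2),
    cM = c(1, 2, 5, 6,     5, 6, 1, 2))   # pLo reverses the contig order
  asg2 <- data.frame(marker_id = c("a1", "a2", "b1", "b2"),
                     contig_id = c("cA", "cA", "cB", "cB"),
                     pos0 = c(10L, 500L, 10L, 500L), strand = "+",
                     lg = 1L)
  lay2 <- order_and_orient(asg2, maps2, c(pHi = 3L, pLo = 1L))
  expect_equal(lay2$contig, c("cA", "cB"))
  # a contig whose cM rises while offsets fall is oriented "-"
  asg3 <- data.frame(marker_id = c("a1", "a2"), contig_id = "cA",
                     pos0 = c(500L, 10L), strand = "+", lg = 1L)
  lay3 <- order_and_orient(asg3, maps2[maps2$parent == "pHi", ][1:2, ],
                           c(pHi = 3L))
  expect_equal(lay3$orientation, "-")
  # single-marker contigs are anchored but unoriented
  asg4 <- data.frame(marker_id = "a1", contig_id = "cA", pos0 = 10L,
                     strand = "+", lg = 1L)
  lay4 <- order_and_orient(asg4, maps2[maps2$parent == "pHi", ][1, ],
                           c(pHi = 3L))
  expect_equal(lay4$orientation, "?")
  # mixed-LG contig at this stage is an error
  asg5 <- data.frame(marker_id = c("a1", "b1"), contig_id = "cA",
                     pos0 = c(1L, 2L), strand = "+", lg = c(1L, 2L))
  expect_error(order_and_orient(asg5, maps2, c(pHi = 3L, pLo = 1L)),
               "chimera")
})

test_that("a fully reversed linkage group yields rho = -1", {
  maps <- data.frame(parent = "p", linkage_group = 1L,
                     marker_id = sprintf("m%d", 1:4), cM = c(3, 2, 1, 0))
  asg <- data.frame(marker_id = sprintf("m%d", 1:4),
                    contig_id = sprintf("c%d", 1:4),
                    pos0 = 0L, strand = "+", lg = 1L)
  lay <- data.frame(object = "LG1", contig = sprintf("c%d", 1:4),
                    orientation = "+", gap_after = TRUE)
  cs <- collinearity_stats(lay, c(c1 = 10L, c2 = 10L, c3 = 10L, c4 = 10L),
                           asg, maps, c(p = 1L))
  expect_equal(cs$mean_rho, -1.0)
})

test_that("shuffled layouts give near-zero mean collinearity", {
  set.seed(8)
  maps <- data.frame(parent = "p", linkage_group = 1L,
                     marker_id = sprintf("m%02d", 1:30),
                     cM = seq(0, 29))
  asg <- data.frame(marker_id = sprintf("m%02d", 1:30),
                    contig_id = sprintf("c%02d", 1:30),
                    pos0 = 0L, strand = "+", lg = 1L)
  lens <- stats::setNames(rep(100L, 30), sprintf("c%02d", 1:30))
  rhos <- replicate(40, {
    lay <- data.frame(object = "LG1", contig = sample(sprintf("c%02d", 1:30)),
                      orientation = "+", gap_after = TRUE)
    collinearity_stats(lay, lens, asg, maps, c(p = 1L))$mean_rho
  })
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("recomb_rate_track: uniform map gives a flat cM/Mb track", {
  # 10 contigs of 100 kb, no gaps, markers every 100 kb, 1 cM per 100 kb
  ids <- sprintf("c%02d", 1:10)
  lens <- stats::setNames(rep(1e5L, 10), ids)
  lay <- data.frame(object = "LG1", contig = ids, orientation = "+",
                    gap_after = FALSE)
  asg <- data.frame(marker_id = sprintf("m%02d", 1:10), contig_id = ids,
                    pos0 = 0L, strand = "+", lg = 1L)
  maps <- data.frame(parent = "p", linkage_group = 1L,
                     marker_id = sprintf("m%02d", 1:10),
                     cM = seq(0, 9))
  rt <- recomb_rate_track(lay, lens, asg, maps, c(p = 1L), window = 1e5)
  inner <- rt[rt$end <= 9e5, ]
  expect_equal(inner$cm_per_mb, rep(10, nrow(inner)), tolerance = 1e-9)
  # beyond the last marker: missing
  expect_true(is.na(rt$cm_per_mb[rt$start >= 9e5]))
  # two-segment map checked by hand: 1 cM over first half, 5 cM over second
  maps2 <- maps
  maps2$cM <- c(seq(0, 0.5, length.out = 5), seq(1.5, 5.5, length.out = 5))
  rt2 <- recomb_rate_track(lay, lens, asg, maps2, c(p = 1L), window = 1e5)
  expect_equal(rt2$cm_per_mb[2], 1.25, tolerance = 1e-9)  # 0.125 cM / 0.1 Mb
  expect_equal(rt2$cm_per_mb[6], 10, tolerance = 1e-9)    # 1 cM / 0.1 Mb
})
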