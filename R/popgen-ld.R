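#' Pairwise linkage disequilibrium (r-squared) within a distance window
#'
#' r2 is the squared Pearson correlation of dosage vectors over the samples
#' non-missing at both sites (the genotype-count r2 of unphased data). Pairs
#' with fewer than 4 complete samples, or with zero dosage variance at either
#' site, are skipped. Only pairs on the same chromosome separated by at most
#' `max_dist` bp are considered; an optional MAF floor is applied first.
#'
#' @param g a [geno_matrix].
#' @param max_dist maximum pair distance in bp.
#' @param maf optional minor-allele-frequency floor applied before pairing.
#' @param min_complete minimum number of samples complete at both sites.
#' @return data.frame with columns `chrom`, `i`, `j` (site indices into the
#'   MAF-filtered matrix used), `dist` (bp) and `r2`; the filtered
#'   [geno_matrix] is attached as `attr(, "geno")`.
#' @export
pairwise_r2 <- function(g, max_dist = 1e5, maf = NULL, min_complete = 4L) {
  stopifnot(inherits(g, "geno_matrix"))
  if (!is.null(maf)) g <- subset_sites(g, !is.na(site_maf(g)) & site_maf(g) >= maf)
  out <- list()
  for (ch in unique(g$sites$chrom)) {
    sel <- which(g$sites$chrom == ch)
    pos <- g$sites$pos[sel]
    X <- g$dosage[, sel, drop = FALSE]
    m <- length(sel)
    if (m < 2L) next
    chunk <- 512L
    starts <- seq(1L, m, by = chunk)
    for (a in starts) {
      b <- min(a + chunk - 1L, m)
      # partners: indices >= a whose position is within max_dist of block end
      last <- max(which(pos <= pos[b] + max_dist))
      if (last <= a) next
      r2m <- .r2_block(X[, a:b, drop = FALSE], X[, a:last, drop = FALSE],
                       min_complete)
      ii <- rep(a:b, times = last - a + 1L)
      jj <- rep(a:last, each = b - a + 1L)
      keep <- jj > ii & (pos[jj] - pos[ii]) <= max_dist & !is.na(as.vector(r2m))
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, i = sel[ii[keep]], j = sel[jj[keep]],
        dist = pos[jj[keep]] - pos[ii[keep]], r2 = as.vector(r2m)[keep],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), i = integer(0), j = integer(0),
               dist = integer(0), r2 = numeric(0))
  attr(res, "geno") <- g
  res
}

# Squared correlation between columns of A and columns of B with pairwise
# complete observations, via moment cross-products (NA -> 0 trick).
.r2_block <- function(A, B, min_complete) {
  Ma <- !is.na(A); Mb <- !is.na(B)
  A0 <- A; A0[!Ma] <- 0L; B0 <- B; B0[!Mb] <- 0L
  storage.mode(A0) <- "double"; storage.mode(B0) <- "double"
  Ma <- matrix(as.double(Ma), nrow(A)); Mb <- matrix(as.double(Mb), nrow(B))
  n <- crossprod(Ma, Mb)
  Sx <- crossprod(A0, Mb); Sy <- crossprod(Ma, B0)
  Sxx <- crossprod(A0^2, Mb); Syy <- crossprod(Ma, B0^2)
  Sxy <- crossprod(A0, B0)
  num <- n * Sxy - Sx * Sy
  den <- (n * Sxx - Sx^2) * (n * Syy - Sy^2)
  r2 <- num^2 / den
  r2[n < min_complete | den <= 0] <- NA_real_
  r2
}

#' Bin r-squared values by pair distance
#'
#' @param pairs data.frame from [pairwise_r2()] (needs `dist`, `r2`).
#' @param bin bin width in bp; bins are `[k*bin, (k+1)*bin)`.
#' @return data.frame with `lo`, `hi`, `mid` (bp), `mean_r2`, `n_pairs`,
#'   sorted by distance; empty bins are omitted.
#' @export
bin_ld <- function(pairs, bin = 1000L) {
  stopifnot(all(c("dist", "r2") %in% names(pairs)))
  if (!nrow(pairs))
    return(data.frame(lo = numeric(0), hi = numeric(0), mid = numeric(0),
                      mean_r2 = numeric(0), n_pairs = integer(0)))
  k <- pairs$dist %/% bin
  agg <- tapply(pairs$r2, k, mean)
  cnt <- tapply(pairs$r2, k, length)
  kk <- as.numeric(names(agg))
  data.frame(lo = kk * bin, hi = (kk + 1) * bin, mid = (kk + 0.5) * bin,
             mean_r2 = as.numeric(agg), n_pairs = as.integer(cnt))[order(kk), ]
}

#' Distance at which mean r-squared decays to a threshold
#'
#' Scans bins by increasing distance and reports the point where the mean r2
#' first drops below `threshold`, linearly interpolated between the previous
#' bin midpoint and the first sub-threshold bin midpoint. Monotone decay is
#' not assumed. If every bin is below the threshold the first midpoint is
#' returned; if none is, the largest midpoint is returned with
#' `censored = TRUE`.
#'
#' @param bins data.frame from [bin_ld()].
#' @param threshold r2 threshold (0.2 by convention).
#' @return list with `extent` (bp) and `censored` (logical).
#' @export
ld_extent <- function(bins, threshold = 0.2) {
  stopifnot(nrow(bins) >= 1)
  below <- which(bins$mean_r2 < threshold)
  if (!length(below))
    return(list(extent = bins$mid[nrow(bins)], censored = TRUE))
  k <- below[1L]
  if (k == 1L) return(list(extent = bins$mid[1L], censored = FALSE))
  x0 <- bins$mid[k - 1L]; y0 <- bins$mean_r2[k - 1L]
  x1 <- bins$mid[k]; y1 <- bins$mean_r2[k]
  list(extent = x0 + (y0 - threshold) / (y0 - y1) * (x1 - x0),
       censored = FALSE)
}

#' Greedy LD pruning
#'
#' Scans sites left to right within each chromosome; whenever a pair within
#' `window` bp has r2 greater than `r2_max`, the later site is removed. The
#' surviving set therefore contains no pair within `window` bp whose r2
#' exceeds `r2_max` (pairs skipped for insufficient complete samples or zero
#' variance cannot disqualify a site).
#'
#' @param g a [geno_matrix].
#' @param window pair distance limit in bp.
#' @param r2_max maximum tolerated r2.
#' @return integer vector of kept site indices (columns of `g`).
#' @export
ld_prune <- function(g, window = 1e5, r2_max = 0.2) {
  stopifnot(inherits(g, "geno_matrix"))
  pairs <- pairwise_r2(g, max_dist = window, maf = NULL)
  kept <- rep(TRUE, ncol(g$dosage))
  if (nrow(pairs)) {
    ord <- order(pairs$j, pairs$i)
    for (k in ord) {
      i <- pairs$i[k]; j <- pairs$j[k]
      if (kept[i] && kept[j] && pairs$r2[k] > r2_max) kept[j] <- FALSE
    }
  }
  which(kept)
}
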