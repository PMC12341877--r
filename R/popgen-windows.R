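#' Windowed diversity statistics: segregating sites, pi, Tajima's D
#'
#' Statistics are computed in non-overlapping windows aligned to multiples of
#' `window` (0-based half-open coordinates). Per site, with `n` the number of
#' non-missing allele copies and `n_alt` alternate copies, the unbiased
#' per-site heterozygosity is `2 * n_ref * n_alt / (n * (n - 1))`; window
#' `pi` is the sum of these divided by the window length (per-bp). Tajima's
#' D uses the classical constants evaluated at the window's average `n`
#' over segregating sites, and is `NA` for windows with no segregating site.
#'
#' @param g a [geno_matrix].
#' @param window window size in bp.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `S`, `pi`, `tajima_d`, `n` (average allele count).
#' @export
window_stats <- function(g, window = 10000L) {
  stopifnot(inherits(g, "geno_matrix"), window >= 1)
  out <- list()
  for (ch in unique(g$sites$chrom)) {
    sel <- which(g$sites$chrom == ch)
    pos0 <- g$sites$pos[sel] - 1L           # to 0-based
    dos <- g$dosage[, sel, drop = FALSE]
    n_al <- 2L * colSums(!is.na(dos))
    n_alt <- colSums(dos, na.rm = TRUE)
    seg <- n_alt > 0L & n_alt < n_al
    pi_site <- ifelse(n_al >= 2,
                      2 * (n_al - n_alt) * n_alt / (n_al * (n_al - 1)), 0)
    win_id <- pos0 %/% as.integer(window)
    for (w in sort(unique(win_id))) {
      in_w <- win_id == w
      S <- sum(seg & in_w)
      theta_pi <- sum(pi_site[in_w])
      n_bar <- if (S > 0) mean(n_al[in_w & seg]) else NA_real_
      D <- if (S > 0) .tajima_d(theta_pi, S, n_bar) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = w * window, end = (w + 1) * window,
        S = S, pi = theta_pi / window, tajima_d = D, n = n_bar,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# harmonic sums H_{n-1} and sum of 1/i^2; literal for integer n, digamma
# otherwise (identical in exact arithmetic)
.harmonics <- function(n) {
  if (n == round(n)) {
    i <- seq_len(n - 1)
    c(a1 = sum(1 / i), a2 = sum(1 / i^2))
  } else {
    c(a1 = digamma(n) - digamma(1), a2 = trigamma(1) - trigamma(n))
  }
}

# Tajima's D from theta_pi (sum of per-site heterozygosity), S and sample
# allele count n (Tajima 1989 constants)
.tajima_d <- function(theta_pi, S, n) {
  if (S == 0 || n < 3) return(NA_real_)
  h <- .harmonics(n)
  a1 <- h[["a1"]]; a2 <- h[["a2"]]
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (theta_pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}
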