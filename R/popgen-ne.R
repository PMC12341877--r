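#' LD-based effective population size per distance bin
#'
#' Each distance bin is converted to a recombination fraction
#' `c = mid * c_rate` (linear map function) and a time depth
#' `t = 1 / (2c)` generations; the effective size at that depth follows the
#' Sved-type expectation `E[r2] = 1 / (a + 4 Ne c)` solved for Ne:
#' `Ne = (1 / (4c)) * (1 / r2_adj - a)`. The bin's mean r2 is first adjusted
#' for finite sample size (`r2_adj = r2 - 1/n_ind` for unphased dosage r2);
#' bins where the adjusted value is non-positive or implies `1/r2_adj <= a`
#' carry no information about a positive Ne and are dropped (their count is
#' reported in `attr(, "dropped")`).
#'
#' @param bins data.frame from [bin_ld()].
#' @param c_rate recombination rate in Morgans per bp.
#' @param a constant of the LD expectation (2.2 for unphased samples).
#' @param n_ind number of diploid individuals behind the r2 values.
#' @param adjust apply the `1/n_ind` sample-size correction.
#' @return data.frame with `dist` (bp), `c`, `t` (generations), `ne`, sorted
#'   by `t`.
#' @export
estimate_ne <- function(bins, c_rate = 1e-9, a = 2.2, n_ind, adjust = TRUE) {
  stopifnot(all(c("mid", "mean_r2") %in% names(bins)), n_ind >= 2)
  r2 <- bins$mean_r2 - if (adjust) 1 / n_ind else 0
  cc <- bins$mid * c_rate
  ok <- r2 > 0 & (1 / r2) > a & cc > 0
  res <- data.frame(dist = bins$mid[ok], c = cc[ok], t = 1 / (2 * cc[ok]),
                    ne = (1 / (4 * cc[ok])) * (1 / r2[ok] - a))
  res <- res[order(res$t), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "dropped") <- sum(!ok)
  res
}

#' Smooth an Ne trajectory: rolling median then smoothing spline
#'
#' The raw per-bin (t, Ne) points are noisy; the trend is estimated as a
#' centred rolling median of `window` points (ends truncated), followed by a
#' cubic smoothing spline fitted on (log t, log Ne) and evaluated at the
#' retained points. With fewer than 4 retained points, or a constant series,
#' the rolling median is returned unsplined.
#'
#' @param points data.frame from [estimate_ne()] (needs `t`, `ne`).
#' @param window rolling-median window (odd integer).
#' @return data.frame with `t` and `ne_trend`, sorted by `t`.
#' @export
smooth_trajectory <- function(points, window = 11L) {
  stopifnot(all(c("t", "ne") %in% names(points)), window %% 2L == 1L)
  pts <- points[order(points$t), , drop = FALSE]
  n <- nrow(pts)
  if (n == 0L) return(data.frame(t = numeric(0), ne_trend = numeric(0)))
  if (n < window) {
    med <- rep(stats::median(pts$ne), n)
    return(data.frame(t = pts$t, ne_trend = med))
  }
  med <- zoo::rollmedian(pts$ne, k = window, align = "center")
  half <- (window - 1L) %/% 2L
  t_mid <- pts$t[(half + 1L):(n - half)]
  if (length(t_mid) >= 4L && stats::sd(med) > 0 && stats::sd(log(t_mid)) > 0) {
    fit <- stats::smooth.spline(log(t_mid), log(med))
    trend <- exp(stats::predict(fit, log(t_mid))$y)
  } else {
    trend <- med
  }
  data.frame(t = t_mid, ne_trend = trend)
}
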