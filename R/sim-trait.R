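#' Simulate a quantitative trait with planted QTL and polygenic background
#'
#' The genetic value is the sum of a QTL component (given site indices and
#' effect sizes) and, optionally, a polygenic component (small Normal
#' effects at every site). The two are standardised and combined so the
#' polygenic part contributes `poly_frac` of the genetic variance, and the
#' total is scaled against Normal noise so the realised narrow-sense
#' heritability matches `h2` up to sampling noise.
#'
#' @param g a [geno_matrix].
#' @param qtl data.frame with columns `site` (column index) and `effect`, or
#'   NULL for no planted QTL.
#' @param h2 target narrow-sense heritability in `[0, 1]`.
#' @param poly_frac fraction of the genetic variance due to the polygenic
#'   background (0 = QTL only, 1 = purely polygenic).
#' @param seed integer seed.
#' @return numeric phenotype vector (one value per sample) with an attribute
#'   `truth` describing the components (target h2, per-site QTL effects on
#'   the realised scale, variance shares).
#' @export
simulate_trait <- function(g, qtl = NULL, h2, poly_frac = 0, seed = 1L) {
  stopifnot(inherits(g, "geno_matrix"), h2 >= 0, h2 <= 1,
            poly_frac >= 0, poly_frac <= 1)
  if (ncol(g$dosage) == 0L) stop("empty genotype matrix")
  if (!is.null(qtl)) {
    stopifnot(all(c("site", "effect") %in% names(qtl)))
    if (any(qtl$site < 1 | qtl$site > ncol(g$dosage)))
      stop("QTL site index out of range")
  }
  set.seed(seed)
  n <- nrow(g$dosage)
  G <- g$dosage
  storage.mode(G) <- "double"
  mu <- colMeans(G, na.rm = TRUE)
  idx_na <- which(is.na(G), arr.ind = TRUE)
  if (nrow(idx_na)) G[idx_na] <- mu[idx_na[, 2L]]

  qtl_part <- if (!is.null(qtl) && nrow(qtl))
    drop(G[, qtl$site, drop = FALSE] %*% qtl$effect) else rep(0, n)
  poly_part <- if (poly_frac > 0)
    drop(G %*% stats::rnorm(ncol(G), 0, 1)) else rep(0, n)

  std <- function(x) {
    s <- stats::sd(x)
    if (s > 0) (x - mean(x)) / s else rep(0, n)
  }
  w_qtl <- sqrt(1 - poly_frac)
  w_poly <- sqrt(poly_frac)
  has_qtl <- stats::sd(qtl_part) > 0
  has_poly <- stats::sd(poly_part) > 0
  genetic <- w_qtl * std(qtl_part) + w_poly * std(poly_part)
  if (h2 > 0 && stats::sd(genetic) == 0) {
    if (h2 == 1) stop("h2 = 1 requires non-zero genetic variance")
    genetic <- rep(0, n)
  }
  g_std <- if (stats::sd(genetic) > 0) std(genetic) else genetic
  noise <- if (h2 < 1) stats::rnorm(n, 0, 1) else rep(0, n)
  y <- sqrt(h2) * g_std + sqrt(1 - h2) * std(noise)
  # realised QTL effects after standardisation (for variance bookkeeping)
  qtl_scale <- if (has_qtl) sqrt(h2) * w_qtl / stats::sd(qtl_part) else 0
  attr(y, "truth") <- list(
    h2 = h2, poly_frac = poly_frac,
    qtl = if (!is.null(qtl)) transform(qtl, effect_realised = effect * qtl_scale),
    qtl_var_share = if (has_qtl) h2 * (1 - poly_frac) else 0)
  y
}
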