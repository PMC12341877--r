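#' Principal component analysis of a genotype matrix
#'
#' Missing dosages are mean-imputed per site, sites are centred and scaled to
#' unit variance (zero-variance sites are dropped), and the sample scores are
#' obtained from the singular value decomposition of the scaled matrix --
#' equivalent to the eigendecomposition of the sample covariance. Percent
#' variance is each eigenvalue's share of the total.
#'
#' @param g a [geno_matrix].
#' @param n_pc number of components to return (capped by the matrix rank).
#' @return list with `scores` (samples x `n_pc`), `percent` (variance
#'   explained by each returned component, in percent of the total), and
#'   `n_sites_used`.
#' @export
pca_genotypes <- function(g, n_pc = 10L) {
  stopifnot(inherits(g, "geno_matrix"))
  X <- g$dosage
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  sdv <- apply(X, 2L, stats::sd)
  use <- sdv > 0 & !is.na(sdv)
  X <- scale(X[, use, drop = FALSE])
  k <- min(n_pc, nrow(X) - 1L, ncol(X))
  sv <- svd(X)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- g$samples
  colnames(scores) <- paste0("PC", seq_len(k))
  ev <- sv$d^2
  list(scores = scores, percent = 100 * ev[seq_len(k)] / sum(ev),
       n_sites_used = sum(use))
}
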