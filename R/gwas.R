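#' Identity-by-state kinship matrix
#'
#' `K[i, j] = 1 - mean(|d_i - d_j|) / 2` over the sites where both samples
#' are non-missing; the diagonal is exactly 1 and every entry lies in
#' `[0, 1]`. Computed via indicator cross-products, so missing data never
#' enters the averages.
#'
#' @param g a [geno_matrix].
#' @return symmetric numeric matrix with sample ids as dimnames.
#' @export
ibs_kinship <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  D <- g$dosage
  I0 <- matrix(as.double(!is.na(D) & D == 0L), nrow(D))
  I1 <- matrix(as.double(!is.na(D) & D == 1L), nrow(D))
  I2 <- matrix(as.double(!is.na(D) & D == 2L), nrow(D))
  M <- I0 + I1 + I2
  diff1 <- tcrossprod(I0, I1) + tcrossprod(I1, I0) +
    tcrossprod(I1, I2) + tcrossprod(I2, I1)
  diff2 <- tcrossprod(I0, I2) + tcrossprod(I2, I0)
  comp <- tcrossprod(M, M)
  K <- 1 - (diff1 + 2 * diff2) / (2 * comp)
  K[comp == 0] <- NA_real_
  diag(K) <- 1
  dimnames(K) <- list(g$samples, g$samples)
  K
}

#' REML fit of the variance-component null model
#'
#' Fits `y = X b + u + e` with `Var(u) = sg2 * K`, `Var(e) = se2 * I` by
#' restricted maximum likelihood, using a single eigendecomposition of `K`
#' and a one-dimensional search over the variance ratio
#' `delta = se2 / sg2` (grid on log10 scale refined by [stats::optimize()]).
#' This is the standard single-eigendecomposition mixed-model fit used by
#' EMMA/EMMAX-style association.
#'
#' @param y numeric phenotype vector.
#' @param X fixed-effect design matrix including the intercept (default:
#'   intercept only).
#' @param K kinship matrix from [ibs_kinship()] (must be positive
#'   semi-definite up to numerical jitter).
#' @param delta_range log10 range searched for the variance ratio.
#' @return object of class `emmax_null` with components `sg2`, `se2`,
#'   `delta`, `h2` (sg2/(sg2+se2)), `loglik` (REML), `beta`, `boundary`
#'   (TRUE if the ratio hit the search edge), `unidentifiable` (TRUE when K
#'   has numerically constant eigenvalues, e.g. K = I, so only the total
#'   variance is estimable), plus the eigendecomposition for reuse by
#'   [score_snps()].
#' @export
fit_null <- function(y, X = NULL, K, delta_range = c(-5, 5)) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n, nrow(K) == n, ncol(K) == n)
  if (n < ncol(X) + 2) stop("need n >= ncol(X) + 2 observations")
  eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
  lam <- eig$values
  if (min(lam) < -1e-6 * max(abs(lam)))
    stop("K is not positive semi-definite")
  lam <- pmax(lam, 0)
  U <- eig$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  p <- ncol(X)
  ldXX <- determinant(crossprod(X), logarithm = TRUE)$modulus

  reml <- function(log10d) {
    d <- 10^log10d
    w <- lam + d
    XtW <- Xt / w
    XWX <- crossprod(Xt, XtW)
    b <- solve(XWX, crossprod(XtW, yt))
    r <- yt - Xt %*% b
    R <- sum(r^2 / w)
    0.5 * ((n - p) * (log((n - p) / (2 * pi)) - 1 - log(R)) -
             sum(log(w)) -
             determinant(XWX, logarithm = TRUE)$modulus + ldXX)
  }
  grid <- seq(delta_range[1], delta_range[2], length.out = 61)
  ll <- vapply(grid, reml, numeric(1))
  k <- which.max(ll)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  opt <- stats::optimize(reml, c(lo, hi), maximum = TRUE, tol = 1e-6)
  log10d <- opt$maximum
  delta <- 10^log10d
  w <- lam + delta
  XtW <- Xt / w
  XWX <- crossprod(Xt, XtW)
  b <- solve(XWX, crossprod(XtW, yt))
  R <- sum((yt - Xt %*% b)^2 / w)
  sg2 <- R / (n - p)
  se2 <- delta * sg2
  structure(list(
    sg2 = sg2, se2 = se2, delta = delta, h2 = sg2 / (sg2 + se2),
    loglik = opt$objective, beta = drop(b),
    boundary = log10d <= delta_range[1] + 0.05 ||
      log10d >= delta_range[2] - 0.05,
    unidentifiable = stats::sd(lam) < 1e-8 * max(1, mean(lam)),
    eig_values = lam, eig_vectors = U, X = X, y = y),
    class = "emmax_null")
}

#' @export
print.emmax_null <- function(x, ...) {
  cat(sprintf("EMMAX null model: sg2 = %.4g, se2 = %.4g (h2 = %.3f)%s%s\n",
              x$sg2, x$se2, x$h2,
              if (x$boundary) " [boundary]" else "",
              if (x$unidentifiable) " [variance partition unidentifiable]" else ""))
  cat(sprintf("  REML log-likelihood: %.4f; fixed effects: %s\n",
              x$loglik, paste(signif(x$beta, 4), collapse = ", ")))
  invisible(x)
}

#' Single-marker mixed-model association scan (EMMAX approximation)
#'
#' Each SNP is tested by generalized least squares with the covariance fixed
#' at the null-model estimates (`V = sg2 K + se2 I`): data are rotated by the
#' eigenvectors of K, whitened by `1/sqrt(sg2 lambda + se2)`, the covariates
#' are projected out once, and the per-SNP 1-df statistic is
#' `(beta / se)^2`, referred to the chi-squared(1) upper tail (or F(1, n-p-1)
#' with `ref = "f"`). Missing dosages are mean-imputed per site; sites with
#' sample MAF below `maf_min` or zero variance are skipped.
#'
#' @param g a [geno_matrix].
#' @param null an `emmax_null` fit from [fit_null()] (carries y and X).
#' @param maf_min minimum sample MAF for a site to be tested.
#' @param threshold significance threshold on the p-value.
#' @param ref reference distribution, `"chisq"` (default) or `"f"`.
#' @return data.frame with one row per tested site: `site` (column index in
#'   `g`), `chrom`, `pos`, `beta`, `se`, `stat`, `p`, `n`, `significant`.
#' @export
score_snps <- function(g, null, maf_min = 0.01, threshold = 5e-5,
                       ref = c("chisq", "f")) {
  stopifnot(inherits(g, "geno_matrix"), inherits(null, "emmax_null"))
  ref <- match.arg(ref)
  n <- length(null$y)
  if (nrow(g$dosage) != n) stop("genotypes and phenotype differ in samples")
  G <- g$dosage
  storage.mode(G) <- "double"
  mu <- colMeans(G, na.rm = TRUE)
  idx_na <- which(is.na(G), arr.ind = TRUE)
  if (nrow(idx_na)) G[idx_na] <- mu[idx_na[, 2L]]
  maf <- pmin(mu / 2, 1 - mu / 2)
  test <- which(!is.na(maf) & maf >= maf_min & apply(G, 2L, stats::sd) > 0)
  w <- null$sg2 * null$eig_values + null$se2
  sw <- sqrt(w)
  U <- null$eig_vectors
  Yt <- crossprod(U, null$y) / sw
  Xt <- crossprod(U, null$X) / sw
  Gt <- crossprod(U, G[, test, drop = FALSE]) / sw
  qrX <- qr(Xt)
  Ey <- qr.resid(qrX, Yt)
  EG <- qr.resid(qrX, Gt)
  gg <- colSums(EG^2)
  gy <- crossprod(EG, Ey)
  ok <- gg > 1e-12
  beta <- drop(gy) / gg
  se <- sqrt(1 / gg)
  stat <- beta^2 * gg
  p <- if (ref == "chisq") stats::pchisq(stat, 1, lower.tail = FALSE)
  else stats::pf(stat, 1, n - ncol(null$X) - 1L, lower.tail = FALSE)
  res <- data.frame(site = test, chrom = g$sites$chrom[test],
                    pos = g$sites$pos[test], beta = beta, se = se,
                    stat = stat, p = p, n = n,
                    significant = p < threshold,
                    stringsAsFactors = FALSE)[ok, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Genomic-control inflation factor
#'
#' Median of the observed 1-df statistics over the median of chi-squared(1),
#' 0.4549364.
#'
#' @param results data.frame from [score_snps()] (needs `stat`), or a numeric
#'   vector of 1-df statistics.
#' @return the inflation factor lambda.
#' @export
lambda_gc <- function(results) {
  stat <- if (is.data.frame(results)) results$stat else results
  stats::median(stat) / stats::qchisq(0.5, df = 1)
}

#' Phenotypic variance explained jointly by significant SNPs
#'
#' R-squared of the ordinary joint regression of the phenotype on the
#' (mean-imputed) dosages of the given sites, in percent. Zero when no site
#' is given.
#'
#' @param g a [geno_matrix].
#' @param y phenotype vector.
#' @param sites integer vector of site (column) indices.
#' @return percent of variance explained (0-100).
#' @export
variance_explained <- function(g, y, sites) {
  stopifnot(inherits(g, "geno_matrix"))
  if (!length(sites)) return(0)
  G <- g$dosage[, sites, drop = FALSE]
  storage.mode(G) <- "double"
  mu <- colMeans(G, na.rm = TRUE)
  idx_na <- which(is.na(G), arr.ind = TRUE)
  if (nrow(idx_na)) G[idx_na] <- mu[idx_na[, 2L]]
  100 * summary(stats::lm(y ~ G))$r.squared
}
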