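# Mixed-linear-model GWAS: variant filtering, VanRaden kinship, PCA
# covariates with LD pruning, EMMA-style REML null fit and the P3D/EMMAX
# association scan with Bonferroni thresholding.

#' Filter a genotype matrix for association analysis
#'
#' Applies, in order: biallelic-SNP check (from variant metadata; indels
#' and multi-allelic records are normally already dropped at VCF read),
#' minor-allele frequency, then missingness. `max_missing` follows the
#' VCFtools convention: sites with call rate >= `max_missing` are kept.
#'
#' @param gd `genotype_data`
#' @param maf minimum minor-allele frequency (default 0.05)
#' @param max_missing minimum call rate (default 0.8)
#' @return list with `data` (filtered `genotype_data`) and `report`
#'   (counts removed per rule, in application order)
#' @export
filter_variants <- function(gd, maf = 0.05, max_missing = 0.8) {
  v <- gd$variants
  is_snp <- nchar(v$ref) == 1 & nchar(v$alt) == 1 & !grepl(",", v$alt)
  g <- gd$geno[, is_snp, drop = FALSE]
  n_nonsnp <- sum(!is_snp)
  p <- colMeans(g, na.rm = TRUE) / 2
  mafs <- pmin(p, 1 - p)
  pass_maf <- !is.na(mafs) & mafs >= maf
  n_maf <- sum(!pass_maf)
  g2 <- g[, pass_maf, drop = FALSE]
  call_rate <- colMeans(!is.na(g2))
  pass_miss <- call_rate >= max_missing
  n_miss <- sum(!pass_miss)
  keep_ids <- colnames(g2)[pass_miss]
  keep_idx <- match(keep_ids, v$id)
  out <- genotype_data(gd$geno[, keep_idx, drop = FALSE],
                       v[keep_idx, , drop = FALSE], gd$samples)
  list(data = out,
       report = data.frame(
         rule = c("non_biallelic_snp", paste0("maf<", maf),
                  paste0("call_rate<", max_missing)),
         removed = c(n_nonsnp, n_maf, n_miss)))
}

# mean-impute missing dosages per site
impute_dosages <- function(g) {
  if (!anyNA(g)) return(g)
  mu <- colMeans(g, na.rm = TRUE)
  idx <- which(is.na(g), arr.ind = TRUE)
  g[idx] <- mu[idx[, 2]]
  g
}

#' VanRaden genomic relationship matrix
#'
#' `K = Z Z' / (2 sum p(1-p))` with `Z = G - 2p`; missing dosages are
#' mean-imputed per site.
#'
#' @param gd `genotype_data` or a dosage matrix
#' @return n x n symmetric kinship matrix
#' @export
grm_vanraden <- function(gd) {
  g <- if (inherits(gd, "genotype_data")) gd$geno else gd
  g <- impute_dosages(g)
  p <- colMeans(g) / 2
  Z <- sweep(g, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  if (denom == 0) stopf("all sites monomorphic; kinship undefined")
  K <- tcrossprod(Z) / denom
  (K + t(K)) / 2
}

# PLINK-style --indep-pairwise LD pruning: sliding window of `window` SNPs,
# advanced by `step`, removing the later SNP of any pair with r^2 > `r2`.
ld_prune <- function(g, window = 50, step = 5, r2 = 0.2) {
  M <- ncol(g)
  keep <- rep(TRUE, M)
  g <- impute_dosages(g)
  starts <- seq(1, max(1, M - 1), by = step)
  for (s in starts) {
    idx <- seq(s, min(s + window - 1, M))
    idx <- idx[keep[idx]]
    if (length(idx) < 2) next
    cm <- suppressWarnings(cor(g[, idx, drop = FALSE]))
    cm[is.na(cm)] <- 0
    for (i in seq_along(idx)[-1]) {
      if (!keep[idx[i]]) next
      earlier <- idx[seq_len(i - 1)]
      earlier <- earlier[keep[earlier]]
      if (length(earlier) && any(cm[match(earlier, idx), i]^2 > r2))
        keep[idx[i]] <- FALSE
    }
    if (s + window - 1 >= M) break
  }
  keep
}

#' Principal-component covariates from LD-pruned genotypes
#'
#' Window-based LD pruning (PLINK `--indep-pairwise` semantics) followed by
#' an eigendecomposition of the centered, scaled genotype matrix; the top
#' eigenvectors are returned as covariates.
#'
#' @param gd `genotype_data`
#' @param n_pcs number of components (default 3)
#' @param ld_prune `c(window_snps, step_snps, r2)` pruning parameters
#' @return n x n_pcs matrix of orthonormal sample eigenvectors
#' @export
pca_covariates <- function(gd, n_pcs = 3, ld_prune = c(50, 5, 0.2)) {
  g <- impute_dosages(gd$geno)
  keep <- ld_prune(g, ld_prune[1], ld_prune[2], ld_prune[3])
  g <- g[, keep, drop = FALSE]
  sds <- apply(g, 2, sd)
  g <- g[, sds > 0, drop = FALSE]
  gs <- scale(g)
  sv <- svd(gs, nu = n_pcs, nv = 0)
  pcs <- sv$u[, seq_len(n_pcs), drop = FALSE]
  colnames(pcs) <- paste0("PC", seq_len(n_pcs))
  rownames(pcs) <- rownames(gd$geno)
  pcs
}

#' Build a fixed-effect design matrix
#'
#' One-hot encodes factor/character covariates with first-level reference
#' and prepends an intercept.
#'
#' @param covariates data frame of covariates (factors, characters or
#'   numerics), or NULL for intercept-only
#' @param n number of individuals (needed when `covariates` is NULL)
#' @return numeric design matrix
#' @export
design_matrix <- function(covariates = NULL, n = NULL) {
  if (is.null(covariates)) {
    stopifnot(!is.null(n))
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  df <- as.data.frame(covariates)
  df[] <- lapply(df, function(col) if (is.character(col)) factor(col) else col)
  model.matrix(~ ., data = df)
}

#' Fit the null mixed model by REML (EMMA)
#'
#' Model `y = X b + u + e`, `u ~ N(0, sigma_g^2 K)`, `e ~ N(0, sigma_e^2 I)`.
#' K is eigendecomposed once; the restricted likelihood is profiled over
#' `delta = sigma_e^2 / sigma_g^2` on a log grid refined by 1-D
#' optimization. Returns variance components, `h2 = sigma_g^2 /
#' (sigma_g^2 + sigma_e^2)` and the spectral pieces the P3D scan reuses.
#'
#' @param y phenotype vector
#' @param X fixed-effect design matrix (see [design_matrix()])
#' @param K kinship matrix (positive semi-definite)
#' @param delta_range log10 search range for delta
#' @return object of class `mlm_null`
#' @export
fit_null_mlm <- function(y, X, K, delta_range = c(-5, 5)) {
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(K) == n, ncol(K) == n)
  if (max(abs(K - t(K))) > 1e-8) stopf("K must be symmetric")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stopf("design matrix is rank-deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  q <- ncol(X)
  # restricted problem: eigen of S K S on the residual space of X
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  eg <- eigen(S %*% K %*% S, symmetric = TRUE)
  xi <- eg$values[seq_len(n - q)]
  xi <- pmax(xi, 0)
  eta <- crossprod(eg$vectors[, seq_len(n - q), drop = FALSE], y)[, 1]
  reml_ll <- function(log10d) {
    d <- 10^log10d
    ss <- sum(eta^2 / (xi + d))
    0.5 * ((n - q) * log((n - q) / (2 * pi)) - (n - q) -
             (n - q) * log(ss) - sum(log(xi + d)))
  }
  grid <- seq(delta_range[1], delta_range[2], length.out = 100)
  ll_grid <- vapply(grid, reml_ll, 0)
  flat <- diff(range(ll_grid)) < 1e-6
  if (flat) {
    warnf("REML profile flat in delta (kinship carries no structure); returning boundary")
    log10d_hat <- delta_range[2]
  } else {
    i <- which.max(ll_grid)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- optimize(reml_ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
    log10d_hat <- opt$maximum
  }
  delta <- 10^log10d_hat
  sigma_g2 <- sum(eta^2 / (xi + delta)) / (n - q)
  sigma_e2 <- delta * sigma_g2
  ek <- eigen(K, symmetric = TRUE)
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, delta = delta,
                 h2 = 1 / (1 + delta), loglik = reml_ll(log10d_hat),
                 flat = flat, reml = reml_ll,
                 eigenK = list(U = ek$vectors, d = pmax(ek$values, 0)),
                 X = X, y = y),
            class = "mlm_null")
}

#' @export
print.mlm_null <- function(x, ...) {
  cat(sprintf("MLM null fit: sigma_g2 = %.4g, sigma_e2 = %.4g, h2 = %.3f%s\n",
              x$sigma_g2, x$sigma_e2, x$h2,
              if (x$flat) " (flat profile; boundary)" else ""))
  invisible(x)
}

#' P3D/EMMAX association scan
#'
#' Variance components are fixed at their null-model estimates; phenotype,
#' covariates and genotypes are rotated by the kinship eigenvectors and
#' whitened, after which each SNP is tested by generalized least squares
#' (Wald t-test). Missing dosages are mean-imputed; monomorphic SNPs get NA
#' with a warning.
#'
#' @param gd `genotype_data` of the SNPs to test
#' @param null `mlm_null` from [fit_null_mlm()]
#' @return data frame: id, chrom, pos, beta, se, p, neglog10p
#' @export
association_scan <- function(gd, null) {
  g <- impute_dosages(gd$geno)
  n <- nrow(g)
  U <- null$eigenK$U
  w <- 1 / sqrt(null$eigenK$d + null$delta)
  Ty <- (crossprod(U, null$y))[, 1] * w
  TX <- crossprod(U, null$X) * w
  TG <- crossprod(U, g) * w
  qrX <- qr(TX)
  ry <- qr.resid(qrX, Ty)
  RG <- qr.resid(qrX, TG)
  gg <- colSums(RG^2)
  mono <- gg < 1e-12
  if (any(mono)) warnf("%d monomorphic SNP(s): association set to NA", sum(mono))
  gy <- colSums(RG * ry)
  beta <- ifelse(mono, NA_real_, gy / gg)
  df <- n - ncol(null$X) - 1
  rss <- pmax(sum(ry^2) - beta^2 * gg, 0)
  se <- sqrt(rss / df / gg)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df)
  p[mono] <- NA_real_
  data.frame(id = gd$variants$id, chrom = gd$variants$chrom,
             pos = gd$variants$pos, beta = beta, se = se, p = p,
             neglog10p = -log10(p), stringsAsFactors = FALSE)
}

#' Bonferroni significance threshold on the -log10 scale
#'
#' @param M number of tests
#' @param alpha family-wise error rate (default 0.05)
#' @return `-log10(alpha / M)`
#' @export
bonferroni_threshold <- function(M, alpha = 0.05) {
  stopifnot(M >= 1, alpha > 0, alpha < 1)
  -log10(alpha / M)
}

#' Genomic-control inflation factor
#'
#' `lambda = median(chi^2) / qchisq(0.5, 1)` over the scan's p-values.
#'
#' @param p vector of p-values
#' @return lambda (1 = well calibrated)
#' @export
genomic_lambda <- function(p) {
  p <- p[!is.na(p)]
  median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)
}
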