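test_that("variant filters apply the stated rules in order", {
  # 10-sample site with 3 missing calls (call rate 0.7) is removed
  g <- cbind(site1 = c(rep(1, 7), NA, NA, NA),
             site2 = rep(c(0, 1), 5))
  gd <- make_toy_gd(g, pos = c(100, 200))
  flt <- filter_variants(gd, maf = 0.05, max_missing = 0.8)
  expect_equal(flt$data$variants$pos, 200)
  # call rate exactly 0.8 is kept
  g2 <- cbind(site1 = c(rep(1, 8), NA, NA))
  expect_equal(ncol(filter_variants(make_toy_gd(g2, pos = 1),
                                    max_missing = 0.8)$data$geno), 1)
  # MAF 0.02 removed
  g3 <- cbind(rare = c(1, rep(0, 24)), common = rep(c(0, 1, 2, 1, 0), 5))
  flt3 <- filter_variants(make_toy_gd(g3, pos = c(10, 20)))
  expect_equal(flt3$data$variants$pos, 20)

  # 5-record toy: 1 indel, 1 multiallelic, 1 low-MAF, 2 clean -> 2 survive
  g5 <- matrix(rep(c(0, 1, 2, 1, 1), 5), nrow = 5)
  gd5 <- make_toy_gd(g5, pos = (1:5) * 100)
  gd5$variants$ref[1] <- "AT"          # indel
  gd5$variants$alt[2] <- "C,T"         # multiallelic
  gd5$geno[, 3] <- c(0, 0, 0, 0, 1)    # MAF 0.1 < ... keep; make it rare
  gd5$geno[, 3] <- c(0, 0, 0, 0, 0)    # monomorphic: MAF 0
  flt5 <- filter_variants(gd5)
  expect_equal(nrow(flt5$data$variants), 2)
  expect_equal(flt5$report$removed, c(2L, 1L, 0L))
})

test_that("VanRaden kinship matches the hand-computed toy", {
  gd <- make_toy_gd(rbind(c(0, 2), c(2, 0)), pos = c(10, 20))
  K <- grm_vanraden(gd)
  expect_equal(unname(K), rbind(c(2, -2), c(-2, 2)), tolerance = 1e-12)
  # duplicated individuals are maximally related
  g <- matrix(rbinom(60, 2, 0.4), nrow = 3)
  g <- rbind(g, g[3, ])
  K2 <- grm_vanraden(make_toy_gd(g, pos = seq_len(20)))
  expect_equal(K2[3, 4], K2[3, 3], tolerance = 1e-12)
  expect_equal(K2, t(K2), tolerance = 1e-12)
  expect_true(all(diag(K2) > 0))
})

test_that("LD pruning removes correlated SNPs (r2 by the textbook formula)", {
  set.seed(12)
  g <- matrix(rbinom(400, 2, 0.5), nrow = 40)
  g <- cbind(g, g[, 1])  # perfect copy of SNP 1
  keep <- ovisatlas:::ld_prune(g, window = 50, step = 5, r2 = 0.2)
  expect_true(keep[1])
  expect_false(keep[11])
  # r^2 between two dosage vectors equals the squared textbook Pearson
  r2 <- pearson_oracle(g[, 1], g[, 11])^2
  expect_equal(r2, 1, tolerance = 1e-12)
})

test_that("PCA covariates separate simulated populations and are orthonormal", {
  cfg <- small_scenario(fst_background = 0.1, sweep_hap_fraction = 0,
                        n_decoys = 0, n_variants = 800, missing_rate = 0)
  gd <- simulate_populations(cfg, seed = 31)
  pcs <- pca_covariates(gd, n_pcs = 3)
  expect_equal(unname(crossprod(pcs)), diag(3), tolerance = 1e-8)
  lab <- gd$samples$pop == "fat_tail"
  # linear separability along PC1: classify by the midpoint of class means
  mid <- mean(c(mean(pcs[lab, 1]), mean(pcs[!lab, 1])))
  side <- pcs[, 1] > mid
  acc <- max(mean(side == lab), mean(side == !lab))
  expect_gte(acc, 0.99)
})

test_that("REML null fit recovers heritability and flags a structureless kinship", {
  set.seed(13)
  n <- 300
  g <- matrix(rbinom(n * 400, 2, runif(400, 0.1, 0.9)), nrow = n, byrow = TRUE)
  K <- grm_vanraden(g)
  ek <- eigen(K, symmetric = TRUE)
  h2s <- vapply(1:5, function(s) {
    set.seed(100 + s)
    u <- (ek$vectors %*% (sqrt(pmax(ek$values, 0)) * rnorm(n)))[, 1] * sqrt(0.5)
    y <- 2 + u + rnorm(n, 0, sqrt(0.5))
    X <- design_matrix(NULL, n = n)
    fit_null_mlm(y, X, K)$h2
  }, 0)
  expect_lt(abs(median(h2s) - 0.5), 0.15)
  # K = I: profile flat in delta -> boundary with warning
  y <- rnorm(50)
  expect_warning(fit <- fit_null_mlm(y, design_matrix(NULL, n = 50), diag(50)),
                 "flat")
  expect_true(fit$flat)
  # optimum beats halving/doubling delta (non-degenerate case)
  fit2 <- suppressWarnings(
    fit_null_mlm(rnorm(n) + g[, 1], design_matrix(NULL, n = n), K))
  if (!fit2$flat) {
    expect_gte(fit2$loglik, fit2$reml(log10(fit2$delta * 2)) - 1e-6)
    expect_gte(fit2$loglik, fit2$reml(log10(fit2$delta / 2)) - 1e-6)
  }
  # rank-deficient design names the collinear column
  Xbad <- cbind(design_matrix(NULL, n = 50), dup = 1)
  expect_error(fit_null_mlm(rnorm(50), Xbad, diag(50) + 0.1), "dup")
})

test_that("the scan reduces to ordinary least squares when K carries no structure", {
  set.seed(14)
  n <- 80; M <- 40
  g <- matrix(rbinom(n * M, 2, 0.4), n, M)
  y <- rnorm(n) + 0.5 * g[, 7]
  gd <- make_toy_gd(g, pos = seq_len(M) * 100)
  X <- design_matrix(NULL, n = n)
  null <- suppressWarnings(fit_null_mlm(y, X, diag(n)))
  res <- association_scan(gd, null)
  ols_p <- vapply(seq_len(M), function(j)
    summary(lm(y ~ g[, j]))$coefficients[2, 4], 0)
  expect_equal(res$p, ols_p, tolerance = 1e-8)
  # monomorphic SNP gives NA with a warning
  g2 <- cbind(g, mono = 1)
  gd2 <- make_toy_gd(g2, pos = c(seq_len(M) * 100, 99999))
  expect_warning(res2 <- association_scan(gd2, null), "monomorphic")
  expect_true(is.na(res2$p[M + 1]))
  # results are independent of SNP order
  perm <- sample(M)
  gd3 <- make_toy_gd(g[, perm], pos = seq_len(M) * 100)
  res3 <- association_scan(gd3, null)
  expect_equal(res3$beta, res$beta[perm], tolerance = 1e-12)
})

test_that("Bonferroni threshold follows the closed form", {
  expect_equal(floor(bonferroni_threshold(21741684, 0.05) * 100) / 100, 8.63)
  expect_equal(bonferroni_threshold(100, 0.05), -log10(5e-4), tolerance = 1e-12)
  expect_equal(round(bonferroni_threshold(100), 4), 3.3010)
  expect_equal(round(bonferroni_threshold(1), 4), 1.3010)
  expect_error(bonferroni_threshold(0))
})
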