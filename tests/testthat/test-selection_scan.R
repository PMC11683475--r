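test_that("window construction keeps full windows only", {
  w <- make_windows(c(chr1 = 1e6))
  expect_equal(nrow(w), 12)
  expect_equal(c(w$start[12], w$end[12]), c(825000, 975000))
  expect_equal(nrow(make_windows(c(chr1 = 150000))), 1)
  expect_equal(nrow(make_windows(c(chr1 = 149999))), 0)
})

test_that("windowed FST matches the variance-component oracle and its identities", {
  win <- genomic_intervals("chr1", 0, 1000)
  # the 1-site toy: nA = nB = 4, pA = 0.75, pB = 0.25, two hets per pop
  gA <- matrix(c(2, 2, 1, 1), ncol = 1)
  gB <- matrix(c(0, 0, 1, 1), ncol = 1)
  gd <- make_toy_gd(rbind(gA, gB), pos = 500,
                    pop = rep(c("A", "B"), each = 4))
  f <- fst_windowed(gd, "A", "B", win)
  expect_equal(f$fst, wc_fst_oracle(gA, gB), tolerance = 1e-12)

  # multi-site toy with missing data against the per-site oracle
  set.seed(4)
  g <- matrix(sample(0:2, 80, replace = TRUE), nrow = 8)
  g[sample(length(g), 5)] <- NA
  gd2 <- make_toy_gd(g, pos = seq(50, 950, length.out = 10),
                     pop = rep(c("A", "B"), each = 4))
  f2 <- fst_windowed(gd2, "A", "B", win)
  expect_equal(f2$fst, wc_fst_oracle(g[1:4, ], g[5:8, ]), tolerance = 1e-12)

  # fixed difference: FST = 1
  gd3 <- make_toy_gd(matrix(c(0, 0, 0, 2, 2, 2), ncol = 1), pos = 10,
                     pop = rep(c("A", "B"), each = 3))
  expect_equal(fst_windowed(gd3, "A", "B", win)$fst, 1)

  # identical populations: near zero (exactly <= 0 in expectation)
  set.seed(5)
  base <- matrix(rbinom(3000, 2, 0.4), nrow = 30)
  gd4 <- make_toy_gd(base, pos = seq(1, 999, length.out = 100),
                     pop = rep(c("A", "B"), 15))
  expect_lt(abs(fst_windowed(gd4, "A", "B", win)$fst), 0.05)
})

test_that("windowed pi counts pairwise differences over the full window length", {
  win <- genomic_intervals("chr1", 0, 100)
  # one site, j = 2 alt alleles of n = 4: h = 2/3, pi = h / 100
  gd <- make_toy_gd(matrix(c(1, 1), ncol = 1), pos = 50)
  p <- pi_windowed(gd, NULL, win)
  expect_equal(p$pi, (2 / 3) / 100, tolerance = 1e-12)
  expect_equal(p$pi * 100, pi_site_oracle(c(1, 1)), tolerance = 1e-12)
  # REF/ALT swap invariance
  gd_swap <- make_toy_gd(matrix(c(1, 1), ncol = 1), pos = 50)
  gd_swap$geno[] <- 2 - gd_swap$geno
  expect_equal(pi_windowed(gd_swap, NULL, win)$pi, p$pi)
  # monomorphic window -> 0
  gd0 <- make_toy_gd(matrix(c(0, 0, 0), ncol = 1), pos = 50)
  expect_equal(pi_windowed(gd0, NULL, win)$pi, 0)
  # random toys against the all-pairs oracle (with missing data)
  set.seed(6)
  g <- matrix(sample(0:2, 50, replace = TRUE), nrow = 5)
  g[sample(length(g), 4)] <- NA
  gd2 <- make_toy_gd(g, pos = seq(5, 95, length.out = 10))
  oracle <- sum(vapply(seq_len(10), function(j)
    pi_site_oracle(g[, j]), 0), na.rm = TRUE) / 100
  expect_equal(pi_windowed(gd2, NULL, win)$pi, oracle, tolerance = 1e-12)
})

test_that("pi ratio divides windows elementwise and propagates missingness", {
  w <- genomic_intervals("chr1", c(0, 100, 200), c(100, 200, 300))
  pa <- w; pa$pi <- c(0.002, 0.001, 0.001); pa$n_variants <- 1L
  pb <- w; pb$pi <- c(0.001, 0.001, 0); pb$n_variants <- 1L
  pr <- pi_ratio(pa, pb)
  expect_equal(pr$pi_ratio, c(2, 1, NA))
})

test_that("EHH/iHH match the brute-force pairwise oracle on a haplotype toy", {
  haps <- rbind(c(1L, 1L, 0L, 1L, 0L),
                c(1L, 1L, 0L, 1L, 1L),
                c(0L, 0L, 1L, 0L, 0L),
                c(0L, 1L, 1L, 0L, 0L))
  gpos <- c(0, 0.3, 0.7, 1.1, 1.6)
  hs <- haplotype_set(haps, positions = c(100L, 400L, 700L, 1100L, 1600L),
                      chrom = rep("chr1", 5), gen_pos = gpos)
  for (core in 1:5) {
    impl <- ovisatlas:::ihh_site(haps, gpos, core, 0.05)
    expect_equal(impl, ihh_oracle(haps, gpos, core, 0.05), tolerance = 1e-12)
  }
  # identical haplotype sets give raw 0 wherever defined
  xp <- xpehh(hs, hs)
  expect_true(all(xp$xpehh_raw[!is.na(xp$xpehh_raw)] == 0))
  # antisymmetry: swapping populations negates the raw score exactly
  haps_b <- haps[c(2, 3, 4, 1), ]
  hs_b <- haplotype_set(haps_b, hs$positions, hs$chrom, gpos)
  ab <- xpehh(hs, hs_b)$xpehh_raw
  ba <- xpehh(hs_b, hs)$xpehh_raw
  expect_equal(ab, -ba)
})

test_that("XP-EHH standardization yields mean 0 sd 1 and window means aggregate", {
  set.seed(10)
  raw <- data.frame(chrom = "chr1", pos = seq(1000, 99000, by = 1000),
                    xpehh_raw = rnorm(99))
  z <- standardize_xpehh(raw)
  expect_equal(mean(z$xpehh_z), 0, tolerance = 1e-9)
  expect_equal(sd(z$xpehh_z), 1, tolerance = 1e-9)
  w <- genomic_intervals("chr1", c(0, 50000), c(50000, 100000))
  wz <- window_xpehh(z, w)
  expect_equal(wz$xpehh_mean[1], mean(z$xpehh_z[z$pos <= 50000]))
  expect_equal(wz$n_variants, c(50L, 49L))
})

test_that("top-quantile intersection selects and merges candidate windows", {
  w <- make_windows(c(chr1 = 1000 * 75000 + 75000))
  stopifnot(nrow(w) == 1000)
  w$fst <- 1:1000; w$pi_ratio <- 1:1000; w$xpehh_mean <- 1:1000
  top <- intersect_top_quantile(w, q = 0.005)
  expect_equal(nrow(top$candidate_windows), 5)
  expect_equal(top$candidate_windows$fst, 996:1000)
  expect_equal(nrow(top$regions), 1)  # overlapping windows merge
  # disjoint top sets give no candidates
  w$pi_ratio <- 1000:1
  expect_equal(nrow(intersect_top_quantile(w, q = 0.005)$candidate_windows), 0)
  # candidate count never exceeds ceil(q * N)
  set.seed(11)
  for (i in 1:5) {
    w$fst <- rnorm(1000); w$pi_ratio <- rnorm(1000); w$xpehh_mean <- rnorm(1000)
    n_sel <- nrow(intersect_top_quantile(w, q = 0.005)$candidate_windows)
    expect_lte(n_sel, ceiling(0.005 * 1000))
  }
})

test_that("the planted sweep intersects the candidate regions across seeds", {
  hit <- 0
  for (s in 1:5) {
    cfg <- scenario_config()
    gd <- simulate_populations(cfg, seed = 300 + s)
    scan <- run_selection_scan(gd, cfg$chrom_sizes, "thin_tail", "fat_tail")
    r <- scan$regions
    if (nrow(r) && any(r$chrom == cfg$sweep_chrom &
                       r$start < cfg$sweep_end & r$end > cfg$sweep_start))
      hit <- hit + 1
  }
  expect_gte(hit, 5 * 0.9)
})
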