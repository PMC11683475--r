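test_that("Poisson binarization thresholds counts against the background rate", {
  # track engineered so the genome-wide mean is exactly 1
  v <- c(rep(1, 93), 7, rep(0, 6))
  tr <- signal_track(list(chr1 = v), 200)
  b <- binarize_track(tr, 1e-4)
  expect_equal(attr(b, "lambda"), 1)
  # P(X >= 7 | 1) = 8.32e-5 < 1e-4 -> on; P(X >= 6 | 1) = 5.9e-4 -> off
  expect_equal(b$chr1[94], 1L)
  expect_equal(b$chr1[1], 0L)
  v6 <- c(rep(1, 94), 6, rep(0, 5))
  b6 <- binarize_track(signal_track(list(chr1 = v6), 200), 1e-4)
  expect_equal(b6$chr1[95], 0L)
  # zero counts are never called
  expect_true(all(b$chr1[v == 0] == 0L))
  # degenerate all-zero track warns and returns zeros
  expect_warning(bz <- binarize_track(signal_track(list(chr1 = rep(0, 10)), 200)),
                 "all-zero")
  expect_equal(bz$chr1, integer(10))
})

test_that("forward likelihood matches exhaustive path enumeration", {
  E <- rbind(c(0.9, 0.8, 0.2), c(0.1, 0.3, 0.7))
  Tm <- rbind(c(0.85, 0.15), c(0.4, 0.6))
  init <- c(0.6, 0.4)
  x <- rbind(c(1L, 1L, 0L), c(0L, 1L, 1L), c(1L, 0L, 0L))
  model <- structure(list(emissions = E, transitions = Tm, init = init),
                     class = "bernoulli_hmm")
  expect_equal(hmm_loglik(model, x), enumerate_loglik(E, Tm, init, x),
               tolerance = 1e-12)
})

test_that("Baum-Welch recovers a known 2-state model and decodes accurately", {
  E <- rbind(c(0.9, 0.9, 0.9), c(0.05, 0.05, 0.05))
  Tm <- rbind(c(0.9, 0.1), c(0.05, 0.95))
  truth <- structure(list(emissions = E, transitions = Tm,
                          init = c(0.5, 0.5)), class = "bernoulli_hmm")
  sim <- simulate_hmm_sequence(truth, 20000, seed = 42)
  fit <- train_hmm(sim$x, K = 2, n_restarts = 3, seed = 1)
  perm <- match_states(E, fit$emissions)
  expect_lt(max(abs(fit$emissions[perm, ] - E)), 0.05)
  seg <- decode_states(fit, sim$x)
  acc <- mean(seg$states$chr == perm[sim$states])
  expect_gte(acc, 0.95)
  # determinism: same data and seed give the identical model
  fit2 <- train_hmm(sim$x, K = 2, n_restarts = 3, seed = 1)
  expect_identical(fit$emissions, fit2$emissions)
  expect_identical(fit$loglik, fit2$loglik)
})

test_that("degenerate single-pattern data collapses gracefully", {
  x <- matrix(0L, 100, 3)
  expect_warning(fit <- train_hmm(x, K = 2, n_restarts = 2, seed = 1),
                 "distinct observed emission patterns")
  # all-zero data has likelihood ~ 1 per bin in the emission -> 0 limit
  expect_lt(abs(fit$loglik), 0.01)
})

test_that("segmentation partitions every bin exactly once", {
  E <- rbind(c(0.9, 0.9, 0.9), c(0.05, 0.05, 0.05))
  truth <- structure(list(emissions = E,
                          transitions = rbind(c(0.9, 0.1), c(0.1, 0.9)),
                          init = c(0.5, 0.5)), class = "bernoulli_hmm")
  sim <- simulate_hmm_sequence(truth, 500, seed = 8)
  seg <- decode_states(truth, list(c1 = sim$x, c2 = sim$x), bin_size = 200)
  iv <- seg$intervals
  for (ch in c("c1", "c2")) {
    d <- iv[iv$chrom == ch, ]
    expect_equal(d$start[1], 0)
    expect_equal(d$end[nrow(d)], 500 * 200)
    if (nrow(d) > 1) expect_equal(d$start[-1], d$end[-nrow(d)])
  }
  expect_equal(sum(state_coverage(seg)), 1, tolerance = 1e-9)
  # near-deterministic emissions force the matching state
  x_hi <- matrix(1L, 10, 3)
  seg_hi <- decode_states(truth, x_hi)
  expect_true(all(seg_hi$states$chr == 1L))
  # posterior and viterbi agree on unambiguous data
  seg_v <- decode_states(truth, x_hi, method = "viterbi")
  expect_identical(seg_hi$states$chr, seg_v$states$chr)
})

test_that("emission rule table labels the six canonical states", {
  E <- rbind(TssA = c(0.9, 0.9, 0.9),
             TssW = c(0.5, 0.8, 0.1),
             EnhA = c(0.9, 0.05, 0.9),
             EnhAW = c(0.5, 0.1, 0.35),
             ATAC_Is = c(0.9, 0.05, 0.05),
             Quies = c(0.05, 0.05, 0.05))
  model <- structure(list(emissions = unname(E)), class = "bernoulli_hmm")
  expect_equal(unname(label_states(model)),
               c("TssA", "TssW", "EnhA", "EnhAW", "ATAC_Is", "Quies"))
  # collision: two TssA-like states resolve by margin with a warning
  E2 <- E
  E2["TssW", ] <- c(0.8, 0.8, 0.8)
  model2 <- structure(list(emissions = unname(E2)), class = "bernoulli_hmm")
  expect_warning(lab2 <- label_states(model2), "map to")
  expect_equal(sum(lab2 == "TssA"), 1L)
  expect_equal(unname(lab2[1]), "TssA")  # larger margin keeps the label
})

test_that("TSS profiles align strand-aware and peak at the promoter", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      strand = c("+", "-"), tss = c(10001L, 30000L),
                      tes = c(12000L, 28000L))
  v <- numeric(200)
  v[(10000 %/% 200) + 1] <- 1   # bin containing g1 TSS
  v[((30000 - 1) %/% 200) + 1] <- 1
  tr <- signal_track(list(chr1 = v), 200)
  prof <- tss_profile(tr, genes, flank = 2000, bin = 200)
  expect_equal(prof$mean[prof$offset == 0], 1)
  expect_true(all(prof$mean[prof$offset != 0] == 0))
  # mirrored profile for the minus-strand gene: downstream bump flips
  v2 <- numeric(200)
  v2[((30000 - 1) %/% 200) + 1 - 2] <- 1   # 400 bp 3' of the "-" TSS in genome coords
  prof2 <- tss_profile(signal_track(list(chr1 = v2), 200),
                       genes[2, ], flank = 2000, bin = 200)
  expect_equal(prof2$mean[prof2$offset == 400], 1)
  expect_error(tss_profile(tr, genes, flank = 2100, bin = 200), "multiple")
})

test_that("nonredundant merging is idempotent and merges book-ended intervals", {
  a <- genomic_intervals("chr1", c(0, 100), c(100, 200))
  m <- merge_nonredundant(list(a, a, a))
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0, 200))
  # disjoint sets concatenate
  b <- genomic_intervals("chr1", 500, 600)
  m2 <- merge_nonredundant(list(a, b))
  expect_equal(nrow(m2), 2)
  # order invariance
  m3 <- merge_nonredundant(list(b, a))
  expect_equal(m2, m3)
})

test_that("tissue presence uses the 1-bp overlap rule", {
  nr <- genomic_intervals("chr1", c(0, 1000), c(500, 1600))
  t1 <- genomic_intervals("chr1", 0, 500)
  t2 <- genomic_intervals("chr1", c(499, 1000), c(600, 1600))  # 1-bp overlap with el 1
  t3 <- genomic_intervals("chr1", 1000, 1600)
  res <- call_tissue_specific(nr, list(a = t1, b = t2, c = t3))
  expect_equal(unname(res$presence[1, ]), c(1L, 1L, 0L))
  expect_equal(unname(res$presence[2, ]), c(0L, 1L, 1L))
  expect_equal(res$elements$category, c("shared", "shared"))
  # single-tissue element is specific; all-tissue element is common
  res2 <- call_tissue_specific(genomic_intervals("chr1", 0, 100),
                               list(a = t1, b = t2, c = t3))
  expect_equal(res2$elements$category, "specific")
  expect_equal(res2$elements$tissue, "a")
})

test_that("variability curve summarizes cumulative coverage by tissue count", {
  # all elements in exactly 1 tissue: f(1) = 1, summary 1
  el <- data.frame(start = c(0, 100), end = c(100, 200), n_tissues = c(1, 1))
  vc <- variability_curve(el, 9)
  expect_equal(vc$f[1], 1)
  expect_equal(vc$summary_k, 1)
  # all common over 9 tissues: f(k) = 0 for k < 9, summary 9
  el2 <- data.frame(start = 0, end = 100, n_tissues = 9)
  vc2 <- variability_curve(el2, 9)
  expect_equal(vc2$f, c(rep(0, 8), 1))
  expect_equal(vc2$summary_k, 9)
  # half specific, half common (equal bp): f(1) = 0.5, summary 9
  el3 <- data.frame(start = c(0, 100), end = c(100, 200), n_tissues = c(1, 9))
  vc3 <- variability_curve(el3, 9)
  expect_equal(vc3$f[1], 0.5)
  expect_equal(vc3$summary_k, 9)
  expect_true(all(diff(vc3$f) >= 0))
})
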