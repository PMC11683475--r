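# Independent brute-force oracles used to validate the package's
# statistics on small fixtures. These are written from the defining
# formulas with explicit loops and stay independent of the vectorized
# implementation paths they check.

# Weir & Cockerham (1984) variance components for one biallelic site,
# two populations, computed scalar-by-scalar.
wc_site_oracle <- function(gA, gB) {
  gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
  r <- 2
  n <- c(length(gA), length(gB))
  p <- c(sum(gA) / (2 * n[1]), sum(gB) / (2 * n[2]))
  h <- c(sum(gA == 1) / n[1], sum(gB == 1) / n[2])
  nbar <- sum(n) / r
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, abc = a + b + cc)
}

wc_fst_oracle <- function(gA_mat, gB_mat) {
  comps <- vapply(seq_len(ncol(gA_mat)), function(j)
    wc_site_oracle(gA_mat[, j], gB_mat[, j]), c(a = 0, abc = 0))
  sum(comps["a", ]) / sum(comps["abc", ])
}

# nucleotide diversity for one site by enumerating every pair of sampled
# alleles and counting differences
pi_site_oracle <- function(dosages) {
  alleles <- unlist(lapply(dosages[!is.na(dosages)], function(d)
    c(rep(1L, d), rep(0L, 2L - d))))
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  diffs <- 0; pairs <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    pairs <- pairs + 1
    if (alleles[i] != alleles[j]) diffs <- diffs + 1
  }
  diffs / pairs
}

# EHH over a span by enumerating all haplotype pairs and checking identity
ehh_span_oracle <- function(haps, cols) {
  n <- nrow(haps)
  cnt <- 0
  for (a in seq_len(n - 1)) for (b in seq(a + 1, n))
    if (all(haps[a, cols] == haps[b, cols])) cnt <- cnt + 1
  cnt / choose(n, 2)
}

# iHH by the stated contract: trapezoids accumulated while EHH >= cutoff,
# stopping without a partial segment at the first EHH < cutoff site
ihh_oracle <- function(haps, gpos, core, cutoff = 0.05) {
  e0 <- ehh_span_oracle(haps, core)
  if (e0 < cutoff) return(0)
  one_side <- function(idx) {
    e_prev <- e0; x_prev <- gpos[core]; ihh <- 0
    for (j in idx) {
      e <- ehh_span_oracle(haps, min(core, j):max(core, j))
      if (e < cutoff) break
      ihh <- ihh + (e_prev + e) / 2 * abs(gpos[j] - x_prev)
      e_prev <- e; x_prev <- gpos[j]
    }
    ihh
  }
  one_side(seq(core + 1, length.out = ncol(haps) - core)) +
    one_side(seq(core - 1, length.out = core - 1, by = -1))
}

# textbook Pearson correlation from raw sums
pearson_oracle <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# tau by an explicit per-element loop
tau_oracle <- function(x) {
  mx <- max(x)
  acc <- 0
  for (xi in x) acc <- acc + (1 - xi / mx)
  acc / (length(x) - 1)
}

# all permutations of a vector (for optimal HMM state matching, K <= 6)
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

# permutation p minimizing sum |E_est[p, ] - E_true|; truth state k
# corresponds to estimated state p[k]
match_states <- function(E_true, E_est) {
  best <- NULL; bd <- Inf
  for (p in all_perms(seq_len(nrow(E_true)))) {
    d <- sum(abs(E_est[p, , drop = FALSE] - E_true))
    if (d < bd) { bd <- d; best <- p }
  }
  best
}

# brute-force forward likelihood by enumerating all K^T state paths
enumerate_loglik <- function(emissions, trans, init, x) {
  K <- nrow(emissions); T_ <- nrow(x)
  paths <- expand.grid(rep(list(seq_len(K)), T_))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    path <- as.integer(paths[r, ])
    p <- init[path[1]]
    for (t in seq_len(T_)) {
      for (m in seq_len(ncol(x)))
        p <- p * (if (x[t, m] == 1) emissions[path[t], m]
                  else 1 - emissions[path[t], m])
      if (t > 1) p <- p * trans[path[t - 1], path[t]]
    }
    tot <- tot + p
  }
  log(tot)
}
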