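# Interval-overlap fold enrichment with a circular-permutation null,
# signal averaging over interval sets, and binned Pearson correlation.

interval_bp <- function(df) {
  if (!nrow(df)) return(0)
  sum(IRanges::width(GenomicRanges::reduce(intervals_to_granges(df))))
}

overlap_bp <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(0)
  ga <- GenomicRanges::reduce(intervals_to_granges(a))
  gb <- GenomicRanges::reduce(intervals_to_granges(b))
  sum(IRanges::width(GenomicRanges::intersect(ga, gb)))
}

#' Fold enrichment of a state within a feature set
#'
#' `fold = (overlap_bp / state_bp) / (feature_bp / genome_bp)` — the
#' ChromHMM OverlapEnrichment convention in base pairs; 1 means the overlap
#' matches the random expectation.
#'
#' @param state,feature interval data frames
#' @param genome_size total genome size in bp
#' @return list with overlap_bp, state_bp, feature_bp, genome_bp, fold
#'   (fold is NA when either set is empty)
#' @export
fold_enrichment <- function(state, feature, genome_size) {
  sbp <- interval_bp(state)
  fbp <- interval_bp(feature)
  obp <- overlap_bp(state, feature)
  fold <- if (sbp == 0 || fbp == 0) NA_real_
          else (obp / sbp) / (fbp / genome_size)
  list(overlap_bp = obp, state_bp = sbp, feature_bp = fbp,
       genome_bp = genome_size, fold = fold)
}

# circularly shift intervals on one chromosome by `off` bp, wrapping and
# splitting intervals that cross the origin
circular_shift <- function(df, chrom_sizes, offsets) {
  out <- lapply(unique(df$chrom), function(ch) {
    d <- df[df$chrom == ch, , drop = FALSE]
    L <- chrom_sizes[[ch]]
    off <- offsets[[ch]]
    s <- (d$start + off) %% L
    e <- s + (d$end - d$start)
    wrap <- e > L
    keep <- data.frame(chrom = ch, start = s[!wrap], end = e[!wrap])
    if (any(wrap)) {
      keep <- rbind(keep,
                    data.frame(chrom = ch, start = s[wrap], end = L),
                    data.frame(chrom = ch, start = 0, end = e[wrap] - L))
    }
    keep[keep$end > keep$start, , drop = FALSE]
  })
  validate_intervals(do.call(rbind, out))
}

# merge possibly-overlapping sorted intervals given as start/end vectors
merge_flat <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (length(start) > 1) {
    keep_s <- numeric(0); keep_e <- numeric(0)
    cs <- start[1]; ce <- end[1]
    for (i in seq(2, length(start))) {
      if (start[i] <= ce) ce <- max(ce, end[i])
      else { keep_s <- c(keep_s, cs); keep_e <- c(keep_e, ce)
             cs <- start[i]; ce <- end[i] }
    }
    start <- c(keep_s, cs); end <- c(keep_e, ce)
  }
  list(start = start, end = end)
}

# total bp overlap of one merged interval list with another (flat vectors)
overlap_bp_flat <- function(a, b) {
  if (!length(a$start) || !length(b$start)) return(0)
  tot <- 0
  j <- 1
  for (i in seq_along(a$start)) {
    while (j <= length(b$start) && b$end[j] <= a$start[i]) j <- j + 1
    k <- j
    while (k <= length(b$start) && b$start[k] < a$end[i]) {
      tot <- tot + min(a$end[i], b$end[k]) - max(a$start[i], b$start[k])
      k <- k + 1
    }
  }
  tot
}

#' Permutation p-value for fold enrichment
#'
#' The feature set is circularly shifted per chromosome by uniform random
#' offsets (preserving feature sizes and spacing) `n_perm` times;
#' `p = (1 + #{permuted fold >= observed}) / (n_perm + 1)`.
#'
#' @param state,feature interval data frames
#' @param chrom_sizes named chromosome lengths (genome size = their sum)
#' @param n_perm number of permutations (>= 100)
#' @param seed integer seed
#' @return list with observed `fold` and permutation `p`
#' @export
permutation_pvalue <- function(state, feature, chrom_sizes, n_perm = 1000,
                               seed = 1) {
  stopifnot(n_perm >= 100)
  genome_size <- sum(chrom_sizes)
  obs <- fold_enrichment(state, feature, genome_size)$fold
  # pre-merge the state per chromosome once; permutations then use flat
  # interval arithmetic (the GRanges layer adds nothing inside this loop)
  state_flat <- lapply(names(chrom_sizes), function(ch) {
    d <- state[state$chrom == ch, , drop = FALSE]
    merge_flat(d$start, d$end)
  })
  names(state_flat) <- names(chrom_sizes)
  feat_by_chr <- split(feature, feature$chrom)
  state_bp <- sum(vapply(state_flat, function(f) sum(f$end - f$start), 0))
  feature_bp <- interval_bp(feature)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ov <- 0
      for (ch in names(feat_by_chr)) {
        d <- feat_by_chr[[ch]]
        L <- chrom_sizes[[ch]]
        off <- sample.int(L, 1)
        s <- (d$start + off) %% L
        e <- s + (d$end - d$start)
        wrap <- e > L
        fs <- c(s[!wrap], s[wrap], rep(0, sum(wrap)))
        fe <- c(e[!wrap], rep(L, sum(wrap)), e[wrap] - L)
        keep <- fe > fs
        f <- merge_flat(fs[keep], fe[keep])
        ov <- ov + overlap_bp_flat(state_flat[[ch]], f)
      }
      if (state_bp == 0 || feature_bp == 0) NA_real_
      else (ov / state_bp) / (feature_bp / genome_size)
    }, 0)
  })
  p <- (1 + sum(perm >= obs, na.rm = TRUE)) / (n_perm + 1)
  list(fold = obs, p = p, perm_folds = perm)
}

#' Mean signal over interval sets
#'
#' Coverage-weighted mean of a binned signal track over each interval set
#' (e.g. average methylation per chromatin state).
#'
#' @param track a [signal_track()]
#' @param interval_sets named list of interval data frames
#' @return named numeric vector of means (NA for empty sets)
#' @export
signal_over_intervals <- function(track, interval_sets) {
  bs <- track$bin_size
  vapply(interval_sets, function(df) {
    if (is.null(df) || !nrow(df)) return(NA_real_)
    tot <- 0; wt <- 0
    for (ch in unique(df$chrom)) {
      v <- track$values[[ch]]
      if (is.null(v)) next
      d <- df[df$chrom == ch, , drop = FALSE]
      rec <- IRanges::IRanges(d$start + 1L, d$end)
      bins <- IRanges::IRanges((seq_along(v) - 1L) * bs + 1L, width = bs)
      hits <- IRanges::findOverlaps(rec, bins)
      ov <- IRanges::width(IRanges::pintersect(
        rec[S4Vectors::queryHits(hits)], bins[S4Vectors::subjectHits(hits)]))
      tot <- tot + sum(v[S4Vectors::subjectHits(hits)] * ov)
      wt <- wt + sum(ov)
    }
    if (wt == 0) NA_real_ else tot / wt
  }, 0)
}

# aggregate a signal track onto a coarser grid (target bin a multiple of
# the track bin) by mean
rebin_track <- function(track, bin) {
  if (bin == track$bin_size) return(track)
  if (bin %% track$bin_size != 0)
    stopf("target bin (%d) must be a multiple of the track bin (%d)",
          bin, track$bin_size)
  k <- bin %/% track$bin_size
  vals <- lapply(track$values, function(v) {
    n_out <- ceiling(length(v) / k)
    pad <- n_out * k - length(v)
    if (pad) v <- c(v, rep(NA_real_, pad))
    colMeans(matrix(v, nrow = k), na.rm = TRUE)
  })
  signal_track(vals, bin)
}

#' Pairwise Pearson correlation of binned tracks
#'
#' All tracks are re-binned to a common window size and correlated over
#' the concatenated genome.
#'
#' @param tracks named list of [signal_track()]s on a common genome
#' @param bin correlation window in bp (default 500)
#' @return symmetric correlation matrix with unit diagonal
#' @export
binned_correlation <- function(tracks, bin = 500) {
  stopifnot(length(tracks) >= 2, !is.null(names(tracks)))
  reb <- lapply(tracks, rebin_track, bin = bin)
  chroms <- names(reb[[1]]$values)
  mat <- vapply(reb, function(tr)
    unlist(tr$values[chroms], use.names = FALSE),
    numeric(sum(lengths(reb[[1]]$values[chroms]))))
  cor(mat)
}
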