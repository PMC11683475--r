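# Selection scans: sliding-window Weir-Cockerham FST, nucleotide diversity
# and its ratio, XP-EHH from phased haplotypes, and the top-quantile
# three-statistic intersection that defines candidate sweep regions.

#' Sliding windows over a genome
#'
#' Full windows only: starts at 0, step, 2*step, ... with
#' `start + window <= chromosome length`.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths
#' @param window window size in bp (default 150 kb)
#' @param step step in bp (default 75 kb)
#' @return `genomic_intervals` data frame of windows
#' @export
make_windows <- function(chrom_sizes, window = 150000, step = 75000) {
  out <- lapply(names(chrom_sizes), function(ch) {
    L <- chrom_sizes[[ch]]
    if (L < window) return(NULL)
    starts <- seq(0, L - window, by = step)
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(starts + window), stringsAsFactors = FALSE)
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out))
    return(genomic_intervals(character(0), integer(0), integer(0)))
  validate_intervals(do.call(rbind, out))
}

# map variant positions (1-based) to window rows; overlapping windows give
# multiple hits per site. Returns data.frame(site, win).
site_window_hits <- function(variants, windows) {
  gr_v <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(gr_v, intervals_to_granges(windows))
  data.frame(site = S4Vectors::queryHits(hits),
             win = S4Vectors::subjectHits(hits))
}

# Per-site Weir & Cockerham (1984) variance components for two populations.
# Returns list(a, abc, usable): among-population component a and total
# a + b + c per site, vectorized over sites.
wc_site_components <- function(gA, gB) {
  nA <- colSums(!is.na(gA)); nB <- colSums(!is.na(gB))
  usable <- nA >= 2 & nB >= 2
  pA <- colMeans(gA, na.rm = TRUE) / 2
  pB <- colMeans(gB, na.rm = TRUE) / 2
  hA <- colMeans(gA == 1, na.rm = TRUE)
  hB <- colMeans(gB == 1, na.rm = TRUE)
  r <- 2
  nbar <- (nA + nB) / r
  nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / (r * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, abc = a + b + cc, usable = usable)
}

#' Windowed Weir-Cockerham FST between two populations
#'
#' Per-site 1984 variance components, combined per window as the ratio of
#' sums `sum(a) / sum(a + b + c)` (the VCFtools "weighted" estimator);
#' negative window values are reported as-is. Windows with no usable site
#' get NA.
#'
#' @param gd `genotype_data` with a `pop` column in `$samples`
#' @param popA,popB population labels to compare
#' @param windows window table from [make_windows()]
#' @return the windows with `n_variants` and `fst` columns added
#' @export
fst_windowed <- function(gd, popA, popB, windows) {
  gA <- gd$geno[gd$samples$pop == popA, , drop = FALSE]
  gB <- gd$geno[gd$samples$pop == popB, , drop = FALSE]
  if (!nrow(gA) || !nrow(gB)) stopf("unknown population label")
  comp <- wc_site_components(gA, gB)
  hits <- site_window_hits(gd$variants, windows)
  hits <- hits[comp$usable[hits$site], , drop = FALSE]
  num <- tapply(comp$a[hits$site], hits$win, sum)
  den <- tapply(comp$abc[hits$site], hits$win, sum)
  nv <- table(hits$win)
  out <- windows
  out$n_variants <- 0L
  out$n_variants[as.integer(names(nv))] <- as.integer(nv)
  out$fst <- NA_real_
  idx <- as.integer(names(num))
  out$fst[idx] <- ifelse(den == 0, NA_real_, as.numeric(num) / as.numeric(den))
  out
}

#' Windowed nucleotide diversity
#'
#' Per-site heterozygosity `h = 2 j (n - j) / (n (n - 1))` from non-missing
#' allele counts (n alleles, j alt), summed per window and divided by the
#' full window length (the VCFtools `--window-pi` convention: monomorphic
#' and uncalled positions contribute zero difference but full length).
#'
#' @param gd `genotype_data`
#' @param pop population label (NULL = all individuals)
#' @param windows window table
#' @return the windows with `n_variants` and `pi` columns added
#' @export
pi_windowed <- function(gd, pop = NULL, windows) {
  g <- if (is.null(pop)) gd$geno else gd$geno[gd$samples$pop == pop, , drop = FALSE]
  n <- 2 * colSums(!is.na(g))
  j <- colSums(g, na.rm = TRUE)
  usable <- n >= 2
  h <- ifelse(usable, 2 * j * (n - j) / (n * pmax(n - 1, 1)), NA_real_)
  hits <- site_window_hits(gd$variants, windows)
  hits <- hits[usable[hits$site], , drop = FALSE]
  s <- tapply(h[hits$site], hits$win, sum)
  nv <- table(hits$win)
  out <- windows
  out$n_variants <- 0L
  out$n_variants[as.integer(names(nv))] <- as.integer(nv)
  out$pi <- 0
  out$pi[out$n_variants == 0] <- 0  # monomorphic windows: zero diversity
  idx <- as.integer(names(s))
  out$pi[idx] <- as.numeric(s) / (out$end[idx] - out$start[idx])
  out
}

#' Per-window nucleotide diversity ratio
#'
#' @param pi_a,pi_b window tables from [pi_windowed()] on identical windows;
#'   the ratio is A/B (record the orientation in your analysis)
#' @return windows with `pi_a`, `pi_b`, `pi_ratio` (NA when denominator 0)
#' @export
pi_ratio <- function(pi_a, pi_b) {
  stopifnot(nrow(pi_a) == nrow(pi_b),
            all(pi_a$start == pi_b$start), all(pi_a$chrom == pi_b$chrom))
  out <- pi_a[, c("chrom", "start", "end")]
  out$pi_a <- pi_a$pi
  out$pi_b <- pi_b$pi
  out$pi_ratio <- ifelse(is.na(pi_b$pi) | pi_b$pi == 0, NA_real_,
                         pi_a$pi / pi_b$pi)
  out
}

#' Construct a phased haplotype set
#'
#' @param haps haplotypes x variants 0/1 matrix (two rows per individual)
#' @param positions physical positions (1-based), strictly increasing within
#'   chromosome
#' @param chrom chromosome per variant
#' @param gen_pos genetic positions in cM; default uniform 1 cM/Mb
#' @return object of class `haplotype_set`
#' @export
haplotype_set <- function(haps, positions, chrom, gen_pos = NULL) {
  stopifnot(ncol(haps) == length(positions), all(haps %in% c(0L, 1L)))
  if (is.null(gen_pos)) gen_pos <- positions / 1e6
  for (ch in unique(chrom)) {
    p <- positions[chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) stopf("positions must be strictly increasing within chromosome")
  }
  structure(list(haps = haps, positions = positions, chrom = as.character(chrom),
                 gen_pos = gen_pos), class = "haplotype_set")
}

# EHH decay and truncated iHH for one core site within one chromosome block.
# Groups haplotypes by identity over the extended region (including the core
# allele); EHH(x) = sum over groups choose(c,2) / choose(n,2). iHH is the
# trapezoid integral over genetic distance, accumulated while EHH >= cutoff,
# stopping (without a partial segment) at the first site where EHH < cutoff.
ihh_one_side <- function(haps, gpos, core, direction, cutoff) {
  n <- nrow(haps)
  pairs_tot <- n * (n - 1) / 2
  g <- haps[, core] + 1L
  hom <- function(grp) {
    tab <- tabulate(grp)
    sum(tab * (tab - 1) / 2) / pairs_tot
  }
  ehh <- hom(g)
  if (ehh < cutoff) return(0)
  ihh <- 0
  idx <- if (direction > 0) seq(core + 1L, length.out = ncol(haps) - core)
         else seq(core - 1L, length.out = core - 1L, by = -1L)
  prev_e <- ehh
  prev_x <- gpos[core]
  for (j in idx) {
    key <- g * 2L + haps[, j]
    g <- match(key, unique.default(key))
    e <- hom(g)
    if (e < cutoff) break
    ihh <- ihh + (prev_e + e) / 2 * abs(gpos[j] - prev_x)
    prev_e <- e
    prev_x <- gpos[j]
  }
  ihh
}

ihh_site <- function(haps, gpos, core, cutoff) {
  ihh_one_side(haps, gpos, core, +1, cutoff) +
    ihh_one_side(haps, gpos, core, -1, cutoff)
}

#' Raw XP-EHH scores per site
#'
#' For each core site, the integrated extended haplotype homozygosity iHH is
#' computed in each population (trapezoid integral of EHH over genetic
#' distance, truncated at the first EHH < `ehh_cutoff` crossing on each
#' side); the raw score is `ln(iHH_A / iHH_B)`, NA where either iHH is 0.
#'
#' @param hap_a,hap_b `haplotype_set`s for the two populations sharing
#'   variants and positions
#' @param ehh_cutoff EHH truncation cutoff (default 0.05)
#' @return data frame: chrom, pos, xpehh_raw
#' @export
xpehh <- function(hap_a, hap_b, ehh_cutoff = 0.05) {
  stopifnot(identical(hap_a$positions, hap_b$positions),
            identical(hap_a$chrom, hap_b$chrom))
  raw <- rep(NA_real_, length(hap_a$positions))
  for (ch in unique(hap_a$chrom)) {
    sel <- which(hap_a$chrom == ch)
    A <- hap_a$haps[, sel, drop = FALSE]
    B <- hap_b$haps[, sel, drop = FALSE]
    gp <- hap_a$gen_pos[sel]
    for (i in seq_along(sel)) {
      ia <- ihh_site(A, gp, i, ehh_cutoff)
      ib <- ihh_site(B, gp, i, ehh_cutoff)
      if (ia > 0 && ib > 0) raw[sel[i]] <- log(ia / ib)
    }
  }
  data.frame(chrom = hap_a$chrom, pos = hap_a$positions, xpehh_raw = raw,
             stringsAsFactors = FALSE)
}

#' Standardize raw XP-EHH scores genome-wide
#' @param scores data frame from [xpehh()] (or a numeric vector)
#' @return same shape with `xpehh_z = (raw - mean) / sd`
#' @export
standardize_xpehh <- function(scores) {
  if (is.numeric(scores)) {
    return((scores - mean(scores, na.rm = TRUE)) / sd(scores, na.rm = TRUE))
  }
  scores$xpehh_z <- (scores$xpehh_raw - mean(scores$xpehh_raw, na.rm = TRUE)) /
    sd(scores$xpehh_raw, na.rm = TRUE)
  scores
}

#' Per-window mean of standardized XP-EHH
#' @param scores data frame with chrom, pos, xpehh_z
#' @param windows window table
#' @return windows with `n_variants` and `xpehh_mean` added
#' @export
window_xpehh <- function(scores, windows) {
  ok <- !is.na(scores$xpehh_z)
  hits <- site_window_hits(
    data.frame(chrom = scores$chrom, pos = scores$pos), windows)
  hits <- hits[ok[hits$site], , drop = FALSE]
  m <- tapply(scores$xpehh_z[hits$site], hits$win, mean)
  nv <- table(hits$win)
  out <- windows
  out$n_variants <- 0L
  out$n_variants[as.integer(names(nv))] <- as.integer(nv)
  out$xpehh_mean <- NA_real_
  out$xpehh_mean[as.integer(names(m))] <- as.numeric(m)
  out
}

#' Top-quantile intersection of window statistics
#'
#' Per statistic, windows at or above the (1 - q) quantile are selected
#' (ties included); candidates are windows selected by all statistics,
#' merged into regions when overlapping or adjacent.
#'
#' @param windows window table carrying the statistic columns
#' @param stats character vector of column names (default fst, pi_ratio,
#'   xpehh_mean)
#' @param q upper-tail fraction (default 0.005, i.e. top 5 per mille)
#' @return list with `selected` (logical matrix windows x stats),
#'   `candidate_windows` (subset of windows) and `regions` (merged
#'   `genomic_intervals`)
#' @export
intersect_top_quantile <- function(windows,
                                   stats = c("fst", "pi_ratio", "xpehh_mean"),
                                   q = 0.005) {
  miss <- setdiff(stats, names(windows))
  if (length(miss)) stopf("window table lacks statistic column(s): %s",
                          paste(miss, collapse = ", "))
  sel <- vapply(stats, function(s) {
    v <- windows[[s]]
    thr <- quantile(v, 1 - q, na.rm = TRUE, names = FALSE)
    !is.na(v) & v >= thr
  }, logical(nrow(windows)))
  if (is.null(dim(sel))) sel <- matrix(sel, nrow = nrow(windows),
                                       dimnames = list(NULL, stats))
  all_sel <- rowSums(sel) == length(stats)
  cand <- windows[all_sel, , drop = FALSE]
  regions <- if (nrow(cand)) {
    granges_to_intervals(GenomicRanges::reduce(intervals_to_granges(
      cand[, c("chrom", "start", "end")])))
  } else genomic_intervals(character(0), integer(0), integer(0))
  list(selected = sel, candidate_windows = cand, regions = regions)
}
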