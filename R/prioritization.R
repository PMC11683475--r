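# The causal-variant funnel: significant GWAS SNPs intersected with sweep
# regions, open chromatin and H3K27ac peaks, annotated by TAD co-membership
# with candidate genes, then tested for genotype-stratified expression and
# ranked.

point_in_intervals <- function(chrom, pos, intervals) {
  # pos is 1-based (VCF); interval membership uses the 0-based point with
  # half-open intervals, so a SNP at an interval's end coordinate is outside
  if (!nrow(intervals)) return(rep(FALSE, length(pos)))
  gr_p <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  IRanges::overlapsAny(gr_p, intervals_to_granges(intervals))
}

union_peaks <- function(peak_sets) {
  if (inherits(peak_sets, "data.frame")) return(validate_intervals(peak_sets))
  merge_nonredundant(peak_sets)
}

#' Run the causal-variant prioritization funnel
#'
#' Stage 1 keeps SNPs with `-log10 p` above the threshold; stage 2
#' intersects with sweep regions; stage 3 requires residence in both the
#' union-of-replicates open-chromatin peaks and the union-of-replicates
#' H3K27ac peaks; stage 4 annotates the TAD containing each SNP and every
#' gene whose TSS lies in that TAD (SNPs outside any TAD are retained with
#' no linked genes).
#'
#' @param assoc association results (id, chrom, pos, neglog10p)
#' @param threshold genome-wide `-log10 p` significance threshold
#' @param sweeps sweep-region intervals
#' @param ocr_peaks open-chromatin peak intervals: a data frame or a list of
#'   per-replicate data frames (union taken)
#' @param k27ac_peaks H3K27ac peak intervals, same form
#' @param tads TAD intervals (a `name` column is used as TAD id if present)
#' @param genes gene-model data frame
#' @return object of class `funnel_report`: `stages` (per-stage counts) and
#'   `candidates` (variant table with provenance flags and linked genes)
#' @export
funnel <- function(assoc, threshold, sweeps, ocr_peaks, k27ac_peaks, tads,
                   genes) {
  ocr <- union_peaks(ocr_peaks)
  k27 <- union_peaks(k27ac_peaks)
  tads <- validate_intervals(tads)
  if (is.null(tads$name))
    tads$name <- sprintf("%s:%d-%d", tads$chrom, tads$start, tads$end)

  cand <- assoc[!is.na(assoc$neglog10p), , drop = FALSE]
  n0 <- nrow(cand)
  s1 <- cand[cand$neglog10p > threshold, , drop = FALSE]
  s1$in_sweep <- point_in_intervals(s1$chrom, s1$pos, sweeps)
  s2 <- s1[s1$in_sweep, , drop = FALSE]
  s2$in_ocr <- point_in_intervals(s2$chrom, s2$pos, ocr)
  s2$in_k27ac <- point_in_intervals(s2$chrom, s2$pos, k27)
  s3 <- s2[s2$in_ocr & s2$in_k27ac, , drop = FALSE]

  s3$tad <- rep(NA_character_, nrow(s3))
  s3$linked_genes <- vector("list", nrow(s3))
  if (nrow(s3)) {
    gr_p <- GenomicRanges::GRanges(s3$chrom, IRanges::IRanges(s3$pos, width = 1L))
    gr_t <- intervals_to_granges(tads)
    hits <- GenomicRanges::findOverlaps(gr_p, gr_t, select = "first")
    s3$tad <- tads$name[hits]
    gr_tss <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(genes$tss, width = 1L))
    tss_tad <- GenomicRanges::findOverlaps(gr_tss, gr_t, select = "first")
    for (i in seq_len(nrow(s3))) {
      if (is.na(s3$tad[i])) next
      s3$linked_genes[[i]] <- genes$gene_id[!is.na(tss_tad) &
                                              tads$name[tss_tad] == s3$tad[i]]
    }
  }
  stages <- data.frame(
    stage = c("tested", "significant", "in_sweep", "in_peaks"),
    n = c(n0, nrow(s1), nrow(s2), nrow(s3)))
  structure(list(stages = stages, candidates = s3,
                 significant = s1, in_sweep = s2),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Prioritization funnel:\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Genotype-stratified expression test
#'
#' One-way ANOVA of per-individual expression across genotype classes at a
#' candidate variant (Kruskal-Wallis via `method`). Requires at least two
#' genotype classes with at least `min_per_class` individuals each.
#'
#' @param expr numeric expression vector (one gene) or genes x individuals
#'   matrix
#' @param dosage genotype dosages (0/1/2/NA) aligned with individuals
#' @param method "anova" (default) or "kruskal"
#' @param min_per_class minimum class size (default 3)
#' @return named p-value vector (one per gene); NA with a warning when the
#'   class structure is insufficient
#' @export
genotype_expression_test <- function(expr, dosage,
                                     method = c("anova", "kruskal"),
                                     min_per_class = 3) {
  method <- match.arg(method)
  if (is.null(dim(expr))) expr <- matrix(expr, nrow = 1,
                                         dimnames = list("gene", NULL))
  stopifnot(ncol(expr) == length(dosage))
  ok <- !is.na(dosage)
  cls <- factor(dosage[ok])
  sizes <- table(cls)
  usable <- names(sizes)[sizes >= min_per_class]
  if (length(usable) < 2) {
    warnf("fewer than two genotype classes with >= %d individuals; returning NA",
          min_per_class)
    return(setNames(rep(NA_real_, nrow(expr)), rownames(expr)))
  }
  keep <- ok
  keep[ok] <- cls %in% usable
  g <- factor(dosage[keep])
  p <- apply(expr[, keep, drop = FALSE], 1, function(e) {
    if (method == "anova") {
      anova(lm(e ~ g))[["Pr(>F)"]][1]
    } else {
      kruskal.test(e, g)$p.value
    }
  })
  setNames(p, rownames(expr))
}

#' Per-population alternate-allele frequencies
#'
#' @param dosage dosage vector (0/1/2/NA)
#' @param pops population labels aligned with individuals
#' @return named vector: `sum(dosage) / (2 * n_called)` per population
#' @export
allele_freq_by_population <- function(dosage, pops) {
  stopifnot(length(dosage) == length(pops))
  vapply(split(dosage, pops), function(d) {
    d <- d[!is.na(d)]
    if (!length(d)) return(NA_real_)
    sum(d) / (2 * length(d))
  }, 0)
}

#' Rank funnel candidates
#'
#' Primary key: minimum linked-gene expression-test p (ascending, missing
#' last); secondary: GWAS `-log10 p` (descending); ties broken by genomic
#' coordinate for determinism.
#'
#' @param report `funnel_report`
#' @param expr_tests data frame with columns `variant_id`, `gene_id`, `p`
#'   (per linked gene, as from [genotype_expression_test()])
#' @return candidate table with `min_expr_p` and `rank` columns, ordered
#' @export
rank_candidates <- function(report, expr_tests = NULL) {
  cand <- report$candidates
  if (!nrow(cand)) {
    cand$min_expr_p <- numeric(0)
    cand$rank <- integer(0)
    return(cand)
  }
  min_p <- rep(NA_real_, nrow(cand))
  if (!is.null(expr_tests) && nrow(expr_tests)) {
    agg <- tapply(expr_tests$p, expr_tests$variant_id, min, na.rm = TRUE)
    agg[!is.finite(agg)] <- NA_real_
    min_p <- as.numeric(agg[match(cand$id, names(agg))])
  }
  cand$min_expr_p <- min_p
  ord <- order(is.na(min_p), min_p, -cand$neglog10p, cand$chrom, cand$pos)
  cand <- cand[ord, , drop = FALSE]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  cand
}
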