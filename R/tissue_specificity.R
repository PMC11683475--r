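# Tissue-specificity of expression: TPM normalization, the tau index, and
# grouping of genes by how many strong enhancers they overlap.

#' Normalize a count matrix to transcripts per million
#'
#' `TPM_g = 1e6 * (count_g / length_g) / sum_h(count_h / length_h)` per
#' sample (column).
#'
#' @param counts genes x samples non-negative count matrix
#' @param lengths gene lengths in bp, aligned with rows (named or positional)
#' @return TPM matrix; every column sums to 1e6
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  stopifnot(length(lengths) == nrow(counts))
  if (any(lengths <= 0)) stopf("gene lengths must be positive")
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) stopf("sample with zero total expression")
  sweep(rate, 2, tot, "/") * 1e6
}

#' Tau tissue-specificity index
#'
#' For an expression vector x over n tissues, `tau = sum(1 - x_i/max(x)) /
#' (n - 1)`: 0 for uniform expression, 1 for single-tissue expression.
#'
#' @param x non-negative expression vector, n >= 2 tissues
#' @return tau in \[0, 1\]; NA with a warning for an all-zero vector
#' @export
tau <- function(x) {
  stopifnot(length(x) >= 2)
  if (any(x < 0, na.rm = TRUE)) stopf("tau is defined for non-negative expression")
  mx <- max(x)
  if (is.na(mx) || mx == 0) {
    warnf("all-zero expression vector: tau undefined")
    return(NA_real_)
  }
  sum(1 - x / mx) / (length(x) - 1)
}

#' Call tissue-specific genes by tau
#'
#' A gene is tissue-specific iff tau strictly exceeds the threshold
#' (tau = threshold exactly is NOT specific); the assigned tissue is the
#' argmax of expression, ties resolved to the lowest tissue index with a
#' warning.
#'
#' @param expr genes x tissues expression matrix (TPM)
#' @param threshold tau cutoff (default 0.8)
#' @return data frame: gene_id, tau, tissue, specific
#' @export
call_specific_genes <- function(expr, threshold = 0.8) {
  expr <- as.matrix(expr)
  taus <- apply(expr, 1, function(v) suppressWarnings(tau(v)))
  argmax <- apply(expr, 1, function(v) {
    w <- which(v == max(v))
    if (length(w) > 1 && max(v) > 0)
      warnf("expression tie for argmax tissue; using the lowest index")
    w[1]
  })
  tissues <- colnames(expr) %||% paste0("tissue", seq_len(ncol(expr)))
  data.frame(gene_id = rownames(expr) %||% as.character(seq_len(nrow(expr))),
             tau = taus,
             tissue = tissues[argmax],
             specific = !is.na(taus) & taus > threshold,
             stringsAsFactors = FALSE)
}

#' Group genes by the number of overlapping strong enhancers
#'
#' Counts EnhA intervals overlapping each gene body (TSS to TES, >= 1 bp)
#' and bins genes into three groups; genes overlapping no enhancer are
#' excluded.
#'
#' @param genes gene-model data frame
#' @param enh_intervals EnhA interval data frame
#' @param boundaries two integers `c(a, b)`: groups are `count <= a`,
#'   `a < count <= b`, `count > b` (default `c(1, 5)`, i.e. 1 / 2-5 / >=6)
#' @param region "body" (default) counts overlap with the gene body;
#'   "promoter" with a 2-kb window centered on the TSS
#' @return data frame gene_id, n_enhancers, group (factor)
#' @export
group_by_enhancer_count <- function(genes, enh_intervals,
                                    boundaries = c(1, 5),
                                    region = c("body", "promoter")) {
  region <- match.arg(region)
  stopifnot(length(boundaries) == 2, boundaries[1] < boundaries[2])
  if (region == "body") {
    gstart <- pmin(genes$tss, genes$tes)
    gend <- pmax(genes$tss, genes$tes)
  } else {
    gstart <- pmax(genes$tss - 1000L, 1L)
    gend <- genes$tss + 1000L
  }
  gr_g <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(gstart, gend))
  counts <- if (nrow(enh_intervals)) {
    GenomicRanges::countOverlaps(gr_g, intervals_to_granges(enh_intervals))
  } else rep(0L, length(gr_g))
  lab <- c(sprintf("1-%d", boundaries[1]),
           sprintf("%d-%d", boundaries[1] + 1, boundaries[2]),
           sprintf(">=%d", boundaries[2] + 1))
  grp <- cut(counts, breaks = c(0, boundaries, Inf), labels = lab)
  out <- data.frame(gene_id = genes$gene_id, n_enhancers = counts,
                    group = grp, stringsAsFactors = FALSE)
  out[counts > 0, , drop = FALSE]
}
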