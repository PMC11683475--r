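# End-to-end wiring: GWAS scan, three-statistic selection scan, and the
# prioritization funnel on a truth bundle (or equivalently structured
# inputs). This is the reference composition of the package's modules.

# split a bundle's phased haplotypes into per-population haplotype sets
bundle_haplotype_sets <- function(gd) {
  v <- gd$variants
  lapply(split(seq_len(nrow(gd$haplotypes)), gd$hap_pop), function(rows)
    haplotype_set(gd$haplotypes[rows, , drop = FALSE], v$pos, v$chrom))
}

#' Run the GWAS arm of the pipeline
#'
#' Filters variants, builds VanRaden kinship and LD-pruned PCA covariates,
#' fits the REML null with birthplace/batch/season and the top PCs as
#' fixed effects, and scans all SNPs under the P3D approximation.
#'
#' @param gd `genotype_data`
#' @param phenotypes phenotype data frame (covariate columns + trait)
#' @param trait trait column name (default "tail_fat_weight")
#' @param covariate_cols factor covariate columns
#' @param n_pcs number of PCA covariates (default 3)
#' @param maf,max_missing variant filters
#' @return list: assoc (scan table), threshold (Bonferroni -log10), null,
#'   filtered (genotype_data), lambda (genomic control)
#' @export
run_gwas <- function(gd, phenotypes, trait = "tail_fat_weight",
                     covariate_cols = c("birthplace", "batch", "season"),
                     n_pcs = 3, maf = 0.05, max_missing = 0.8) {
  stopifnot(trait %in% names(phenotypes))
  flt <- filter_variants(gd, maf = maf, max_missing = max_missing)
  fgd <- flt$data
  K <- grm_vanraden(fgd)
  pcs <- pca_covariates(fgd, n_pcs = n_pcs)
  X <- design_matrix(cbind(phenotypes[, covariate_cols, drop = FALSE],
                           as.data.frame(pcs)))
  y <- phenotypes[[trait]]
  null <- fit_null_mlm(y, X, K)
  assoc <- association_scan(fgd, null)
  list(assoc = assoc, threshold = bonferroni_threshold(nrow(assoc)),
       null = null, filtered = fgd, filter_report = flt$report,
       lambda = genomic_lambda(assoc$p))
}

#' Run the selection-scan arm of the pipeline
#'
#' Windowed Weir-Cockerham FST between reference and swept populations,
#' per-population nucleotide diversity and the reference/swept ratio, and
#' windowed standardized XP-EHH oriented as ln(iHH_swept / iHH_reference),
#' so all three statistics are high inside a sweep in the swept population;
#' candidates are their top-quantile intersection.
#'
#' @param gd genotypes carrying phased `haplotypes` (as from
#'   [simulate_populations()])
#' @param chrom_sizes named chromosome lengths
#' @param ref_pop,swept_pop population labels
#' @param window,step scan window geometry (default 150 kb / 75 kb)
#' @param q top quantile for the intersection (default 0.005)
#' @return list: windows (with fst, pi_ratio, xpehh_mean), regions
#'   (candidate sweep intervals), selection (per-statistic logical matrix)
#' @export
run_selection_scan <- function(gd, chrom_sizes, ref_pop, swept_pop,
                               window = 150000, step = 75000, q = 0.005) {
  win <- make_windows(chrom_sizes, window, step)
  fst <- fst_windowed(gd, ref_pop, swept_pop, win)
  pi_ref <- pi_windowed(gd, ref_pop, win)
  pi_swp <- pi_windowed(gd, swept_pop, win)
  pr <- pi_ratio(pi_ref, pi_swp)
  hs <- bundle_haplotype_sets(gd)
  xp <- standardize_xpehh(xpehh(hs[[swept_pop]], hs[[ref_pop]]))
  xpw <- window_xpehh(xp, win)
  win$n_variants <- fst$n_variants
  win$fst <- fst$fst
  win$pi_ref <- pr$pi_a
  win$pi_swept <- pr$pi_b
  win$pi_ratio <- pr$pi_ratio
  win$xpehh_mean <- xpw$xpehh_mean
  top <- intersect_top_quantile(win, q = q)
  list(windows = win, regions = top$regions, selection = top$selected,
       xpehh = xp)
}

#' Run the full prioritization pipeline on a truth bundle
#'
#' GWAS scan + selection scan + funnel (open chromatin and H3K27ac peaks
#' restricted to one tissue, union of replicates) + genotype-stratified
#' expression tests + ranking.
#'
#' @param bundle `truth_bundle` from [make_truth_bundle()]
#' @param trait trait column (default "tail_fat_weight")
#' @param tissue tissue whose peaks gate the funnel (default the scenario's
#'   adipose analog)
#' @param q top quantile for the sweep candidate intersection
#' @return list with gwas, scan, funnel, expr_tests, ranked
#' @export
run_prioritization <- function(bundle, trait = "tail_fat_weight",
                               tissue = NULL, q = 0.005) {
  cfg <- bundle$config
  tissue <- tissue %||% cfg$adipose_tissue
  ref_pop <- setdiff(cfg$pop_names, cfg$swept_pop)[1]
  gwas <- run_gwas(bundle$genotypes, bundle$phenotypes, trait = trait)
  scan <- run_selection_scan(bundle$genotypes, cfg$chrom_sizes,
                             ref_pop = ref_pop, swept_pop = cfg$swept_pop,
                             q = q)
  pk <- bundle$epigenome$peaks[[tissue]]
  rep_list <- function(mark) list(pk[[mark]]$rep1, pk[[mark]]$rep2)
  fun <- funnel(gwas$assoc, gwas$threshold, scan$regions,
                rep_list("ATAC"), rep_list("H3K27ac"),
                bundle$tads, bundle$genes)
  expr_tests <- NULL
  cand <- fun$candidates
  if (nrow(cand)) {
    rows <- list()
    for (i in seq_len(nrow(cand))) {
      genes_i <- cand$linked_genes[[i]]
      if (!length(genes_i)) next
      genes_i <- intersect(genes_i, rownames(bundle$expression$indiv_expr))
      if (!length(genes_i)) next
      dos <- bundle$genotypes$geno[, cand$id[i]]
      p <- genotype_expression_test(
        bundle$expression$indiv_expr[genes_i, , drop = FALSE], dos)
      rows[[length(rows) + 1]] <- data.frame(
        variant_id = cand$id[i], gene_id = names(p), p = unname(p),
        stringsAsFactors = FALSE)
    }
    if (length(rows)) expr_tests <- do.call(rbind, rows)
  }
  ranked <- rank_candidates(fun, expr_tests)
  list(gwas = gwas, scan = scan, funnel = fun, expr_tests = expr_tests,
       ranked = ranked)
}
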