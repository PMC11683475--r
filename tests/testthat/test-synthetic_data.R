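test_that("genotype simulation is deterministic and plants its controls", {
  cfg <- small_scenario()
  gd1 <- simulate_populations(cfg, seed = 11)
  gd2 <- simulate_populations(cfg, seed = 11)
  expect_identical(gd1$geno, gd2$geno)
  expect_identical(gd1$haplotypes, gd2$haplotypes)
  gd3 <- simulate_populations(cfg, seed = 12)
  expect_false(identical(gd1$geno, gd3$geno))

  expect_true(gd1$causal_id %in% gd1$variants$id)
  expect_length(gd1$decoy_ids, cfg$n_decoys)
  # decoys carry the causal genotype column (missingness is masked per
  # genotype afterwards, so compare where both are called)
  for (d in gd1$decoy_ids) {
    both <- !is.na(gd1$geno[, d]) & !is.na(gd1$geno[, gd1$causal_id])
    expect_identical(unname(gd1$geno[both, d]),
                     unname(gd1$geno[both, gd1$causal_id]))
    expect_gt(sum(both), 100)
  }
  # no bystander SNP inside the causal enhancer
  v <- gd1$variants
  in_enh <- v$chrom == cfg$sweep_chrom &
    v$pos - 1 >= cfg$causal_enhancer[1] & v$pos - 1 < cfg$causal_enhancer[2]
  expect_equal(v$id[in_enh], gd1$causal_id)
})

test_that("windowed FST vanishes without differentiation and flags the sweep", {
  win <- make_windows(c(chr1 = 3e6, chr2 = 3e6))
  # near-zero F: expected FST ~ 0 in every window
  cfg0 <- small_scenario(fst_background = 1e-7, fst_sweep = 0.5,
                         sweep_hap_fraction = 0, n_decoys = 0)
  gd0 <- simulate_populations(cfg0, seed = 3)
  f0 <- fst_windowed(gd0, "thin_tail", "fat_tail", win)
  outside <- !(f0$chrom == "chr1" & f0$start < 1050000 & f0$end > 900000)
  expect_lt(abs(mean(f0$fst[outside], na.rm = TRUE)), 0.01)

  # F_sweep = 0.5 vs F = 0.02: sweep windows exceed background, each seed
  cfg <- small_scenario()
  for (s in 1:3) {
    gd <- simulate_populations(cfg, seed = s)
    f <- fst_windowed(gd, "thin_tail", "fat_tail", win)
    inside <- f$chrom == "chr1" & f$start >= 900000 & f$end <= 1050000
    expect_gt(mean(f$fst[inside], na.rm = TRUE),
              mean(f$fst[!inside], na.rm = TRUE))
  }
})

test_that("phenotypes respond to the planted causal variant as constructed", {
  cfg <- small_scenario()
  gd <- simulate_populations(cfg, seed = 5)
  ph <- simulate_phenotypes(gd, cfg, seed = 6)
  g <- gd$geno[, gd$causal_id]
  means <- tapply(ph$tail_fat_weight, g, mean)
  expect_true(all(diff(means[as.character(0:2)]) > 0))
  expect_true(all(c("tail_fat_weight", "carcass_weight", "rel_tail_fat")
                  %in% names(ph)))
  # null scenario: no causal effect, no polygenic signal
  cfg0 <- small_scenario(causal_beta = 0, h2 = 0)
  ph0 <- simulate_phenotypes(gd, cfg0, seed = 6)
  fit <- anova(lm(tail_fat_weight ~ factor(g), data = ph0))
  expect_gt(fit[["Pr(>F)"]][1], 0.001)
})

test_that("epigenome tracks realize the planted architecture", {
  cfg <- small_scenario()
  genes <- make_gene_models(cfg)
  epi <- simulate_epigenome(cfg, genes, seed = 9)
  ts <- cfg$adipose_tissue
  # foreground exceedance of the binarization threshold matches the
  # Poisson tail-sum oracle (lambda_fg = 10 against the fitted threshold)
  atac <- epi$tracks[[ts]]$ATAC
  bin <- binarize_track(atac)
  thr <- attr(bin, "threshold_count")
  # Poisson upper tail by iterative term accumulation (no ppois)
  term <- exp(-cfg$lambda_fg)
  tail_oracle <- 0
  for (k in 0:300) {
    if (k >= thr) tail_oracle <- tail_oracle + term
    term <- term * cfg$lambda_fg / (k + 1)
  }
  fg_states <- c(1L, 3L, 5L)  # states with ATAC at the enriched rate
  fg_bins <- lapply(names(atac$values), function(ch)
    bin[[ch]][epi$true_states[[ts]][[ch]] %in% fg_states])
  frac <- mean(unlist(fg_bins))
  expect_lt(abs(frac - tail_oracle), 0.05)

  # quiescent-only tissue signal stays at background: almost nothing called
  q_bins <- unlist(lapply(names(atac$values), function(ch)
    bin[[ch]][epi$true_states[[ts]][[ch]] == 6L]))
  expect_lt(mean(q_bins), 1e-3)

  # planted tissue-specific enhancers: EnhA elements present in exactly one
  # tissue, one (or more) per tissue, and the shared enhancers are common
  enha_sets <- lapply(epi$true_states, function(chroms) {
    iv <- do.call(rbind, lapply(names(chroms), function(ch) {
      r <- rle(chroms[[ch]] == 3L)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths
      if (!any(r$values)) return(NULL)
      data.frame(chrom = ch, start = starts[r$values] * cfg$bin_size,
                 end = ends[r$values] * cfg$bin_size)
    }))
    validate_intervals(iv)
  })
  nr <- merge_nonredundant(enha_sets)
  spec <- call_tissue_specific(nr, enha_sets)
  specific <- spec$elements[spec$elements$category == "specific", ]
  expect_setequal(unique(specific$tissue), cfg$tissues)
  expect_true(any(spec$elements$category == "common"))
})

test_that("the causal variant is the funnel's positive control by construction", {
  cfg <- small_scenario()
  b <- make_truth_bundle(cfg, seed = 21)
  pk <- b$epigenome$peaks[[cfg$adipose_tissue]]
  pos <- cfg$causal_pos
  in_peak <- function(p) any(p$chrom == cfg$sweep_chrom &
                               p$start <= pos - 1 & p$end > pos - 1)
  expect_true(in_peak(pk$ATAC$rep1))
  expect_true(in_peak(pk$H3K27ac$rep1))
  # causal TAD contains the target gene TSS
  tads <- b$tads
  tad <- tads[tads$chrom == cfg$sweep_chrom & tads$start <= pos - 1 &
                tads$end > pos - 1, ]
  tg <- b$genes[b$genes$gene_id == cfg$target_gene, ]
  expect_true(tg$tss - 1 >= tad$start && tg$tss - 1 < tad$end)
  # decoys lie outside both peak sets
  v <- b$genotypes$variants
  for (d in b$genotypes$decoy_ids) {
    dpos <- v$pos[v$id == d]
    expect_false(any(pk$ATAC$rep1$chrom == cfg$sweep_chrom &
                       pk$ATAC$rep1$start <= dpos - 1 &
                       pk$ATAC$rep1$end > dpos - 1) &&
                 any(pk$H3K27ac$rep1$chrom == cfg$sweep_chrom &
                       pk$H3K27ac$rep1$start <= dpos - 1 &
                       pk$H3K27ac$rep1$end > dpos - 1))
  }
})

test_that("written bundles validate under the readers and hash reproducibly", {
  cfg <- small_scenario()
  d1 <- file.path(tempdir(), "bundle1")
  b <- make_truth_bundle(cfg, seed = 4, out_dir = d1)
  gd <- read_vcf(file.path(d1, "genotypes.vcf"))
  expect_equal(gd$geno, b$genotypes$geno)
  tads <- read_bed(file.path(d1, "tads.bed"))
  expect_equal(nrow(tads), nrow(b$tads))
  tr <- read_bedgraph(file.path(d1, "tracks/tail_fat_ATAC.bedgraph"),
                      cfg$bin_size, cfg$chrom_sizes)
  expect_equal(tr$values$chr1, b$epigenome$tracks$tail_fat$ATAC$values$chr1)
  genes <- read_gene_models(file.path(d1, "genes.tsv"))
  expect_setequal(genes$gene_id, b$genes$gene_id)

  m1 <- jsonlite::read_json(file.path(d1, "manifest.json"))
  d2 <- file.path(tempdir(), "bundle2")
  make_truth_bundle(cfg, seed = 4, out_dir = d2)
  m2 <- jsonlite::read_json(file.path(d2, "manifest.json"))
  expect_identical(m1$config_md5, m2$config_md5)
  expect_identical(unname(tools::md5sum(file.path(d1, "genotypes.vcf"))),
                   unname(tools::md5sum(file.path(d2, "genotypes.vcf"))))
  unlink(c(d1, d2), recursive = TRUE)
})
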