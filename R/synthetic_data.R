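# Seeded generators for every input the pipeline consumes, with planted
# ground truth: a differentiated sweep carrying a causal regulatory variant
# inside a tissue-specific enhancer, a polygenic phenotype responding to
# that variant, per-tissue mark tracks realizing a 6-state chromatin
# architecture, tissue-specific expression, and TADs linking the variant to
# its target gene.

#' Scenario configuration for the synthetic truth bundle
#'
#' Defaults define the package's standard study conditions: two populations
#' (a "thin_tail" reference and a "fat_tail" swept population, 200 diploids
#' each) on a 2 x 3 Mb genome with ~4000 SNPs; Balding-Nichols
#' differentiation F = 0.02 genome-wide and F_sweep = 0.5 for the swept
#' population inside chr1:900,000-1,050,000 (one full 150-kb scan window);
#' a causal variant at chr1:975,000 inside a 2-kb tail-fat-specific
#' enhancer, carried by an extended haplotype copied into 85% of the swept
#' population (a nearly complete sweep, consistent with the near-fixed
#' haplotype blocks such scans detect); h2 = 0.3 and a causal effect of one
#' phenotypic SD per
#' allele; nine tissues with promoter/enhancer/ATAC-island architecture at
#' Poisson rates 1 (background), 4 (weak) and 10 (enriched) per 200-bp bin.
#'
#' @param ... named overrides of any default listed above
#' @return object of class `scenario_config`
#' @export
scenario_config <- function(...) {
  cfg <- list(
    chrom_sizes = c(chr1 = 3e6, chr2 = 3e6),
    pop_names = c("thin_tail", "fat_tail"),
    pop_sizes = c(thin_tail = 200, fat_tail = 200),
    swept_pop = "fat_tail",
    fst_background = 0.02,
    fst_sweep = 0.5,
    sweep_chrom = "chr1",
    sweep_start = 900000, sweep_end = 1050000,  # 0-based half-open
    sweep_hap_fraction = 0.85,
    n_variants = 4000,
    missing_rate = 0.01,
    causal_pos = 975000,          # 1-based
    causal_beta = 1,              # phenotypic SDs per alt allele
    causal_ref_freq = 0.05,       # alt frequency off the swept haplotype
    causal_enhancer = c(974000, 976000),  # 0-based half-open
    h2 = 0.3,
    covariate_effects = list(
      birthplace = c(north = 0, central = 0.5, south = -0.4),
      batch = c(b1 = 0, b2 = 0.3, b3 = -0.3, b4 = 0.2),
      season = c(spring = 0, autumn = 0.4)),
    tissues = c("cartilage", "cecum", "pituitary", "hypothalamus", "liver",
                "longissimus_dorsi", "rumen", "spleen", "tail_fat"),
    adipose_tissue = "tail_fat",
    bin_size = 200,
    lambda_bg = 1, lambda_mid = 4, lambda_fg = 10,
    tad_size = 300000,
    target_gene = "gene_bmp2l",
    expr_hi = 200, expr_lo = 10, expr_mid = 50, expr_sdlog = 0.4,
    target_expr_base = 100, target_expr_sd = 20, target_delta = 1,
    n_decoys = 20)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stopf("unknown scenario field(s): %s",
                             paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_scenario(cfg)
}

validate_scenario <- function(cfg) {
  if (!(cfg$fst_background > 0 && cfg$fst_background < cfg$fst_sweep &&
        cfg$fst_sweep < 1))
    stopf("require 0 < F < F_sweep < 1")
  if (cfg$h2 < 0 || cfg$h2 >= 1) stopf("h2 must be in [0, 1)")
  if (cfg$lambda_fg <= cfg$lambda_bg)
    stopf("lambda_fg must exceed lambda_bg (states unidentifiable)")
  L <- cfg$chrom_sizes[[cfg$sweep_chrom]]
  if (is.null(L) || cfg$sweep_end > L || cfg$sweep_start < 0 ||
      cfg$sweep_end <= cfg$sweep_start)
    stopf("sweep region outside genome")
  enh <- cfg$causal_enhancer
  if (!(cfg$causal_pos - 1 >= enh[1] && cfg$causal_pos - 1 < enh[2]))
    stopf("causal variant must lie inside its enhancer")
  if (!(enh[1] >= cfg$sweep_start && enh[2] <= cfg$sweep_end))
    stopf("causal enhancer must lie inside the sweep region")
  if (!(cfg$swept_pop %in% cfg$pop_names)) stopf("swept_pop not in pop_names")
  structure(cfg, class = "scenario_config")
}

#' Deterministic gene models for a scenario
#'
#' Genes are laid on a regular grid (20-kb bodies every 120 kb, alternating
#' strand), with the sweep neighbourhood on the sweep chromosome kept free
#' of gene promoters; the target gene and two neighbours are placed in the
#' TAD downstream of the sweep so that only the planted enhancer carries
#' regulatory signal inside the sweep itself.
#'
#' @param cfg `scenario_config`
#' @return gene-model data frame (see [read_gene_models()])
#' @export
make_gene_models <- function(cfg) {
  rows <- list()
  excl_lo <- cfg$sweep_start - 30000
  excl_hi <- cfg$sweep_start + cfg$tad_size + 160000
  for (ch in names(cfg$chrom_sizes)) {
    L <- cfg$chrom_sizes[[ch]]
    starts <- seq(20000, L - 30000, by = 120000)
    if (ch == cfg$sweep_chrom)
      starts <- starts[starts < excl_lo | starts > excl_hi]
    for (i in seq_along(starts)) {
      s <- starts[i]
      strand <- if (i %% 2 == 1) "+" else "-"
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = sprintf("gene_%s_%03d", ch, i), chrom = ch,
        strand = strand, start = s, end = s + 20000,
        stringsAsFactors = FALSE)
    }
  }
  tad0 <- (cfg$sweep_start %/% cfg$tad_size) * cfg$tad_size
  anchor <- max(cfg$sweep_end, tad0) + 10000
  extra <- data.frame(
    gene_id = c(cfg$target_gene, "gene_tadneighbor1", "gene_tadneighbor2"),
    chrom = cfg$sweep_chrom, strand = c("+", "+", "-"),
    start = c(anchor + 40000, anchor, anchor + 100000),
    end = c(anchor + 60000, anchor + 20000, anchor + 120000),
    stringsAsFactors = FALSE)
  g <- rbind(do.call(rbind, rows), extra)
  g$length <- g$end - g$start + 1L
  g$tss <- ifelse(g$strand == "+", g$start, g$end)
  g$tes <- ifelse(g$strand == "+", g$end, g$start)
  g[order(g$chrom, g$start),
    c("gene_id", "chrom", "strand", "tss", "tes", "start", "end", "length")]
}

#' Deterministic TAD intervals for a scenario
#' @param cfg `scenario_config`
#' @return TAD interval data frame (tiling each chromosome)
#' @export
make_tads <- function(cfg) {
  out <- lapply(names(cfg$chrom_sizes), function(ch) {
    L <- cfg$chrom_sizes[[ch]]
    starts <- seq(0, L - 1, by = cfg$tad_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + cfg$tad_size, L),
               name = sprintf("TAD_%s_%02d", ch, seq_along(starts)),
               stringsAsFactors = FALSE)
  })
  validate_intervals(do.call(rbind, out))
}

#' Simulate multi-population genotypes with a planted sweep
#'
#' Per-variant ancestral frequencies are uniform on (0.05, 0.95);
#' per-population frequencies follow the Balding-Nichols Beta model with
#' F = `fst_background`, except inside the sweep region where the swept
#' population drifts at `fst_sweep`. Phased haplotypes are drawn binomially;
#' inside the sweep one extended core haplotype (carrying the causal alt
#' allele) is copied into `sweep_hap_fraction` of the swept population's
#' haplotypes, giving XP-EHH its haplotype-homozygosity signal. A set of
#' decoy variants in the sweep receives the causal variant's genotype
#' column verbatim (perfect LD): significant by construction, outside all
#' peaks — the funnel's negative controls.
#'
#' @param cfg `scenario_config`
#' @param seed integer seed
#' @return `genotype_data` augmented with `haplotypes` (2n x M 0/1 matrix),
#'   `hap_pop`, `causal_id`, `decoy_ids`, `sweep_region`
#' @export
simulate_populations <- function(cfg, seed = 1) {
  enh <- cfg$causal_enhancer
  with_seed(seed, {
    # variant positions, proportional to chromosome size, keeping the causal
    # enhancer free of bystander SNPs
    sizes <- cfg$chrom_sizes
    n_per <- round(cfg$n_variants * sizes / sum(sizes))
    pos_list <- lapply(names(sizes), function(ch) {
      p <- sort(sample.int(sizes[[ch]] - 1L, n_per[[ch]]))
      if (ch == cfg$sweep_chrom) {
        inside_enh <- p - 1 >= enh[1] & p - 1 < enh[2]
        p <- p[!inside_enh]
        p <- sort(unique(c(p, cfg$causal_pos)))
      }
      p
    })
    chrom <- rep(names(sizes), lengths(pos_list))
    pos <- unlist(pos_list, use.names = FALSE)
    M <- length(pos)
    anc <- runif(M, 0.05, 0.95)
    in_sweep <- chrom == cfg$sweep_chrom & pos - 1 >= cfg$sweep_start &
      pos - 1 < cfg$sweep_end
    causal_idx <- which(chrom == cfg$sweep_chrom & pos == cfg$causal_pos)
    stopifnot(length(causal_idx) == 1)

    pops <- rep(cfg$pop_names, cfg$pop_sizes[cfg$pop_names])
    n_ind <- length(pops)
    haps <- matrix(0L, 2 * n_ind, M)
    hap_pop <- rep(pops, each = 2)
    pfreq_swept <- NULL
    for (pp in cfg$pop_names) {
      F_vec <- rep(cfg$fst_background, M)
      if (pp == cfg$swept_pop) F_vec[in_sweep] <- cfg$fst_sweep
      Fs <- pmax(F_vec, 1e-12)
      pfreq <- rbeta(M, anc * (1 - Fs) / Fs, (1 - anc) * (1 - Fs) / Fs)
      pfreq[F_vec < 1e-6] <- anc[F_vec < 1e-6]
      if (pp == cfg$swept_pop) pfreq_swept <- pfreq
      rows <- which(hap_pop == pp)
      haps[rows, ] <- matrix(
        rbinom(length(rows) * M, 1L, rep(pfreq, each = length(rows))),
        length(rows), M)
    }
    # causal allele: rare off the swept haplotype
    swept_rows <- which(hap_pop == cfg$swept_pop)
    other_rows <- which(hap_pop != cfg$swept_pop)
    haps[swept_rows, causal_idx] <- rbinom(length(swept_rows), 1L, 0.02)
    haps[other_rows, causal_idx] <- rbinom(length(other_rows), 1L,
                                           cfg$causal_ref_freq)
    # extended core haplotype copied into a fraction of the swept
    # population; its alleles follow the swept population's own drifted
    # frequencies (a sweep amplifies an existing haplotype), so copying
    # reduces diversity there rather than adding it
    sweep_idx <- which(in_sweep)
    core_pattern <- rbinom(length(sweep_idx), 1L, pfreq_swept[sweep_idx])
    core_pattern[sweep_idx == causal_idx] <- 1L
    carriers <- swept_rows[runif(length(swept_rows)) < cfg$sweep_hap_fraction]
    haps[carriers, sweep_idx] <- rep(core_pattern, each = length(carriers))

    # decoys: evenly spaced sweep variants receiving the causal column;
    # kept clear of the enhancer plus one bin of margin so they stay
    # outside every peak replicate (replicate 2 is widened by one bin)
    margin <- cfg$bin_size
    near_enh <- pos - 1 >= enh[1] - margin & pos - 1 < enh[2] + margin
    decoy_pool <- setdiff(sweep_idx[!near_enh[sweep_idx]], causal_idx)
    n_dec <- min(cfg$n_decoys, length(decoy_pool))
    decoy_idx <- decoy_pool[round(seq(1, length(decoy_pool),
                                      length.out = n_dec))]
    haps[, decoy_idx] <- haps[, causal_idx]

    geno <- haps[seq(1, 2 * n_ind, by = 2), ] + haps[seq(2, 2 * n_ind, by = 2), ]
    storage.mode(geno) <- "double"
    if (cfg$missing_rate > 0) {
      miss <- matrix(runif(n_ind * M) < cfg$missing_rate, n_ind, M)
      geno[miss] <- NA_real_
    }
    refs <- c("A", "G")[pos %% 2 + 1]
    alts <- c("C", "T")[pos %% 2 + 1]
    variants <- data.frame(chrom = chrom, pos = pos,
                           id = paste0(chrom, ":", pos),
                           ref = refs, alt = alts, stringsAsFactors = FALSE)
    samples <- data.frame(id = sprintf("ind_%04d", seq_len(n_ind)),
                          pop = pops, stringsAsFactors = FALSE)
    gd <- genotype_data(geno, variants, samples)
    gd$haplotypes <- haps
    gd$hap_pop <- hap_pop
    gd$causal_id <- variants$id[causal_idx]
    gd$decoy_ids <- variants$id[decoy_idx]
    gd$sweep_region <- genomic_intervals(cfg$sweep_chrom, cfg$sweep_start,
                                         cfg$sweep_end)
    gd
  })
}

#' Simulate phenotypes over simulated genotypes
#'
#' `y = mu + covariate effects + beta * g_causal + u + e`, with
#' `u ~ N(0, sigma_g^2 K)` (VanRaden kinship of the simulated genotypes)
#' and variances set from h2 on a unit phenotypic-variance scale. Emits the
#' primary trait (tail fat weight analog), an independent carcass-weight
#' trait, and their ratio.
#'
#' @param gd genotypes from [simulate_populations()]
#' @param cfg `scenario_config`
#' @param seed integer seed
#' @return phenotype data frame: id, pop, birthplace, batch, season,
#'   tail_fat_weight, carcass_weight, rel_tail_fat
#' @export
simulate_phenotypes <- function(gd, cfg, seed = 1) {
  if (is.null(gd$causal_id) || !(gd$causal_id %in% gd$variants$id))
    stopf("causal variant missing from genotype matrix")
  n <- nrow(gd$geno)
  g <- gd$geno[, gd$causal_id]
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  with_seed(seed, {
    covar <- lapply(cfg$covariate_effects, function(eff)
      sample(names(eff), n, replace = TRUE))
    fixed <- Reduce(`+`, Map(function(lv, eff) unname(eff[lv]),
                             covar, cfg$covariate_effects))
    sigma_g2 <- cfg$h2
    sigma_e2 <- 1 - cfg$h2
    u <- if (sigma_g2 > 0) {
      K <- grm_vanraden(gd)
      ek <- eigen(K, symmetric = TRUE)
      (ek$vectors %*% (sqrt(pmax(ek$values, 0)) * rnorm(n)))[, 1] *
        sqrt(sigma_g2)
    } else numeric(n)
    e <- rnorm(n, 0, sqrt(sigma_e2))
    tail_fat <- 1.5 + fixed + cfg$causal_beta * g + u + e
    carcass <- rnorm(n, 25, 2)
    data.frame(id = gd$samples$id, pop = gd$samples$pop,
               birthplace = covar$birthplace, batch = covar$batch,
               season = covar$season,
               tail_fat_weight = tail_fat, carcass_weight = carcass,
               rel_tail_fat = tail_fat / carcass,
               stringsAsFactors = FALSE)
  })
}

# deterministic regulatory architecture: per tissue, per chromosome, a list
# of (start, end, state) elements on top of a quiescent background.
# States: 1 TssA, 2 TssW, 3 EnhA, 4 EnhAW, 5 ATAC_Is, 6 Quies.
scenario_architecture <- function(cfg, genes) {
  tissues <- cfg$tissues
  slot_pos <- function(L) seq(80000, L - 10000, by = 120000)
  arch <- list()
  add <- function(tissue, chrom, start, end, state) {
    arch[[tissue]][[chrom]] <<- rbind(
      arch[[tissue]][[chrom]],
      data.frame(start = start, end = end, state = state))
  }
  for (ts in tissues) arch[[ts]] <- list()
  specific_genes <- tissue_specific_genes(cfg, genes)
  for (ch in names(cfg$chrom_sizes)) {
    L <- cfg$chrom_sizes[[ch]]
    slots <- slot_pos(L)
    if (ch == cfg$sweep_chrom) {
      excl <- slots >= cfg$sweep_start - 30000 &
        slots < cfg$sweep_start + cfg$tad_size + 160000
      free <- slots[!excl]
    } else free <- slots
    need <- 8 + length(tissues)
    if (length(free) < need)
      stopf("chromosome %s too short for the planted architecture", ch)
    sel <- floor(seq(1, length(free), length.out = need))
    shared_enh <- free[sel[1:3]]
    weak_enh <- free[sel[4:5]]
    atac_is <- free[sel[6:8]]
    ts_slots <- free[sel[9:need]]
    gch <- genes[genes$chrom == ch, , drop = FALSE]
    for (ts in tissues) {
      # promoters at every TSS; tissue-specific genes get TssA only at home
      for (i in seq_len(nrow(gch))) {
        own <- specific_genes$tissue[match(gch$gene_id[i],
                                           specific_genes$gene_id)]
        st <- if (!is.na(own) && own != ts) 2L else 1L
        p0 <- max(gch$tss[i] - 1 - 400, 0)
        add(ts, ch, p0, p0 + 800, st)
      }
      for (s in shared_enh) add(ts, ch, s, s + 2000, 3L)
      for (s in weak_enh) add(ts, ch, s, s + 2000, 4L)
      for (s in atac_is) add(ts, ch, s, s + 1000, 5L)
      add(ts, ch, ts_slots[match(ts, tissues)],
          ts_slots[match(ts, tissues)] + 2000, 3L)
      if (ch == cfg$sweep_chrom && ts == cfg$adipose_tissue)
        add(ts, ch, cfg$causal_enhancer[1], cfg$causal_enhancer[2], 3L)
    }
  }
  arch
}

# which genes are designated tissue-specific (one per tissue on the
# non-sweep chromosome, plus the target gene in the adipose analog)
tissue_specific_genes <- function(cfg, genes) {
  other_chrom <- setdiff(names(cfg$chrom_sizes), cfg$sweep_chrom)[1]
  cand <- genes$gene_id[genes$chrom == other_chrom]
  if (length(cand) < length(cfg$tissues))
    stopf("not enough genes on %s to designate one specific gene per tissue",
          other_chrom)
  picks <- cand[seq_along(cfg$tissues)]
  data.frame(gene_id = c(picks, cfg$target_gene),
             tissue = c(cfg$tissues, cfg$adipose_tissue),
             stringsAsFactors = FALSE)
}

# per-state Poisson rates for the three marks (ATAC, H3K4me3, H3K27ac)
state_mark_rates <- function(cfg) {
  rbind(TssA    = c(cfg$lambda_fg, cfg$lambda_fg, cfg$lambda_fg),
        TssW    = c(cfg$lambda_mid, cfg$lambda_mid, cfg$lambda_bg),
        EnhA    = c(cfg$lambda_fg, cfg$lambda_bg, cfg$lambda_fg),
        EnhAW   = c(cfg$lambda_mid, cfg$lambda_bg, cfg$lambda_mid),
        ATAC_Is = c(cfg$lambda_fg, cfg$lambda_bg, cfg$lambda_bg),
        Quies   = c(cfg$lambda_bg, cfg$lambda_bg, cfg$lambda_bg))
}

#' Simulate per-tissue epigenomic mark tracks and peak calls
#'
#' Realizes the planted 6-state architecture
#' (promoter/enhancer/ATAC-island/quiescent) as Poisson bin counts for
#' ATAC, H3K4me3 and H3K27ac per tissue: each state's defining marks emit
#' at the enriched rate, weak states at the intermediate rate, everything
#' else at background. Peak BEDs are the planted enriched intervals per
#' mark and tissue, in two replicates (replicate 2 widened by one bin per
#' side as deterministic jitter).
#'
#' @param cfg `scenario_config`
#' @param genes gene models from [make_gene_models()]
#' @param seed integer seed
#' @return list with `tracks` (tissue -> mark -> [signal_track()]),
#'   `true_states` (tissue -> chrom -> integer state vector),
#'   `state_labels`, `peaks` (tissue -> mark -> list(rep1, rep2)) and
#'   `specific_genes`
#' @export
simulate_epigenome <- function(cfg, genes, seed = 1) {
  labels <- c("TssA", "TssW", "EnhA", "EnhAW", "ATAC_Is", "Quies")
  marks <- c("ATAC", "H3K4me3", "H3K27ac")
  rates <- state_mark_rates(cfg)
  bs <- cfg$bin_size
  arch <- scenario_architecture(cfg, genes)
  n_bins <- ceiling(cfg$chrom_sizes / bs)
  with_seed(seed, {
    out_tracks <- list(); out_states <- list(); out_peaks <- list()
    for (ts in cfg$tissues) {
      states <- lapply(names(cfg$chrom_sizes), function(ch) {
        s <- rep(6L, n_bins[[ch]])
        el <- arch[[ts]][[ch]]
        if (!is.null(el)) for (i in seq_len(nrow(el))) {
          b0 <- el$start[i] %/% bs + 1L
          b1 <- (el$end[i] - 1L) %/% bs + 1L
          s[b0:b1] <- el$state[i]
        }
        s
      })
      names(states) <- names(cfg$chrom_sizes)
      tr <- lapply(seq_along(marks), function(m) {
        vals <- lapply(states, function(s)
          as.numeric(rpois(length(s), rates[s, m])))
        signal_track(vals, bs)
      })
      names(tr) <- marks
      pk <- lapply(seq_along(marks), function(m) {
        enriched <- which(rates[, m] > cfg$lambda_bg)
        iv <- do.call(rbind, lapply(names(states), function(ch) {
          s <- states[[ch]] %in% enriched
          if (!any(s)) return(NULL)
          r <- rle(s)
          ends <- cumsum(r$lengths); starts <- ends - r$lengths
          data.frame(chrom = ch, start = starts[r$values] * bs,
                     end = ends[r$values] * bs, stringsAsFactors = FALSE)
        }))
        if (is.null(iv))
          iv <- genomic_intervals(character(0), integer(0), integer(0))
        rep1 <- validate_intervals(iv)
        rep2 <- rep1
        if (nrow(rep2)) {
          rep2$start <- pmax(rep2$start - bs, 0)
          rep2$end <- pmin(rep2$end + bs, cfg$chrom_sizes[rep2$chrom])
        }
        list(rep1 = rep1, rep2 = validate_intervals(rep2))
      })
      names(pk) <- marks
      out_tracks[[ts]] <- tr
      out_states[[ts]] <- states
      out_peaks[[ts]] <- pk
    }
    list(tracks = out_tracks, true_states = out_states,
         state_labels = labels, peaks = out_peaks,
         specific_genes = tissue_specific_genes(cfg, genes))
  })
}

#' Simulate expression: gene-by-tissue counts and per-individual expression
#'
#' Designated tissue-specific genes express at `expr_hi` in their home
#' tissue and `expr_lo` elsewhere (log-normal noise), planting tau > 0.8;
#' all other genes are housekeeping at `expr_mid`. The target gene's
#' per-individual expression is `base + delta * g_causal + noise` with
#' `delta` in units of the expression SD; the TAD neighbours do not respond
#' to genotype.
#'
#' @param cfg `scenario_config`
#' @param gd genotypes from [simulate_populations()]
#' @param genes gene models
#' @param seed integer seed
#' @return list with `counts` (genes x tissues integer matrix),
#'   `gene_lengths`, `indiv_expr` (TAD genes x individuals),
#'   `specific_genes`
#' @export
simulate_expression <- function(cfg, gd, genes, seed = 1) {
  if (cfg$expr_hi <= cfg$expr_lo) stopf("expr_hi must exceed expr_lo")
  if (!(cfg$target_gene %in% genes$gene_id))
    stopf("target gene missing from gene models")
  spec <- tissue_specific_genes(cfg, genes)
  tissues <- cfg$tissues
  with_seed(seed, {
    mu <- matrix(cfg$expr_mid, nrow(genes), length(tissues),
                 dimnames = list(genes$gene_id, tissues))
    for (i in seq_len(nrow(spec))) {
      mu[spec$gene_id[i], ] <- cfg$expr_lo
      mu[spec$gene_id[i], spec$tissue[i]] <- cfg$expr_hi
    }
    noise <- matrix(rlnorm(length(mu), 0, cfg$expr_sdlog), nrow(mu))
    lam <- mu * noise * genes$length / 1000
    counts <- matrix(rpois(length(lam), lam), nrow(lam),
                     dimnames = dimnames(mu))
    # per-individual expression for genes in the causal TAD
    tads <- make_tads(cfg)
    tad_hit <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(cfg$sweep_chrom,
                             IRanges::IRanges(cfg$causal_pos, width = 1L)),
      intervals_to_granges(tads), select = "first")
    tad_id <- tads$name[tad_hit]
    gr_tss <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(genes$tss, width = 1L))
    hit <- GenomicRanges::findOverlaps(gr_tss, intervals_to_granges(tads),
                                       select = "first")
    tad_genes <- genes$gene_id[!is.na(hit) & tads$name[hit] == tad_id]
    if (!(cfg$target_gene %in% tad_genes))
      stopf("target gene TSS not inside the causal TAD")
    g <- gd$geno[, gd$causal_id]
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    n <- length(g)
    indiv <- t(vapply(tad_genes, function(gene) {
      delta <- if (gene == cfg$target_gene)
        cfg$target_delta * cfg$target_expr_sd else 0
      cfg$target_expr_base + delta * g + rnorm(n, 0, cfg$target_expr_sd)
    }, numeric(n)))
    colnames(indiv) <- gd$samples$id
    list(counts = counts, gene_lengths = setNames(genes$length, genes$gene_id),
         indiv_expr = indiv, specific_genes = spec)
  })
}

#' Build the full synthetic truth bundle
#'
#' Wires all generators under one seed and (optionally) writes every file
#' the pipeline consumes - VCF, phenotype/gene/expression TSVs, per-tissue
#' mark bedGraphs and peak BEDs, TAD and true-state BEDs - plus a
#' `manifest.json` recording the seed and a config hash.
#'
#' @param cfg `scenario_config`
#' @param seed integer seed (sub-generators derive seeds seed+1 ... seed+3)
#' @param out_dir output directory, or NULL for an in-memory bundle only
#' @return object of class `truth_bundle`
#' @export
make_truth_bundle <- function(cfg, seed = 1, out_dir = NULL) {
  genes <- make_gene_models(cfg)
  tads <- make_tads(cfg)
  gd <- simulate_populations(cfg, seed)
  phen <- simulate_phenotypes(gd, cfg, seed + 1L)
  epi <- simulate_epigenome(cfg, genes, seed + 2L)
  expr <- simulate_expression(cfg, gd, genes, seed + 3L)
  bundle <- structure(list(config = cfg, seed = seed, genes = genes,
                           tads = tads, genotypes = gd, phenotypes = phen,
                           epigenome = epi, expression = expr),
                      class = "truth_bundle")
  if (!is.null(out_dir)) write_truth_bundle(bundle, out_dir)
  bundle
}

config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA),
             tf)
  unname(tools::md5sum(tf))
}

#' Write a truth bundle to disk
#' @param bundle `truth_bundle`
#' @param out_dir output directory (created if needed)
#' @return the manifest (invisibly)
#' @export
write_truth_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- bundle$config
  files <- character(0)
  wr <- function(rel, writer) {
    path <- file.path(out_dir, rel)
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    writer(path)
    files <<- c(files, rel)
  }
  wr("genotypes.vcf", function(p)
    write_vcf(bundle$genotypes, p, cfg$chrom_sizes))
  wr("phenotypes.tsv", function(p)
    write.table(bundle$phenotypes, p, sep = "\t", quote = FALSE,
                row.names = FALSE))
  wr("genes.tsv", function(p) write_gene_models(bundle$genes, p))
  wr("tads.bed", function(p) write_bed(bundle$tads, p))
  wr("sweep_truth.bed", function(p) write_bed(bundle$genotypes$sweep_region, p))
  wr("expression_tissue_counts.tsv", function(p)
    write.table(data.frame(gene_id = rownames(bundle$expression$counts),
                           bundle$expression$counts, check.names = FALSE),
                p, sep = "\t", quote = FALSE, row.names = FALSE))
  wr("expression_individual.tsv", function(p)
    write.table(data.frame(gene_id = rownames(bundle$expression$indiv_expr),
                           bundle$expression$indiv_expr, check.names = FALSE),
                p, sep = "\t", quote = FALSE, row.names = FALSE))
  for (ts in cfg$tissues) {
    for (mk in names(bundle$epigenome$tracks[[ts]])) {
      wr(sprintf("tracks/%s_%s.bedgraph", ts, mk), function(p)
        write_bedgraph(bundle$epigenome$tracks[[ts]][[mk]], p))
      for (rp in c("rep1", "rep2"))
        wr(sprintf("peaks/%s_%s_%s.bed", ts, mk, rp), function(p)
          write_bed(bundle$epigenome$peaks[[ts]][[mk]][[rp]], p))
    }
  }
  manifest <- list(seed = bundle$seed, config_md5 = config_hash(cfg),
                   files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
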