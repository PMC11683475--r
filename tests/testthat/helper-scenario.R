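# Shared fixtures built in code.

# scaled-down scenario for fast unit tests (same genome/architecture,
# fewer individuals and variants)
small_scenario <- function(...) {
  scenario_config(pop_sizes = c(thin_tail = 60, fat_tail = 60),
                  n_variants = 1200, ...)
}

# wrap a dosage matrix into genotype_data with minimal metadata
make_toy_gd <- function(geno, chrom = "chr1", pos = NULL, pop = NULL) {
  M <- ncol(geno)
  pos <- pos %||% seq(100, by = 100, length.out = M)
  variants <- data.frame(chrom = rep(chrom, M), pos = pos,
                         id = paste0(chrom, ":", pos),
                         ref = rep("A", M), alt = rep("C", M),
                         stringsAsFactors = FALSE)
  samples <- data.frame(id = sprintf("s%02d", seq_len(nrow(geno))),
                        stringsAsFactors = FALSE)
  if (!is.null(pop)) samples$pop <- pop
  genotype_data(geno, variants, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a small VCF fixture and return its path
write_vcf_fixture <- function(lines, dir = tempdir()) {
  path <- tempfile("fixture", fileext = ".vcf", tmpdir = dir)
  writeLines(lines, path)
  path
}

vcf_header <- function(samples = c("s1", "s2"), format = "GT:DP") {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}
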