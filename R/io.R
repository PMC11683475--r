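# Coordinate conventions: genomic intervals are 0-based half-open (BED);
# variant positions are 1-based (VCF). All conversions between the two
# happen inside this file only.

#' Construct a genomic interval table
#'
#' Intervals are 0-based half-open, the BED convention. The returned
#' data frame is sorted by chromosome then start and validated.
#'
#' @param chrom character chromosome names
#' @param start integer start (0-based, inclusive)
#' @param end integer end (exclusive); must satisfy `end > start`
#' @param name,score,strand optional BED6 columns
#' @return data frame with class `genomic_intervals`
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, score = NULL,
                              strand = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  if (!is.null(strand)) df$strand <- as.character(strand)
  validate_intervals(df)
}

#' Validate an interval table
#'
#' Asserts the invariants every downstream interval operation relies on:
#' non-negative starts, strictly positive widths, and per-chromosome
#' sorting (sorting is applied, not just checked).
#'
#' @param df data frame with columns chrom, start, end
#' @return the sorted, validated data frame
#' @export
validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df)) {
    if (any(is.na(df$start)) || any(is.na(df$end)))
      stopf("interval table contains missing coordinates")
    if (any(df$start < 0)) stopf("interval start < 0")
    if (any(df$end <= df$start))
      stopf("interval with end <= start (empty or negative width)")
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- unique(c("genomic_intervals", class(df)))
  df
}

# 0-based half-open -> 1-based closed GRanges (internal)
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

granges_to_intervals <- function(gr) {
  genomic_intervals(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr) - 1L,
                    GenomicRanges::end(gr))
}

#' Read a BED3/BED6 file
#'
#' @param path path to a tab-separated BED file (no header)
#' @return validated `genomic_intervals` data frame
#' @export
read_bed <- function(path) {
  df <- tryCatch(
    read.delim(path, header = FALSE, stringsAsFactors = FALSE,
               comment.char = "#"),
    error = function(e) stopf("cannot parse BED file '%s': %s", path,
                              conditionMessage(e)))
  if (ncol(df) < 3) stopf("BED file '%s' has fewer than 3 columns", path)
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = suppressWarnings(as.integer(df[[2]])),
                    end = suppressWarnings(as.integer(df[[3]])),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4) out$name <- as.character(df[[4]])
  if (ncol(df) >= 5) out$score <- suppressWarnings(as.numeric(df[[5]]))
  if (ncol(df) >= 6) out$strand <- as.character(df[[6]])
  validate_intervals(out)
}

#' Write a BED file
#'
#' Canonical 3- or 6-column tab-separated output; round-trips byte-identically
#' with [read_bed()] for canonical sorted 3-column input.
#'
#' @param df interval data frame
#' @param path output path
#' @export
write_bed <- function(df, path) {
  df <- validate_intervals(df)
  if (!is.null(df$name)) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", df$chrom, df$start, df$end,
                     df$name, df$score %||% rep(0, nrow(df)),
                     df$strand %||% rep(".", nrow(df)))
  } else {
    lines <- sprintf("%s\t%d\t%d", df$chrom, df$start, df$end)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct a binned signal track
#'
#' A signal track stores one numeric value per fixed-size bin per
#' chromosome, origin 0 (bin i covers `[i*bin_size, (i+1)*bin_size)`).
#'
#' @param values named list, chromosome -> numeric vector of bin values
#' @param bin_size bin width in bp
#' @return object of class `signal_track`
#' @export
signal_track <- function(values, bin_size) {
  stopifnot(is.list(values), !is.null(names(values)), bin_size >= 1)
  structure(list(values = values, bin_size = as.integer(bin_size)),
            class = "signal_track")
}

#' Read a bedGraph file onto a fixed bin grid
#'
#' Interval values are projected onto bins by coverage-weighted mean:
#' a bin's value is the sum of `value * overlap_bp` over records divided by
#' the bin size, so uncovered stretches contribute 0.
#'
#' @param path bedGraph path (chrom, start, end, value; 0-based half-open)
#' @param bin_size bin width in bp
#' @param chrom_sizes named numeric vector of chromosome lengths
#' @return a [signal_track()]
#' @export
read_bedgraph <- function(path, bin_size, chrom_sizes) {
  n_bins <- ceiling(chrom_sizes / bin_size)
  values <- lapply(n_bins, function(n) numeric(n))
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0)
    return(signal_track(values, bin_size))
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stopf("bedGraph '%s' needs 4 columns", path)
  names(df)[1:4] <- c("chrom", "start", "end", "value")
  bad <- !(df$chrom %in% names(chrom_sizes))
  if (any(bad)) stopf("bedGraph chromosome '%s' not in chrom_sizes",
                      df$chrom[which(bad)[1]])
  if (any(df$end > chrom_sizes[df$chrom]))
    stopf("bedGraph interval exceeds chromosome length")
  if (any(df$end <= df$start)) stopf("bedGraph interval with end <= start")
  for (chrom in unique(df$chrom)) {
    d <- df[df$chrom == chrom, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stopf("overlapping bedGraph records on %s", chrom)
    acc <- values[[chrom]]
    rec <- IRanges::IRanges(d$start + 1L, d$end)
    bins <- IRanges::IRanges(seq(0L, (n_bins[[chrom]] - 1L)) * bin_size + 1L,
                             width = bin_size)
    hits <- IRanges::findOverlaps(rec, bins)
    ov <- IRanges::width(IRanges::pintersect(
      rec[S4Vectors::queryHits(hits)], bins[S4Vectors::subjectHits(hits)]))
    contr <- d$value[S4Vectors::queryHits(hits)] * ov / bin_size
    idx <- S4Vectors::subjectHits(hits)
    agg <- tapply(contr, idx, sum)
    acc[as.integer(names(agg))] <- acc[as.integer(names(agg))] + as.numeric(agg)
    values[[chrom]] <- acc
  }
  signal_track(values, bin_size)
}

#' Write a signal track as bedGraph
#' @param track a [signal_track()]
#' @param path output path
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bs <- track$bin_size
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    nz <- which(v != 0)
    if (!length(nz)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", chrom, (nz - 1L) * bs, nz * bs,
                       format(v[nz], trim = TRUE, scientific = FALSE)), con)
  }
  invisible(path)
}

#' Read a gene-model table
#'
#' Expects a tab-separated file with header columns `gene_id`, `chrom`,
#' `strand`, `start`, `end` (1-based inclusive gene body) and optionally
#' `length` (defaults to `end - start + 1`). The TSS is `start` for
#' "+"-strand genes and `end` for "-"-strand genes; the TES is the other end.
#'
#' @param path TSV path
#' @return data frame with gene_id, chrom, strand, tss, tes, start, end, length
#' @export
read_gene_models <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "chrom", "strand", "start", "end")
  miss <- setdiff(req, names(df))
  if (length(miss)) stopf("gene model table missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stopf("duplicate gene_id in gene model table: %s",
          df$gene_id[duplicated(df$gene_id)][1])
  if (!all(df$strand %in% c("+", "-")))
    stopf("gene strand must be '+' or '-'")
  if (is.null(df$length)) df$length <- df$end - df$start + 1L
  if (any(df$length <= 0)) stopf("gene with non-positive length")
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  df$tes <- ifelse(df$strand == "+", df$end, df$start)
  df[, c("gene_id", "chrom", "strand", "tss", "tes", "start", "end", "length")]
}

#' Write a gene-model table
#' @param genes gene model data frame (as from [read_gene_models()])
#' @param path output path
#' @export
write_gene_models <- function(genes, path) {
  write.table(genes[, c("gene_id", "chrom", "strand", "start", "end", "length")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a VCF file into a dosage matrix
#'
#' Parses diploid GT fields into alt-allele dosages (0/1/2, NA for missing).
#' Indels and multi-allelic records are dropped; when a per-genotype DP field
#' is present, genotypes with `DP < min_dp` are set to missing, mirroring the
#' VCFtools `--remove-indels --min-alleles 2 --max-alleles 2 --minDP` filters.
#'
#' @param path VCF path (plain text or bgzipped)
#' @param min_dp minimum per-genotype depth; 0 disables the mask
#' @return a `genotype_data` object: list with `geno` (individuals x variants
#'   dosage matrix), `variants` (chrom, pos, id, ref, alt) and `samples`
#' @export
read_vcf <- function(path, min_dp = 0) {
  stopifnot(min_dp >= 0)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stopf("malformed VCF '%s': %s", path,
                                            conditionMessage(e)))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) stopf("VCF '%s' contains no records", path)
  ref <- fix$REF
  alt <- fix$ALT
  keep <- nchar(ref) == 1 & !grepl(",", alt) & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stopf("VCF '%s' has no GT field", path)
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  gt_clean <- gsub("\\|", "/", gt)
  alleles <- strsplit(gt_clean, "/", fixed = TRUE)
  n_alleles <- lengths(alleles)
  called <- !is.na(gt_clean) & gt_clean != "." & gt_clean != "./."
  if (any(called & n_alleles != 2))
    stopf("non-diploid genotype encountered (e.g. '%s')",
          gt_clean[which(called & n_alleles != 2)[1]])
  dos <- vapply(alleles, function(a) {
    if (length(a) != 2 || any(a == ".")) return(NA_real_)
    sum(a == "1")
  }, numeric(1))
  dos <- matrix(dos, nrow = nrow(gt), dimnames = dimnames(gt))
  if (min_dp > 0) {
    dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP",
                                            as.numeric = TRUE))
    if (!is.null(dp)) {
      dp <- dp[keep, , drop = FALSE]
      dos[!is.na(dp) & dp < min_dp] <- NA_real_
    }
  }
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                     paste0(fix$CHROM, ":", fix$POS), fix$ID),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  genotype_data(t(dos), variants,
                data.frame(id = colnames(gt), stringsAsFactors = FALSE))
}

#' Construct a genotype container
#'
#' @param geno individuals x variants dosage matrix (0/1/2/NA)
#' @param variants data frame (chrom, pos, id, ref, alt)
#' @param samples data frame with at least an `id` column; an optional
#'   `pop` column carries population labels
#' @return object of class `genotype_data`
#' @export
genotype_data <- function(geno, variants, samples) {
  stopifnot(ncol(geno) == nrow(variants), nrow(geno) == nrow(samples))
  ok <- geno %in% c(0, 1, 2) | is.na(geno)
  if (!all(ok)) stopf("dosages must be 0, 1, 2 or NA")
  rownames(geno) <- samples$id
  colnames(geno) <- variants$id
  structure(list(geno = geno, variants = variants, samples = samples),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("genotype_data: %d individuals x %d variants (%s missing)\n",
              nrow(x$geno), ncol(x$geno),
              format(mean(is.na(x$geno)), digits = 3)))
  invisible(x)
}

#' Write a genotype container as VCF
#'
#' Minimal VCF 4.2 writer (GT field only) used by the synthetic-data
#' generator so that bundles round-trip through [read_vcf()].
#'
#' @param gd `genotype_data` object
#' @param path output path
#' @param chrom_sizes optional named vector for contig header lines
#' @export
write_vcf <- function(gd, path, chrom_sizes = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ovisatlas",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  if (!is.null(chrom_sizes))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(chrom_sizes),
                       as.integer(chrom_sizes)), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gd$samples$id), collapse = "\t"), con)
  code <- c("0/0", "0/1", "1/1")
  g <- t(gd$geno)  # variants x individuals
  gt <- matrix("./.", nrow(g), ncol(g))
  gt[!is.na(g)] <- code[g[!is.na(g)] + 1L]
  v <- gd$variants
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                sep = "\t")
  writeLines(paste(body, apply(gt, 1, paste, collapse = "\t"), sep = "\t"),
             con)
  invisible(path)
}
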