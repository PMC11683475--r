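---
title: "From genotypes and epigenomes to candidate causal regulatory variants"
author: "ovisatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From genotypes and epigenomes to candidate causal regulatory variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovisatlas)
```

## The problem

Selection scans and genome-wide association studies in livestock routinely
end with hundreds of significant variants sitting in noncoding DNA and in
strong linkage disequilibrium with one another. Statistical evidence alone
cannot separate the causal regulatory variant from its passengers. The way
out, used across farm-animal functional genomics, is to overlay an
epigenomic annotation: a variant that is significant, lies in a selective
sweep, falls inside open chromatin *and* an active-enhancer mark, and shares
a topologically associating domain (TAD) with a plausible target gene is a
far stronger candidate than one that merely clears a p-value threshold.

`ovisatlas` implements that integration end-to-end for a sheep-style study
design: chromatin-state annotation of tissue epigenomes, tissue-specificity
scoring of expression, selection scans between populations, a
mixed-linear-model GWAS, enrichment statistics, and the final
prioritization funnel. Because the raw data of such a study (thousands of
genomes, dozens of epigenomic libraries) cannot ship with a package, a
first-class synthetic-data module generates every input with planted
ground truth, so the whole pipeline is testable against known answers.

## Chromatin states

Mark tracks (ATAC, H3K4me3, H3K27ac) are binned at 200 bp and binarized
against a Poisson background: with genome-wide mean bin count
$\hat\lambda$, a bin is "on" iff $P(X \ge c \mid \hat\lambda) < 10^{-4}$.
These are the defaults of the standard segmentation tool in this field and
we keep them.

A single multivariate hidden Markov model with $K = 6$ states and
independent Bernoulli emissions per mark is trained by Baum-Welch on the
concatenation of all tissues, then decoded per tissue by posterior maximum
(Viterbi is available behind a flag). Numerical choices:

* forward-backward uses per-position scaling constants (implemented in
  C++; the log-likelihood is the sum of log scale factors);
* emissions are clamped to $[10^{-6}, 1-10^{-6}]$ in the M-step so
  degenerate states cannot produce zero likelihoods;
* EM stops when the log-likelihood gain falls below $10^{-4}$ or after 500
  iterations, and monotonicity is asserted every iteration;
* each restart initializes emissions from distinct observed mark patterns
  (frequency-weighted, jittered), which keeps EM away from collapsed
  solutions when states are pattern-separated; the best of 5 restarts by
  log-likelihood wins.

States are labelled from their emission rows by a rule table (H3K4me3 and
H3K27ac high: TssA; H3K4me3 high alone: TssW; H3K27ac with ATAC, H3K4me3
low: EnhA; H3K27ac moderate: EnhAW; ATAC alone: ATAC_Is; all low: Quies).
The thresholds (0.5 "high", 0.2 "moderate") are our operationalization of
what is usually done by inspecting the emission heat map; collisions are
resolved by emission margin. Tissue specificity of the resulting elements
uses the 1-bp-overlap presence rule: an element present in exactly one
tissue is tissue-specific, in all tissues common. The variability curve
reports, per state, the cumulative fraction of nonredundant base pairs
present in at most $k$ tissues; we summarize it as the smallest $k$
reaching 0.75. That cumulative-fraction reading is one interpretation of a
curve whose exact definition is ambiguous in the literature we follow; it
is stated here so the number is interpretable.

## Tissue specificity of expression

Counts are normalized to transcripts per million using gene lengths, and
specificity is scored with the tau index on the TPM vector across tissues:

$$\tau = \frac{\sum_{i=1}^{n} (1 - \hat x_i)}{n - 1}, \qquad
  \hat x_i = \frac{x_i}{\max_i x_i}.$$

Genes with $\tau > 0.8$ (strictly) are called tissue-specific and assigned
to their argmax tissue. No log transform or expression floor is applied
before tau; raw TPM keeps the formula exactly as published, at the price of
instability for very low-expressed genes — filter those upstream if that
matters for your data. Genes can also be grouped by the number of strong
enhancers overlapping the gene body (defaults 1 / 2-5 / >= 6, configurable;
a promoter-window alternative is behind a flag).

## Selection scans

All three statistics are computed on 150-kb windows stepped by 75 kb (full
windows only):

* **FST** — per-site Weir-Cockerham (1984) variance components, windowed
  as the ratio of sums $\sum a / \sum(a+b+c)$ (the "weighted" estimator of
  the usual VCF toolchain); negative values are reported as-is.
* **pi** — per-site heterozygosity $2j(n-j)/(n(n-1))$ from non-missing
  allele counts, summed and divided by the *full* window length, so
  monomorphic and uncalled positions count as zero difference. The pi
  ratio is reference/swept by default, so values above 1 flag reduced
  diversity in the swept population; the orientation is configurable and
  recorded in the output.
* **XP-EHH** — from phased haplotypes: EHH at distance $x$ is the
  probability two random haplotypes are identical from the core out to
  $x$; iHH is its trapezoid integral over genetic distance (uniform
  1 cM/Mb by default), truncated at the first site where EHH drops below
  0.05 — segments are accumulated only while both endpoints are at or
  above the cutoff, and no partial segment is added at the crossing. The
  raw score $\ln(\mathrm{iHH}_A/\mathrm{iHH}_B)$ is standardized
  genome-wide (no frequency binning) and averaged per window. The pipeline
  orients it as swept/reference so sweeps score high.

Candidate regions are windows in the top 5 per mille of **all three**
statistics (ties at the quantile included), merged when overlapping or
adjacent. The published analyses this mirrors report both "5%" and "5 per
mille"; we default to the stricter 5 per mille and expose `q`.

## Mixed-model GWAS

Variants are filtered as in the standard VCF toolchain (biallelic SNPs,
depth masking at read time, MAF >= 0.05, call rate >= 0.8, in that order).
Kinship is the VanRaden GRM $ZZ^\top / 2\sum p(1-p)$; population
structure additionally enters as the top 3 eigenvectors of the LD-pruned
(50-SNP window, step 5, $r^2 > 0.2$) genotype matrix. The null model
$y = X\beta + u + e$, $u \sim N(0, \sigma_g^2 K)$ is fitted by EMMA-style
REML: one eigendecomposition, then a 1-D profile over
$\delta = \sigma_e^2/\sigma_g^2$ on a log grid refined by Brent search.
When $K$ carries no structure the profile is flat; the fit warns and
returns the boundary rather than a spurious estimate. The scan uses the
P3D/EMMAX approximation — variance components fixed from the null, each
SNP tested by GLS on the rotated, whitened data with a Wald t-test —
which is the standard behavior of the mixed-model GWAS packages this
follows; missing dosages are mean-imputed and monomorphic SNPs return NA.
Significance is Bonferroni: $-\log_{10}(0.05/M)$ over the $M$ SNPs tested.
Factor covariates are one-hot encoded against a first-level reference (the
coding is not identifiable from published summaries; estimates of the
covariate effects themselves are not of interest here).

The ratio trait (tail fat / carcass weight) is analyzed untransformed;
no normalizing transform is applied by default because none is stated in
the analyses this follows.

## Enrichment

Fold enrichment of a state within a feature set is
$(\mathrm{overlap\ bp}/\mathrm{state\ bp}) / (\mathrm{feature\ bp}/\mathrm{genome\ bp})$,
in base pairs (not element counts). Published folds of this kind usually
come without a null; we add a circular-permutation p-value — features are
rotated per chromosome by uniform offsets, preserving their sizes and
spacing, and $p = (1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(n+1)$.
Circular rotation was chosen over independent re-placement because it
preserves the clustering of real annotations; note it is exact only when
feature placement is rotation-invariant.

## The prioritization funnel

1. SNPs with $-\log_{10} p$ above the genome-wide threshold;
2. intersect with candidate sweep regions;
3. require residence in open chromatin **and** in an H3K27ac peak
   (union of replicates per mark, one tissue — the tissue is an explicit
   argument, not a default, because the right choice depends on the
   trait);
4. annotate the containing TAD and link every gene whose **TSS** lies in
   that TAD (gene bodies can straddle TAD boundaries; the TSS is what the
   regulatory contact argument is about). SNPs in no TAD are kept with no
   linked genes.

SNP-in-interval membership converts the 1-based variant position to a
0-based point against half-open intervals, so a SNP at an interval's end
coordinate is outside. Linked genes are tested for genotype-stratified
expression by one-way ANOVA (Kruskal-Wallis behind a flag; at least two
genotype classes with three individuals each). Candidates are ranked by
minimum linked-gene expression p, then GWAS $-\log_{10} p$, then
coordinate — candidates with no testable gene rank last. The ranking rule
is ours; the published analyses narrow informally by the same quantities.

## What the synthetic data emulates — and what it does not

`scenario_config()` fixes the study conditions; `make_truth_bundle()`
realizes them. Defaults (chosen once as a desk-scale analog of the study
design, and stated here so the acceptance numbers are interpretable):

* two populations — `thin_tail` (reference) and `fat_tail` (swept) — of
  200 diploids each on a 2 x 3 Mb genome with ~4000 SNPs and 1% missing
  genotypes;
* Balding-Nichols differentiation $F = 0.02$ genome-wide, $F_{sweep} =
  0.5$ for the swept population inside chr1:900,000-1,050,000. The sweep
  is deliberately aligned to one full scan window, and a 150-kb sweep is
  within the size range such scans report;
* one extended core haplotype — drawn from the swept population's own
  drifted frequencies and carrying the causal alt allele — copied into
  85% of swept-population haplotypes: a nearly complete sweep, consistent
  with the near-fixed haplotype blocks differentiation scans detect.
  At much lower haplotype frequencies an incomplete sweep barely reduces
  diversity and the pi-ratio signal disappears — a genuine property of
  incomplete sweeps, worth remembering when interpreting real scans;
* the causal variant at chr1:975,000 inside a 2-kb tail-fat-specific
  enhancer, effect +1 phenotypic SD per allele on a trait with $h^2=0.3$
  plus birthplace/batch/season effects; a carcass-weight trait and the
  ratio trait are emitted alongside;
* 20 decoy variants spread through the sweep, outside all peaks, carrying
  the causal genotype column verbatim (perfect LD): significant by
  construction, they must die at the peak-intersection stage;
* nine tissues with a planted promoter/enhancer/ATAC-island architecture
  at Poisson rates 1 (background), 4 (weak states), 10 (enriched marks),
  tissue-specific enhancers present in exactly one tissue, and peak BEDs
  in two replicates (replicate 2 widened by one bin as deterministic
  jitter);
* tissue-specific genes at a 20-fold expression contrast (planting
  $\tau > 0.8$) and a target gene whose per-individual expression rises
  1 SD per causal allele, with two non-responding TAD neighbours.

Deliberate idealizations: no linkage disequilibrium outside the copied
sweep haplotype, no demographic history, uniform recombination, clean
peaks exactly where states are planted, and no bystander SNP inside the
causal enhancer (so planted-truth recovery is a clean positive control).
Passing the end-to-end checks therefore demonstrates that the machinery is
correct and the funnel's logic sound — not that real data, with LD between
peaks and decoys, would resolve a single candidate as cleanly.

## Problem sizes and reproducibility

Every generator draws through one seeded entry point, and the whole
bundle is reproducible from `(config, seed)` — the manifest records the
seed and a config hash. The shipped validation uses desk-scale sizes
chosen to exercise every code path with comfortable statistical margins:
HMM recovery on $10^5$ bins with 5 restarts; GWAS calibration and power at
$n = 500$, $M = 5000$ over 10-20 seeds; end-to-end funnel recovery over 20
bundle seeds. `scripts/acceptance.R` recomputes the same quantities from
scratch for any seed.

## Known limitations

* The Bernoulli HMM assumes conditionally independent marks; correlated
  assay noise is not modelled (nor is it in the tools this mirrors).
* XP-EHH uses a uniform genetic map and genome-wide standardization;
  frequency-binned standardization is a noted option, off by default.
* The EMMAX approximation underestimates significance slightly for very
  large effects; an exact per-SNP refit is out of scope here.
* The permutation null for enrichment conditions on the state set and is
  exact only under rotation-invariant feature placement.
* Multi-allelic variants are dropped, not decomposed.
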