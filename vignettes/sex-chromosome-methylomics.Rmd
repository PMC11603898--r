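---
title: "Sex-chromosome methylomics from WGBS cytosine reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-chromosome methylomics from WGBS cytosine reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Whole-genome bisulfite sequencing (WGBS) reports, for every cytosine, how
many reads support methylation and how many do not. In species with
XX females and XY males, these counts carry two signals at once: the
methylation state itself, and the copy number of the sequence the reads come
from. `methylsex` implements the downstream analyses that exploit both —
quantifying CpG methylation with explicit coverage filters, contrasting
female and male methylomes along the X chromosome, classifying unplaced
assembly contigs into autosome/X/Y linkage from the female:male depth ratio,
and resolving allele-specific methylation (ASM) at a candidate
X-inactivation locus from single-read methylation states — plus a synthetic
generator that plants all of these signals with known truth so every
estimator can be tested by parameter recovery.

# Methylation quantification

**Strand merging.** CpG methylation is symmetric: the cytosines at positions
$p$ (+ strand) and $p+1$ (− strand) report the same CpG. `merge_symmetric_cpgs`
sums their counts into one site at the +-strand coordinate; totals are
conserved, and lone records are kept (a lone −-strand record is mapped to its
+-coordinate). All internal coordinates are 0-based half-open; the cytosine
report (1-based) and GTF (1-based inclusive) readers shift on ingest, BED12
is taken as-is. A single internal convention is the cheapest insurance
against off-by-one errors between modules.

**Site filter.** Fractional methylation $m/(m+u)$ is emitted only for sites
with at least `min_coverage = 5` reads in that sample, the standard filter
for per-site estimates at ~15x genomes. The filter is a parameter, so a
stricter 10-read variant can be run to confirm findings are not
coverage-artefacts.

**Region statistics.** Two summaries are computed per region:
the *weighted* methylation level $\sum m / \sum (m+u)$ over all covered
sites (robust at low coverage, used for profiles and global summaries), and
the *mean* methylation level, the unweighted average of qualifying-site
fractions, reported only when the region has **more than** `min_sites = 3`
qualifying sites. The strict reading of "more than three" (i.e. at least 4)
is deliberate and configurable, since either convention is defensible.

**Sex-level pooling.** For weighted summaries, counts are pooled across
same-sex samples (the statistic is count-based); for mean summaries, each
site's per-sample fractions are averaged within sex first (animals are
replicates). Per-site sex deltas likewise use the unweighted mean of
per-sample fractions, so one deeply sequenced animal cannot dominate.

**Downsampling control.** `downsample_counts` thins methylated and
unmethylated counts binomially and independently per site — the
count-level equivalent of discarding reads at random — to verify that
female-X results are not artefacts of the 2:1 female:male X coverage.

# Metagene profiles and expression ranks

Gene bodies (the longest transcript of each gene) are scaled into 60 bins;
2 kb flanks are cut into fixed 100-bp bins; minus-strand genes are reversed
so bin 0 is always most upstream. Per-bin values are weighted methylation
pooled over genes. Genes are ranked 0–20 by expression: rank 0 holds exactly
the zero-expression genes, ranks 1–20 are ascending quantile bins of the
non-zero genes with ties broken lexically by gene id for determinism.
Promoters are the 2 kb immediately upstream of the gene-body start,
strand-aware, truncated (never extended) at contig edges and flagged.

# Sex-differential statistics

Per-gene promoter deltas (male − female mean methylation) are classified
into `female_hypo` (> 0.05), `female_hyper` (< −0.05) and `unbiased` — the
0.05 band is the conventional threshold for calling a promoter sex-biased.
The group tests are:

- **Mann–Whitney U**, two-sided; exact by full enumeration of group
  assignments when the pooled size is ≤ 12 (valid under ties), otherwise the
  tie-corrected normal approximation without continuity correction.
- **Pearson chi-square on 2×2 tables without continuity correction** for
  the proportion of sex-specific genes per chromosome class. Without the
  correction the published autosome-vs-X comparison (479/32,302 vs 14/783)
  reproduces at P ≈ 0.49; with Yates it lands near 0.58, so the
  uncorrected form is the one the analysis uses.
- **Spearman rank correlation** with an exact permutation P-value for
  n ≤ 9 (own enumeration, valid under ties) and the t-approximation above.

No multiple-testing correction is applied across these comparisons; the
outputs carry raw P-values, as is conventional for the handful of planned
contrasts here, and the metadata says so.

# CpG content

The CpG observed/expected ratio per window is the Gardiner–Garden
normalisation $(n_{CpG} \cdot L)/(n_C \cdot n_G)$ with $L$ the non-N window
length, computed over 1000-bp windows stepped by 500 bp; a trailing partial
window is kept if at least half a window long, flagged. Windows are
annotated by the position of their centre, with promoter taking precedence
over gene body on overlap (a deterministic rule is required; promoter-first
matches the analysis's emphasis). The CpG-island scan uses
Gardiner–Garden-style defaults (≥ 200 bp, GC ≥ 0.5, O/E ≥ 0.6 in 200-bp
1-bp-shift windows, merged) — the criteria are configurable because no
single convention is universal.

# Sex-linkage classification

For each unplaced contig, the per-sample mean read depth over CG-context
cytosines (both strands, pre-merge — the unit the depth data come in) is
averaged within sex, and the metric $D = 1 - \bar F/\bar M$ computed for
contigs with **more than 40** covered cytosines. Expected values are 0
(autosomal, two copies in both sexes), −1 (X: two female copies vs one
male), +1 (Y: no female copies). Classes follow the published thresholds
exactly: Y iff $D > 0.95$, A iff $-0.5 \le D \le 0.5$, X iff $D < -0.5$;
the gap $(0.5, 0.95]$ is left `unclassified` (it is never assigned), as are
contigs with zero male depth. "More than 40 cytosines" is read as *covered*
cytosines (configurable), since coverage is what the metric averages over.

The windowed depth scan flags `female_absent` windows (mean female depth
below 0.5 while male depth is clearly present) — the signature of Y-derived
sequence misassembled into the X — and `PAR_like` windows
($|1 - \bar F/\bar M| < 0.2$), merging contiguous flags into exclusion
intervals. The *present* threshold must sit below the single-copy male
depth of the data at hand: the function default (5 reads/cytosine) suits
~12–18x genomes, while the bundled synthetic study (per-allele depth 7.5,
i.e. ~3.75 per strand-cytosine for single-copy male X) is scanned at 2.

# Allele-specific methylation

Within a candidate region, each read's CpG calls are collapsed to a
per-read methylation fraction (reads with fewer than 3 CpG calls are
dropped; conflicting duplicate calls are an error). ASM appears as a
bimodal distribution: one allele's reads near 0, the other's near 1. The
call requires the extreme-read proportion
(fraction ≤ 0.25 or ≥ 0.75) to reach 0.8 with at least 5 reads in each
mode. These cutoffs are set analytically from the binomial behaviour of
short reads: with 3–8 CpGs per read and allele rates 0.95/0.05, a read from
the methylated allele exceeds 0.75 with probability ~0.86–0.99 (expected
extreme fraction ~0.95), whereas a non-ASM locus at rate 0.5 yields an
expected extreme fraction of only ~0.3; stricter cutoffs at 0.1/0.9 would
reject genuinely ASM reads of 5–8 CpGs (e.g. eight-for-eight successes at
rate 0.95 occur only 66% of the time) and cannot reach a 0.9 extreme
fraction. All four numbers are configurable.

Per-CpG methylation–expression correlation across the six samples uses
Pearson's r with the exact t-based P at n = 6, flagging sites at raw
P < 0.05 (no correction across CpGs, stated in the output), and annotates
each site's sex-bias direction. The locus delta track uses a deliberately
looser inclusion rule — pooled coverage of at least 2 reads in either sex —
because locus plots should show every informative site, including those
covered in only one sex.

# The synthetic generator

The generator is first-class, tested code. It emulates the study conditions
the analyses assume:

- **Design**: 3 female + 3 male samples; assembled autosomes and an X
  chromosome carrying genes; unplaced A/X/Y contigs for the classifier.
- **Coverage**: per CpG, strand and sample, Poisson with mean
  (allele copies × `per_allele_depth`/2), copies being 2/2 (autosome),
  2/1 (X), 0/1 (Y). The default `per_allele_depth = 7.5` gives ~15x merged
  autosomal coverage, in the range of real 12–18x brain WGBS, and
  structurally reproduces the 2:1 female:male X depth. A PAR-like interval
  (male copies 2) and a misassembled Y-in-X interval (female copies 0) are
  planted on the X.
- **Methylation**: CpG methylation ~0.8 (autosomes, male X), Y contigs 0.3;
  promoter levels per gene drawn uniformly in (0.05, 0.95); female X sites
  are hypomethylated by 0.15, attenuated in promoters by
  `1 − cpg_count/80` so the effect shrinks with promoter CpG count and
  crosses zero (female-hyper) above ~80 CpGs. Methylated counts are
  Binomial at the sex's true rate; at the ASM island, female counts are
  drawn per allele at rates 0.95/0.05.
- **Sequence**: CpGs are placed by Bernoulli draws on alternate positions
  at the contig's density after background CG dinucleotides are removed, so
  the realized density is controlled; promoter densities are per-gene
  multipliers (0.25–1.75×, mean 1) of the contig density, spanning the
  CpG-count range the binning analyses need without shifting the contig-wide
  density; the Xist-like gene's 5' island gets a high density (0.08/bp) on a
  GC-rich background so it passes island criteria.
- **Expression**: gene mean abundance follows
  `100 · exp(−3 · promoter methylation)` of the *sex-independent* baseline
  promoter methylation with lognormal noise (sdlog 0.8) — so female-X
  hypomethylation does not move expression, reproducing the central
  negative result that X hypomethylation and sex-biased expression are
  uncoupled; ~10% of genes are silent (rank 0), ~3% carry a planted sex
  effect (the DE labels), and the Xist-like gene is expressed only in
  females.
- **ASM reads**: fixed 150-bp single-end reads with uniform starts (the
  read-length of the underlying chemistry, without modelling pairs), one
  allele per read in females.

What the generator does **not** emulate: sequencing error and bisulfite
conversion failure, non-CpG methylation, within-promoter methylation
gradients (the TSS profile is a promoter-vs-body step rather than a smooth
dip), mappability structure, and biological between-animal variance beyond
binomial sampling. Passing recovery tests therefore demonstrates estimator
correctness under the planted model, not robustness to those artefacts.

# Problem sizes and determinism

The test and acceptance runs use a ~250-kb default genome (~5,000 CpGs,
6 samples), a 200-contig genome for the classifier, a 1.8-Mb autosome set
(~190 genes) for null-correlation checks, and 100–200 replicates for
ASM detection rates — sizes chosen so the full suite completes in about a
minute while keeping Monte-Carlo bounds far from their thresholds. All
generator outputs are byte-identical under a fixed seed; sub-stages derive
their seeds by fixed offsets from the configured seed.

The parameter-recovery check for the planted −0.15 female-X effect runs the
generator with attenuation disabled and no PAR, because those features
intentionally dilute promoter-site deltas and the recovery target is the
base parameter; the attenuation itself is validated separately by the
CpG-count binning shape.

# Known limitations

- The classifier thresholds are taken as published constants; no attempt is
  made to re-estimate them from the depth-ratio mixture.
- Spearman exact P-values enumerate up to 9! permutations; beyond n = 9 the
  t-approximation is used (accurate to ~2 decimal places there).
- BED12 input uses only the first six columns (gene extent per transcript);
  exon-block structure is not needed by any analysis here.
- The pipeline consumes externally produced differential-expression labels
  and never calls differential expression or DMRs itself.
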