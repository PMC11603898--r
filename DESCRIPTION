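Package: methylsex
Title: Sex-Differential DNA Methylation Analysis from WGBS Cytosine Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of whole-genome bisulfite sequencing (WGBS)
    cytosine reports for studies of sex-chromosome regulation: strand-aware
    CpG merging, coverage-filtered site and region methylation (weighted and
    mean), metagene/TSS profiles by expression rank, female-male differential
    methylation at site and gene level with CpG-content binning, CpG
    observed/expected landscape and CpG-island scanning, read-depth-ratio
    classification of unplaced contigs into autosome/X/Y linkage, windowed
    sex-specific depth-anomaly scanning, and read-level allele-specific
    methylation calling at candidate loci. Includes a synthetic diploid-genome
    generator that emulates the coverage and methylation structure these
    analyses assume (2:1 female:male X depth, female-X hypomethylation
    attenuated by promoter CpG count, methylation-linked expression, an
    Xist-like locus with an allele-specifically methylated 5' CpG island),
    with a ground-truth record for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
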