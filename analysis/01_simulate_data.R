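#!/usr/bin/env Rscript
# Stage 1: generate the synthetic WGBS + RNA-seq study bundle.
#
# Emits, under results/sim/: a FASTA genome (two autosomes, one X with a
# PAR-like interval, a misassembled Y-in-X interval and an Xist-like gene
# carrying an allele-specifically methylated 5' CpG island; unplaced A/X/Y
# contigs), GTF gene models, per-sample Bismark-style cytosine reports for
# 3 females + 3 males, expression and DE-label tables, per-read methylation
# calls at the ASM locus, and the ground-truth JSON.

suppressMessages({
  library(methylsex)
  library(data.table)
})

outdir <- "results/sim"
cfg <- sim_config(seed = 1L)
bundle <- simulate_bundle(cfg, outdir)

truth <- bundle$truth
cat("Synthetic study written to", outdir, "\n")
cat(sprintf("  contigs: %d (%s)\n", length(truth$contig_class),
            paste(sprintf("%s=%d", names(table(truth$contig_class)),
                          table(truth$contig_class)), collapse = ", ")))
cat(sprintf("  CpG sites: %d | genes: %d | samples: %d\n",
            nrow(truth$sites), nrow(truth$genes),
            nrow(bundle$methylomes$samples)))
cat(sprintf("  Xist-like gene: %s with ASM island %s:%d-%d\n",
            truth$xist_gene_id, truth$asm_locus$chrom,
            truth$asm_locus$start0, truth$asm_locus$end0))
cat(sprintf("  planted female-X hypomethylation: %.2f (attenuated by promoter CpG count)\n",
            cfg$femaleX_hypo_base))
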