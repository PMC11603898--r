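#!/usr/bin/env Rscript
# Stage 5: allele-specific methylation at the Xist-like 5' CpG island.
#
# Builds the per-CpG female-male delta track over the gene +- flank (with the
# locus-specific >=2-reads-in-either-sex inclusion rule), correlates each
# island CpG's methylation with the gene's expression across the six samples
# (Pearson), and calls ASM from per-read methylation states. Writes
# results/asm/.

suppressMessages({
  library(methylsex)
  library(data.table)
})

sim <- "results/sim"
outdir <- "results/asm"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

sheet <- fread(file.path(sim, "sample_sheet.tsv"))
sample_sex <- setNames(sheet$sex, sheet$sample_id)
records <- rbindlist(lapply(seq_len(nrow(sheet)), function(i) {
  r <- read_cytosine_report(file.path(sim, sheet$path[i]))
  r[, sample_id := sheet$sample_id[i]]
}))
genes <- read_gene_annotation(file.path(sim, "genes.gtf"), format = "gtf")
expr <- read_expression_table(file.path(sim, "expression.tsv"))
truth <- jsonlite::read_json(file.path(sim, "truth.json"))
merged <- merge_symmetric_cpgs(records)

xist_id <- truth$xist_gene_id
xist <- genes[gene_id == xist_id]
island <- truth$asm_locus

# delta track across the gene body +- flank
track <- region_delta_track(
  merged, sample_sex,
  list(chrom = xist$chrom, start0 = xist$body_start0,
       end0 = xist$body_end0), flank = 8000L)
fwrite(track, file.path(outdir, "delta_track.tsv"), sep = "\t")
dmin <- track[which.min(delta_fm)]
cat(sprintf("Strongest female hypomethylation at %s:%d (delta %.2f); island %d-%d\n",
            dmin$chrom, dmin$pos0, dmin$delta_fm,
            island$start0, island$end0))

# per-CpG methylation vs expression across the six samples (island +- 1 kb)
sm <- site_fractional_methylation(merged, min_coverage = 5L)
sm_loc <- sm[chrom == island$chrom & pos0 >= island$start0 - 1000L &
               pos0 < island$end0 + 1000L]
xist_expr <- setNames(expr[gene_id == xist_id, tpm],
                      expr[gene_id == xist_id, sample_id])
cc <- cpg_expression_correlation(sm_loc, xist_expr, sample_sex)
fwrite(cc, file.path(outdir, "cpg_expression_correlation.tsv"), sep = "\t")
cat(sprintf("\nCpGs tested: %d; significant at P < 0.05: %d (%d negative, %d positive r)\n",
            nrow(cc), sum(cc$significant),
            sum(cc$significant & cc$r < 0), sum(cc$significant & cc$r > 0)))
isl_cc <- cc[pos0 >= island$start0 & pos0 < island$end0 & significant == TRUE]
cat(sprintf("Significant island CpGs: %d, all negatively correlated: %s\n",
            nrow(isl_cc), all(isl_cc$r < 0)))

# read-level ASM call at the island
calls <- read_read_calls(file.path(sim, "asm_read_calls.tsv"))
profs <- per_read_profiles(calls, list(chrom = island$chrom,
                                       start0 = island$start0,
                                       end0 = island$end0))
asm <- call_asm(profs)
fwrite(profs, file.path(outdir, "per_read_profiles.tsv"), sep = "\t")
jsonlite::write_json(asm[c("n_reads_used", "n_low_mode", "n_high_mode",
                           "frac_extreme", "is_asm", "reason")],
                     file.path(outdir, "asm_call.json"),
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("\nASM call: %s (reads %d, extremes %.2f, modes %d/%d)\n",
            asm$is_asm, asm$n_reads_used, asm$frac_extreme,
            asm$n_low_mode, asm$n_high_mode))
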