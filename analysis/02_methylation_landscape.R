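#!/usr/bin/env Rscript
# Stage 2: genome-wide methylation landscape and its link to expression.
#
# Merges symmetric CpGs, applies the >= 5-read site filter, builds the
# metagene/TSS profile and the expression-rank (0-20) profiles, and
# correlates promoter/gene-body methylation with expression rank per
# chromosome (Spearman). Writes results/landscape/.

suppressMessages({
  library(methylsex)
  library(data.table)
})

sim <- "results/sim"
outdir <- "results/landscape"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

sheet <- fread(file.path(sim, "sample_sheet.tsv"))
records <- rbindlist(lapply(seq_len(nrow(sheet)), function(i) {
  r <- read_cytosine_report(file.path(sim, sheet$path[i]))
  r[, sample_id := sheet$sample_id[i]]
}))
genes <- read_gene_annotation(file.path(sim, "genes.gtf"), format = "gtf")
expr <- read_expression_table(file.path(sim, "expression.tsv"))

merged <- merge_symmetric_cpgs(records)
site_meth <- site_fractional_methylation(merged, min_coverage = 5L)
cat(sprintf("CpG sites qualifying at >=5 reads: %.1f%%\n",
            100 * attr(site_meth, "prop_qualifying")))

# global weighted methylation per sample
glob <- merged[, .(weighted_meth = sum(m) / sum(m + u)), by = sample_id]
fwrite(glob, file.path(outdir, "global_weighted_methylation.tsv"), sep = "\t")
cat("Global weighted CpG methylation by sample:\n")
print(glob)

# metagene profile: promoters (the upstream flank) sit below gene bodies
prof <- metagene_profile(merged, genes)
fwrite(prof, file.path(outdir, "metagene_profile.tsv"), sep = "\t")
zmeans <- prof[, .(meth = sum(m) / sum(m + u)), by = zone]
cat(sprintf("Zone methylation: upstream(promoter) %.3f | body %.3f | downstream %.3f\n",
            zmeans[zone == "upstream", meth], zmeans[zone == "body", meth],
            zmeans[zone == "downstream", meth]))
cat(sprintf("TSS-proximal hypomethylation (promoter < body): %s\n",
            ifelse(zmeans[zone == "upstream", meth] <
                     zmeans[zone == "body", meth], "yes", "no")))

# expression ranks and per-rank profiles
mean_tpm <- expr[, .(tpm = mean(tpm)), by = gene_id]
ranks <- assign_expression_ranks(setNames(mean_tpm$tpm, mean_tpm$gene_id))
rp <- rank_methylation_profile(merged, genes, ranks)
fwrite(rp, file.path(outdir, "rank_profiles.tsv"), sep = "\t")

# promoter/body methylation vs expression rank, per chromosome (Spearman)
prom <- genes[, .(region_id = gene_id, chrom, start0 = prom_start0,
                  end0 = prom_end0)]
body <- genes[, .(region_id = gene_id, chrom, start0 = body_start0,
                  end0 = body_end0)]
summaries <- rbind(
  region_methylation(merged, prom)[, region := "promoter"],
  region_methylation(merged, body)[, region := "gene_body"])
gene_meth <- summaries[!is.na(mean_meth),
                       .(meth = mean(mean_meth)), by = .(region_id, region)]
gs <- merge(gene_meth, ranks, by.x = "region_id", by.y = "gene_id")
gs <- merge(gs, genes[, .(gene_id, chrom)], by.x = "region_id",
            by.y = "gene_id")
gs[, chrom_class := fifelse(chrom == "chrX", "X", "autosome")]
corr <- spearman_meth_expression(
  gs[, .(gene_id = region_id, meth, expr = rank_bin, region, chrom_class)],
  by = c("region", "chrom_class"))
fwrite(corr, file.path(outdir, "rank_correlations.tsv"), sep = "\t")
cat("Spearman rho, region methylation vs expression rank:\n")
print(corr)
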