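test_that("config validation rejects bad inputs", {
  expect_error(sim_config(contig_specs = data.frame(
    name = "c", class = "A", length = 500L, cpg_density = 0.02)),
    "invalid config")
  expect_error(sim_config(contig_specs = data.frame(
    name = "c", class = "Z", length = 5000L, cpg_density = 0.02)),
    "invalid config")
  expect_error(sim_config(femaleX_hypo_base = 1.5), "invalid config")
  expect_error(sim_config(per_allele_depth = 0), "invalid config")
})

test_that("genome generation is deterministic and density-faithful", {
  specs <- data.frame(name = c("a", "b"), class = c("A", "A"),
                      length = c(50000L, 20000L), cpg_density = c(0.02, 0))
  cfg <- sim_config(seed = 5L, contig_specs = specs, misassembly = NULL)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$sequences, g2$sequences)
  expect_identical(g1$truth$sites, g2$truth$sites)
  # zero-density contig emits no CpG sites
  expect_equal(nrow(g1$truth$sites[chrom == "b"]), 0L)
  # binomial placement oracle: ~1000 CpGs at 0.02/bp over 50 kb
  n <- nrow(g1$truth$sites[chrom == "a"])
  expect_gte(n, 800L)
  expect_lte(n, 1200L)
  # realized dinucleotide count in the sequence matches the site table
  seq_n <- length(gregexpr("CG", g1$sequences[["a"]])[[1]])
  expect_equal(seq_n, n)
})

test_that("every autosomal/X contig gets genes; the Xist-like gene has a 5' island", {
  st <- get_study()
  gen <- st$gen
  gene_chroms <- unique(gen$genes$chrom)
  ax <- names(st$truth$contig_class)[st$truth$contig_class != "Y"]
  big_ax <- ax[st$truth$contig_lengths[ax] >= 12000L]
  expect_true(all(c("chrA1", "chrA2", "chrX") %in% gene_chroms))
  xist <- gen$genes[gene_id == st$truth$xist_gene_id]
  expect_equal(xist$chrom, "chrX")
  # a CpG island (O/E > 0.6, >= 200 bp) overlapping the gene's 5' end
  islands <- cpg_island_scan(gen$sequences[["chrX"]], chrom = "chrX",
                             min_oe = 0.6, min_len = 200L)
  loc <- st$truth$asm_locus
  hit <- islands[start0 < loc$end0 & end0 > loc$start0]
  expect_gte(nrow(hit), 1L)
  expect_gte(max(hit$end0 - hit$start0), 200L)
  # island sits at the 5' end: within the promoter/body-start neighbourhood
  expect_lte(abs(loc$start0 + (loc$end0 - loc$start0) / 2 - xist$tss0), 2000)
})

test_that("coverage structure: Poisson sums, 2:1 female X, empty female Y", {
  specs <- data.frame(name = c("a", "x", "y"), class = c("A", "X", "Y"),
                      length = 30000L, cpg_density = 0.02)
  cfg <- sim_config(seed = 6L, per_allele_depth = 6, contig_specs = specs,
                    misassembly = NULL, par_bp = 0L)
  gen <- generate_genome(cfg)
  meth <- simulate_methylomes(cfg, gen$truth)
  merged <- merge_symmetric_cpgs(meth$records)
  merged[, sex := substr(sample_id, 1, 1)]
  cov <- merged[, .(cov = sum(m + u) / data.table::uniqueN(paste(sample_id, pos0))),
                by = .(chrom, sex)]
  # autosomal site coverage = Poisson(2 x 6): mean in [11, 13]
  a <- cov[chrom == "a"]
  expect_true(all(a$cov > 11 & a$cov < 13))
  expect_lt(abs(1 - a[sex == "F", cov] / a[sex == "M", cov]), 0.2)
  # female:male X ratio in [1.8, 2.2]
  x <- cov[chrom == "x"]
  ratio <- x[sex == "F", cov] / x[sex == "M", cov]
  expect_gte(ratio, 1.8)
  expect_lte(ratio, 2.2)
  # Y contigs give no female reads
  expect_equal(nrow(meth$records[chrom == "y" &
                                   startsWith(sample_id, "F")]), 0L)
})

test_that("empirical site methylation tracks truth within 0.03 at >= 15x", {
  st <- get_study()
  merged <- st$merged
  merged2 <- data.table::copy(merged)[, sex := substr(sample_id, 1, 1)]
  bysex <- merged2[, .(m = sum(m), cov = sum(m + u)), by = .(chrom, pos0, sex)]
  bysex <- bysex[cov >= 15L]
  truth <- st$truth$sites
  jm <- merge(bysex, truth, by = c("chrom", "pos0"))
  jm[, true_meth := data.table::fifelse(sex == "F", meth_f, meth_m)]
  err <- jm[, m / cov - true_meth]
  # unbiased per sex, with noise at the binomial scale of ~45x pooled depth
  bias <- jm[, .(b = mean(m / cov - true_meth)), by = sex]
  expect_true(all(abs(bias$b) < 0.03))
  expect_lt(mean(abs(err)), 0.08)
  # degenerate binomial: truth 1.0 sites are always fully methylated
  ones <- jm[true_meth == 1]
  if (nrow(ones)) expect_true(all(ones$m == ones$cov))
})

test_that("expression link: noiseless monotone gives Spearman -1", {
  cfg <- sim_config(seed = 9L, noise_sd = 0, frac_silent = 0, de_frac = 0)
  gen <- generate_genome(cfg)
  ex <- simulate_expression(cfg, gen$truth)
  mt <- ex$expression[, .(tpm = mean(tpm)), by = gene_id]
  gg <- merge(mt, gen$truth$genes[, .(gene_id, p_base)], by = "gene_id")
  gg <- gg[gene_id != gen$truth$xist_gene_id]
  expect_equal(spearman_test(gg$p_base, gg$tpm)$value, -1)
})

test_that("default expression noise keeps rho in the plausible band", {
  # larger gene count for a stable estimate: a longer autosome
  specs <- data.frame(name = c("big1", "big2"), class = "A",
                      length = 200000L, cpg_density = 0.02)
  rhos <- vapply(1:5, function(i) {
    cfg <- sim_config(seed = 400L + i, contig_specs = specs,
                      misassembly = NULL, frac_silent = 0)
    gen <- generate_genome(cfg)
    ex <- simulate_expression(cfg, gen$truth)
    # per-sample pairs: the per-observation noise level the link is set for
    gg <- merge(ex$expression,
                gen$truth$genes[, .(gene_id, p_base)], by = "gene_id")
    spearman_test(gg$p_base, gg$tpm)$value
  }, numeric(1))
  expect_true(all(rhos > -0.8 & rhos < -0.2))
})

test_that("Xist-like expression is female-restricted", {
  st <- get_study()
  xe <- st$expr$expression[gene_id == st$truth$xist_gene_id]
  xe[, sex := substr(sample_id, 1, 1)]
  expect_lt(mean(xe[sex == "M", tpm]), 0.01 * mean(xe[sex == "F", tpm]))
  expect_true(st$truth$xist_gene_id %in%
                st$expr$de_table[significant == TRUE, gene_id])
})

test_that("ASM reads at degenerate rates are all-or-none", {
  st <- get_study()
  reads <- simulate_reads_at_locus(st$cfg, st$truth, n_reads = 40L,
                                   rate_a = 1, rate_b = 0)
  prof <- per_read_profiles(reads, st$truth$asm_locus)
  # calls outside the island follow site truth; restrict to island-only reads
  loc <- st$truth$asm_locus
  island_reads <- reads[, .(all_in = all(pos0 >= loc$start0 &
                                           pos0 < loc$end0)), by = read_id]
  pure <- prof[read_id %in% island_reads[all_in == TRUE, read_id]]
  expect_true(all(pure$per_read_fraction %in% c(0, 1)))
  expect_error(simulate_reads_at_locus(
    st$cfg, within(st$truth, asm_locus <- list(chrom = "chrX", start0 = -5L,
                                               end0 = 100L, rate_a = 1,
                                               rate_b = 0)),
    n_reads = 5L), "bounds")
})

test_that("the written bundle is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- sim_config(seed = 33L, contig_specs = data.frame(
    name = c("chrA1", "chrX", "ctgY"), class = c("A", "X", "Y"),
    length = c(30000L, 60000L, 6000L), cpg_density = 0.02))
  b1 <- simulate_bundle(cfg, d1)
  b2 <- simulate_bundle(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # truth JSON schema
  tj <- jsonlite::read_json(file.path(d1, "truth.json"))
  expect_true(all(c("contig_class", "asm_locus", "xist_gene_id",
                    "femaleX_hypo_base", "de_genes") %in% names(tj)))
})
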