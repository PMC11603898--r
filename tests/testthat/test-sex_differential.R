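test_that("per-site deltas are female minus male and drop one-sex sites", {
  sm <- data.table::data.table(
    chrom = "c", pos0 = rep(c(1L, 2L), each = 6L),
    sample_id = rep(c("F1", "F2", "F3", "M1", "M2", "M3"), 2L),
    coverage = 10L,
    fraction = c(0.2, 0.2, 0.2, 0.8, 0.8, 0.8,
                 0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
  sm <- rbind(sm, data.table::data.table(chrom = "c", pos0 = 3L,
                                         sample_id = "F1", coverage = 10L,
                                         fraction = 1))
  sx <- c(F1 = "F", F2 = "F", F3 = "F", M1 = "M", M2 = "M", M3 = "M")
  d <- per_site_delta(sm, sx)
  expect_equal(d[pos0 == 1L, delta_fm], -0.6)
  expect_equal(d[pos0 == 2L, delta_fm], 0)
  expect_false(3L %in% d$pos0)
  expect_equal(attr(d, "n_skipped"), 1L)
})

test_that("planted X hypomethylation of -0.15 is recovered at 15x, 3v3", {
  cfg <- sim_config(seed = 202L, cpg_count_attenuation = 0, par_bp = 0L)
  gen <- generate_genome(cfg)
  meth <- simulate_methylomes(cfg, gen$truth)
  sx <- stats::setNames(meth$samples$sex, meth$samples$sample_id)
  merged <- merge_symmetric_cpgs(meth$records)
  d <- per_site_delta(site_fractional_methylation(merged), sx)
  xconts <- names(gen$truth$contig_class)[gen$truth$contig_class == "X"]
  med <- median(d[chrom %in% xconts, delta_fm])
  expect_lt(abs(med - (-0.15)), 0.02)
  # autosomes are symmetric around zero
  aconts <- names(gen$truth$contig_class)[gen$truth$contig_class == "A"]
  expect_lt(abs(median(d[chrom %in% aconts, delta_fm])), 0.02)
})

test_that("gene-level deltas classify by the 0.05 promoter band", {
  mk <- function(id, f, m) data.table::data.table(
    region_id = id, sex = c("F", "M"), weighted_meth = c(f, m),
    mean_meth = c(f, m), n_sites_qualifying = 10L, n_sites_total = 10L,
    reason = "ok")
  prom <- rbind(mk("hypo", 0.70, 0.80),   # delta_mf 0.10 -> female_hypo
                mk("hyper", 0.80, 0.70),  # delta_mf -0.10 -> female_hyper
                mk("flat", 0.74, 0.75))   # inside the band
  body <- rbind(mk("hypo", 0.7, 0.7), mk("hyper", 0.7, 0.7),
                mk("flat", 0.7, 0.7))
  de <- data.table::data.table(gene_id = c("hypo", "flat", "ghost"),
                               log2fc_fm = c(0.3, -0.1, 2),
                               significant = c(TRUE, FALSE, TRUE))
  g <- per_gene_delta(prom, body, de)
  expect_equal(g[gene_id == "hypo", sex_bias_class], "female_hypo")
  expect_equal(g[gene_id == "hyper", sex_bias_class], "female_hyper")
  expect_equal(g[gene_id == "flat", sex_bias_class], "unbiased")
  expect_equal(attr(g, "unmatched_de_ids"), "ghost")
  # delta_fm = -delta_mf by construction
  expect_equal(g$prom_delta_mf, -(g[, prom_f - prom_m]))
})

test_that("chi-square and Mann-Whitney behave on toy group comparisons", {
  # identical small groups: exact P near 1
  r <- expression_fc_comparison(c(1, 2, 3, 1, 2, 3),
                                rep(c("autosome", "X"), each = 3))
  expect_equal(r$test$p, 1)
  expect_equal(unname(r$group_means), c(2, 2))
  # planted shift is detected with high power at n = 200/group
  set.seed(41)
  rej <- mean(replicate(40, {
    fc <- c(rnorm(200), rnorm(200, 0.5))
    cls <- rep(c("autosome", "X"), each = 200)
    expression_fc_comparison(fc, cls)$test$p < 0.05
  }))
  expect_gte(rej, 0.95)
})

test_that("promoter delta shrinks with CpG count under planted attenuation", {
  st <- get_xwide_study()
  sx <- st$sample_sex
  genes <- st$gen$genes
  # the ASM-island gene's promoter delta reflects allelic methylation, not
  # the attenuation relation; the binning analysis targets the latter
  xg <- genes[chrom == "chrX" & gene_id != st$truth$xist_gene_id]
  prom <- xg[, .(region_id = gene_id, chrom, start0 = prom_start0,
                 end0 = prom_end0)]
  body <- xg[, .(region_id = gene_id, chrom, start0 = body_start0,
                 end0 = body_end0)]
  ps <- region_methylation_by_sex(st$merged, prom, sx, min_sites = 1L)
  bs <- region_methylation_by_sex(st$merged, body, sx, min_sites = 1L)
  gd <- per_gene_delta(ps, bs)
  counts <- promoter_cpg_count(st$merged, xg, mode = "sites")
  bins <- cpg_count_binning(gd, counts, bin_width = 20L, top_open = 80L)
  # per-bin male-female delta decreases as promoter CpG count grows
  expect_gt(nrow(bins), 2L)
  expect_lt(bins$mean_delta_mf[nrow(bins)], bins$mean_delta_mf[1])
  fit <- stats::coef(stats::lm(mean_delta_mf ~ bin_low, data = bins))[2]
  expect_lt(fit, 0)
  # truth cross-check: simulated promoter hypo is attenuation-linear
  tg <- st$truth$genes[chrom == "chrX"]
  expect_equal(tg$hypo,
               0.15 * (1 - tg$cpg_count / 80), tolerance = 1e-12)
  # measured per-gene deltas track the planted values
  chk <- merge(gd, tg[, .(gene_id, hypo)], by = "gene_id")
  expect_lt(mean(abs(chk$prom_delta_mf - chk$hypo)), 0.03)
})

test_that("delta-expression correlation is null when expression ignores sex", {
  # expression carries no methylation-linked sex effect, so the correlation
  # between sex methylation delta and log2 fold-change should vanish;
  # several hundred autosomal genes keep the null bound tight
  specs <- data.frame(name = sprintf("nullA%d", 1:6), class = "A",
                      length = 300000L, cpg_density = 0.02)
  cfg <- sim_config(seed = 909L, contig_specs = specs, misassembly = NULL,
                    de_frac = 0, frac_silent = 0)
  gen <- generate_genome(cfg)
  meth <- simulate_methylomes(cfg, gen$truth)
  merged <- merge_symmetric_cpgs(meth$records)
  sx <- stats::setNames(meth$samples$sex, meth$samples$sample_id)
  expr <- simulate_expression(cfg, gen$truth)
  genes <- gen$genes
  prom <- genes[, .(region_id = gene_id, chrom, start0 = prom_start0,
                    end0 = prom_end0)]
  body <- genes[, .(region_id = gene_id, chrom, start0 = body_start0,
                    end0 = body_end0)]
  ps <- region_methylation_by_sex(merged, prom, sx, min_sites = 1L)
  bs <- region_methylation_by_sex(merged, body, sx, min_sites = 1L)
  gd <- per_gene_delta(ps, bs, expr$de_table)
  corr <- delta_expression_correlation(gd)
  expect_equal(nrow(corr), 4L)
  expect_gt(corr[region == "promoter" & subset == "all", n], 150L)
  expect_lt(abs(corr[region == "promoter" & subset == "all", rho]), 0.25)
  expect_lt(abs(corr[region == "gene_body" & subset == "all", rho]), 0.25)
  # perfectly anti-monotone toy input
  toy <- data.table::data.table(
    gene_id = sprintf("g%d", 1:6), prom_delta_mf = 1:6,
    body_delta_mf = 1:6, log2fc_fm = 6:1, significant = TRUE)
  tc <- delta_expression_correlation(toy)
  expect_true(all(tc$rho == -1))
  expect_error(delta_expression_correlation(rbind(toy, toy[1])),
               "duplicated")
})
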