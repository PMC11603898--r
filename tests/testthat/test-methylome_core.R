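test_that("symmetric CpG merge sums paired strands and keeps lone sites", {
  merged <- merge_symmetric_cpgs(tiny_cg_records())
  # (+,100,3/2) & (-,101,1/4) -> site 100 with (4, 6)
  s100 <- merged[pos0 == 100L]
  expect_equal(c(s100$m, s100$u), c(4L, 6L))
  # lone (-, 301) maps to the (+) coordinate 300
  expect_true(300L %in% merged$pos0)
  expect_equal(merged[pos0 == 300L, m], 2L)
  # duplicate (+) records at one position are an error
  dup <- rbind(tiny_cg_records(), tiny_cg_records()[1])
  expect_error(merge_symmetric_cpgs(dup), "duplicate")
})

test_that("merge conserves total counts on random records", {
  rec <- random_cg_records(1000L)
  merged <- merge_symmetric_cpgs(rec)
  expect_equal(sum(merged$m), sum(rec$m))
  expect_equal(sum(merged$u), sum(rec$u))
  expect_false(anyDuplicated(merged, by = c("chrom", "pos0")) > 0)
})

test_that("site methylation applies the >= 5-read filter", {
  tab <- data.table::data.table(chrom = "c", pos0 = c(1L, 2L, 3L),
                                m = c(4L, 1L, 5L), u = c(6L, 3L, 0L))
  sm <- site_fractional_methylation(tab)
  expect_equal(sm[pos0 == 1L, fraction], 0.4)
  expect_false(2L %in% sm$pos0)        # coverage 4 < 5
  expect_equal(sm[pos0 == 3L, fraction], 1)
  expect_equal(attr(sm, "prop_qualifying"), 2 / 3)
})

test_that("region summaries match hand computation and a brute-force oracle", {
  tab <- data.table::data.table(chrom = "c", pos0 = c(10L, 20L),
                                m = c(9L, 1L), u = c(1L, 1L))
  reg <- data.table::data.table(region_id = "r", chrom = "c",
                                start0 = 0L, end0 = 100L)
  s <- region_methylation(tab, reg, min_coverage = 2L, min_sites = 1L)
  expect_equal(s$weighted_meth, 10 / 12)
  expect_equal(s$mean_meth, 0.7)

  # randomized oracle: recompute both statistics from raw counts
  set.seed(21)
  big <- data.table::data.table(
    chrom = "c", pos0 = sort(sample.int(50000L, 3000L)),
    m = rpois(3000L, 5), u = rpois(3000L, 5))
  regs <- data.table::data.table(
    region_id = sprintf("r%03d", 1:200),
    chrom = "c", start0 = sample.int(45000L, 200L))
  regs[, end0 := start0 + sample(500:4000, 200L, replace = TRUE)]
  out <- region_methylation(big, regs, min_coverage = 5L, min_sites = 3L)
  for (i in sample(200L, 25L)) {
    sub <- big[pos0 >= regs$start0[i] & pos0 < regs$end0[i] & m + u > 0L]
    row <- out[region_id == regs$region_id[i]]
    if (nrow(sub) == 0L) {
      expect_identical(row$reason, "no_covered_sites")
      next
    }
    expect_equal(row$weighted_meth, sum(sub$m) / sum(sub$m + sub$u))
    q <- sub[m + u >= 5L]
    expected_mean <- if (nrow(q) > 3L) mean(q$m / (q$m + q$u)) else NA_real_
    expect_equal(row$mean_meth, expected_mean)
  }
})

test_that("weighted methylation is invariant to region splitting", {
  set.seed(8)
  tab <- data.table::data.table(chrom = "c", pos0 = 0:399,
                                m = rpois(400, 6), u = rpois(400, 3))
  whole <- region_methylation(tab, data.table::data.table(
    region_id = "w", chrom = "c", start0 = 0L, end0 = 400L))
  halves <- region_methylation(tab, data.table::data.table(
    region_id = c("a", "b"), chrom = "c",
    start0 = c(0L, 200L), end0 = c(200L, 400L)))
  cov <- tab[, sum(m + u), by = pos0 < 200L]$V1
  pooled <- sum(halves$weighted_meth * cov) / sum(cov)
  expect_equal(whole$weighted_meth, pooled, tolerance = 1e-12)
})

test_that("sex-pooled summaries pool counts (weighted) and fractions (mean)", {
  tab <- data.table::data.table(
    chrom = "c", pos0 = rep(c(10L, 20L), each = 2L),
    sample_id = rep(c("F1", "M1"), 2L),
    m = c(8L, 2L, 6L, 4L), u = c(2L, 8L, 4L, 6L))
  reg <- data.table::data.table(region_id = "r", chrom = "c",
                                start0 = 0L, end0 = 100L)
  s <- region_methylation_by_sex(tab, reg, c(F1 = "F", M1 = "M"),
                                 min_coverage = 5L, min_sites = 1L)
  expect_equal(s[sex == "F", weighted_meth], (8 + 6) / 20)
  expect_equal(s[sex == "F", mean_meth], mean(c(0.8, 0.6)))
  expect_equal(s[sex == "M", mean_meth], mean(c(0.2, 0.4)))
})

test_that("binomial thinning preserves fractions and is seeded", {
  tab <- data.table::data.table(chrom = "c", pos0 = 1:1000,
                                m = 100L, u = 100L)
  thin1 <- downsample_counts(tab, 0.5, seed = 9L)
  thin2 <- downsample_counts(tab, 0.5, seed = 9L)
  expect_identical(thin1, thin2)
  expect_identical(downsample_counts(tab, 1, seed = 1L), tab)
  # retained coverage near half (200 -> ~100), fractions unbiased
  expect_true(mean(thin1$m + thin1$u) > 90 & mean(thin1$m + thin1$u) < 110)
  frac_after <- thin1$m / (thin1$m + thin1$u)
  expect_lt(mean(abs(frac_after - 0.5)), 0.06)  # binomial noise at ~100x
  expect_lt(abs(mean(frac_after) - 0.5), 0.01)  # no bias
})

test_that("downsampled female X reproduces the hypomethylation signal", {
  st <- get_study()
  xconts <- names(st$truth$contig_class)[st$truth$contig_class == "X"]
  merged <- st$merged
  females <- names(st$sample_sex)[st$sample_sex == "F"]
  thin <- rbind(
    downsample_counts(merged[sample_id %in% females & chrom %in% xconts],
                      0.5, seed = 4L),
    merged[!(sample_id %in% females & chrom %in% xconts)])
  d_full <- per_site_delta(site_fractional_methylation(merged), st$sample_sex)
  d_thin <- per_site_delta(site_fractional_methylation(thin), st$sample_sex)
  med_full <- median(d_full[chrom %in% xconts, delta_fm])
  med_thin <- median(d_thin[chrom %in% xconts, delta_fm])
  expect_lt(abs(med_full - med_thin), 0.03)
})
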