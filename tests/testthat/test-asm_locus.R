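test_that("per-read profiles count calls and enforce the site minimum", {
  calls <- data.table::data.table(
    read_id = c("r1", "r1", "r1", "r2", "r2"),
    strand = "+", chrom = "cX",
    pos0 = c(10L, 20L, 30L, 10L, 20L),
    methylated = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  region <- list(chrom = "cX", start0 = 0L, end0 = 100L)
  p <- per_read_profiles(calls, region)
  expect_equal(p[read_id == "r1", per_read_fraction], 2 / 3)
  expect_false("r2" %in% p$read_id)   # 2 sites < minimum 3
  expect_equal(attr(p, "n_dropped"), 1L)
  # total calls conserved across kept + dropped reads
  p_all <- per_read_profiles(calls, region, min_sites_per_read = 1L)
  expect_equal(sum(p_all$n_sites), nrow(calls))
  expect_equal(sum(p_all$n_meth), sum(calls$methylated))
  # conflicting duplicate call errors
  bad <- rbind(calls, data.table::data.table(
    read_id = "r1", strand = "+", chrom = "cX", pos0 = 10L,
    methylated = FALSE))
  expect_error(per_read_profiles(bad, region), "conflicting")
})

test_that("ASM calls fire on bimodal reads and reject unimodal ones", {
  bimodal <- data.table::data.table(
    read_id = sprintf("r%d", 1:20), n_sites = 5L,
    n_meth = rep(c(0L, 5L), 10L),
    per_read_fraction = rep(c(0, 1), 10L))
  expect_true(call_asm(bimodal)$is_asm)
  middle <- data.table::copy(bimodal)[, per_read_fraction := 0.5]
  expect_false(call_asm(middle)$is_asm)
  onemode <- data.table::copy(bimodal)[, per_read_fraction := 1]
  expect_false(call_asm(onemode)$is_asm)          # low mode empty
  few <- bimodal[1:6]
  r <- call_asm(few)
  expect_true(is.na(r$is_asm))
  expect_equal(r$reason, "too_few_reads")
  # order invariance
  expect_equal(call_asm(bimodal[sample.int(20)])$frac_extreme,
               call_asm(bimodal)$frac_extreme)
})

test_that("ASM detection and rejection rates on simulated loci", {
  st <- get_study()
  cfg <- st$cfg
  truth <- st$truth
  n_rep <- 60L
  pos_calls <- logical(n_rep)
  neg_calls <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i * 10L
    reads <- simulate_reads_at_locus(cfg_i, truth, n_reads = 60L)
    pos_calls[i] <- isTRUE(call_asm(per_read_profiles(
      reads, truth$asm_locus))$is_asm)
    reads0 <- simulate_reads_at_locus(cfg_i, truth, n_reads = 60L,
                                      rate_a = 0.5, rate_b = 0.5)
    neg_calls[i] <- isTRUE(call_asm(per_read_profiles(
      reads0, truth$asm_locus))$is_asm)
  }
  expect_equal(mean(pos_calls), 1)
  expect_equal(mean(neg_calls), 0)
})

test_that("per-read fractions follow the binomial mixture oracle", {
  # construction oracle: reads with 3-8 CpGs at allele rates 0.9/0.1;
  # the extreme-read fraction matches the closed-form binomial expectation
  set.seed(55)
  k <- sample(3:8, 1000L, replace = TRUE)
  rate <- rep(c(0.9, 0.1), 500L)
  n_meth <- rbinom(1000L, k, rate)
  frac <- n_meth / k
  observed <- mean(frac >= 0.9 | frac <= 0.1)
  expected <- mean(vapply(3:8, function(kk) {
    x <- 0:kk
    p <- dbinom(x, kk, 0.9)
    sum(p[x / kk >= 0.9 | x / kk <= 0.1])
  }, numeric(1)))
  expect_lt(abs(observed - expected), 0.05)
  expect_gt(observed, 0.55)
  expect_lt(observed, 0.95)
})

test_that("per-CpG expression correlation flags ~5% under the null", {
  set.seed(61)
  n_sites <- 600L
  sm <- data.table::CJ(pos0 = seq_len(n_sites),
                       sample_id = c("F1", "F2", "F3", "M1", "M2", "M3"))
  sm[, `:=`(chrom = "cX", coverage = 10L, fraction = runif(.N))]
  expr <- stats::setNames(rnorm(6), c("F1", "F2", "F3", "M1", "M2", "M3"))
  sx <- c(F1 = "F", F2 = "F", F3 = "F", M1 = "M", M2 = "M", M3 = "M")
  cc <- cpg_expression_correlation(sm, expr, sx)
  rate <- mean(cc$significant)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
  # exact anti-monotone toy input gives r = -1
  toy <- data.table::data.table(
    chrom = "cX", pos0 = 1L, sample_id = names(expr), coverage = 10L,
    fraction = c(1, 0.8, 0.6, 0.4, 0.2, 0))
  toy_expr <- stats::setNames(0:5, names(expr))
  r1 <- cpg_expression_correlation(toy, toy_expr, sx)
  expect_equal(r1$r, -1)
  expect_equal(r1$direction, "male_hypo")  # female fractions are the high ones
  # incomplete sites are excluded and counted
  r2 <- cpg_expression_correlation(toy[-1], toy_expr, sx)
  expect_equal(nrow(r2), 0L)
  expect_equal(attr(r2, "n_excluded"), 1L)
})

test_that("delta track uses the >=2-reads-either-sex rule and finds the island", {
  st <- get_study()
  loc <- st$truth$asm_locus
  track <- region_delta_track(st$merged, st$sample_sex,
                              list(chrom = loc$chrom, start0 = 38000L,
                                   end0 = 46000L), flank = 8000L)
  # minimum of the delta track falls inside the planted hypomethylated island
  dmin <- track[which.min(delta_fm)]
  expect_gte(dmin$pos0, loc$start0)
  expect_lt(dmin$pos0, loc$end0)
  # island sites are strongly female-hypomethylated on average
  isl <- track[pos0 >= loc$start0 & pos0 < loc$end0]
  expect_lt(mean(isl$delta_fm, na.rm = TRUE), -0.2)
  # inclusion rule: a site covered in only one sex stays, with NA other mean
  one_sex <- data.table::data.table(
    chrom = "cQ", pos0 = 5L, m = 2L, u = 0L, sample_id = "F1")
  tr <- region_delta_track(one_sex, st$sample_sex,
                           list(chrom = "cQ", start0 = 0L, end0 = 10L),
                           flank = 0L)
  expect_equal(nrow(tr), 1L)
  expect_true(is.na(tr$mean_m))
  expect_equal(tr$mean_f, 1)
  # identical sexes give a flat zero track
  flat <- data.table::CJ(pos0 = 1:20,
                         sample_id = c("F1", "M1"))
  flat[, `:=`(chrom = "cQ", m = 5L, u = 5L)]
  trf <- region_delta_track(flat, st$sample_sex,
                            list(chrom = "cQ", start0 = 0L, end0 = 30L),
                            flank = 0L)
  expect_true(all(trf$delta_fm == 0))
})
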