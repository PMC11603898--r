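# Read-level allele-specific methylation (ASM) at a candidate region and
# per-CpG methylation-expression correlation across samples.

#' Per-read methylation profiles within a region
#'
#' Counts methylated and total CpG calls per read inside the region. Reads
#' with fewer than `min_sites_per_read` calls are dropped and counted.
#' Conflicting duplicate calls for one (read, position) are an error;
#' identical duplicates are collapsed.
#'
#' @param calls Read calls from [read_read_calls()].
#' @param region List or data.frame with `chrom`, `start0`, `end0`.
#' @param min_sites_per_read Minimum CpG calls per read (default 3).
#' @return `data.table` with `read_id`, `n_sites`, `n_meth`,
#'   `per_read_fraction`; dropped-read count in attribute `n_dropped`.
#' @export
per_read_profiles <- function(calls, region, min_sites_per_read = 3L) {
  dt <- data.table::as.data.table(calls)
  dt <- dt[chrom == region$chrom & pos0 >= region$start0 &
             pos0 < region$end0]
  if (nrow(dt)) {
    conf <- dt[, .(k = data.table::uniqueN(methylated)),
               by = .(read_id, pos0)][k > 1L]
    if (nrow(conf)) {
      stop("conflicting duplicate calls for read ", conf$read_id[1],
           " at position ", conf$pos0[1])
    }
    dt <- unique(dt, by = c("read_id", "pos0"))
  }
  prof <- dt[, .(n_sites = .N, n_meth = sum(methylated)), by = read_id]
  out <- prof[n_sites >= min_sites_per_read]
  out[, per_read_fraction := n_meth / n_sites]
  data.table::setattr(out, "n_dropped", nrow(prof) - nrow(out))
  out[]
}

#' Call allele-specific methylation from per-read profiles
#'
#' ASM shows as a bimodal per-read methylation distribution: one allele's
#' reads nearly fully methylated, the other's nearly unmethylated. The region
#' is called ASM when the proportion of reads at the extremes
#' (fraction <= `low_cut` or >= `high_cut`) reaches `extreme_min` AND both
#' modes hold at least `mode_min` reads.
#'
#' @param profiles Output of [per_read_profiles()].
#' @param low_cut,high_cut Extreme-read cutoffs (defaults 0.25 / 0.75).
#' @param extreme_min Minimum extreme-read proportion (default 0.8).
#' @param mode_min Minimum reads per mode (default 5).
#' @return List with `n_reads_used`, `n_low_mode`, `n_high_mode`,
#'   `frac_extreme`, `is_asm` (NA with a `reason` when reads are too few),
#'   and `fraction_summary` (quantiles of the per-read distribution).
#' @export
call_asm <- function(profiles, low_cut = 0.25, high_cut = 0.75,
                     extreme_min = 0.8, mode_min = 5L) {
  fr <- data.table::as.data.table(profiles)$per_read_fraction
  n <- length(fr)
  n_low <- sum(fr <= low_cut)
  n_high <- sum(fr >= high_cut)
  res <- list(
    n_reads_used = n, n_low_mode = n_low, n_high_mode = n_high,
    frac_extreme = if (n > 0L) (n_low + n_high) / n else NA_real_,
    fraction_summary = if (n > 0L) stats::quantile(fr) else NULL
  )
  if (n < 2L * mode_min) {
    res$is_asm <- NA
    res$reason <- "too_few_reads"
    return(res)
  }
  res$is_asm <- res$frac_extreme >= extreme_min &&
    n_low >= mode_min && n_high >= mode_min
  res$reason <- "ok"
  res
}

#' Per-CpG Pearson correlation of methylation with gene expression
#'
#' Correlates each site's fractional methylation with a gene's expression
#' across samples (exact t-based two-sided P). Only sites with complete data
#' in all `min_samples` samples are tested; incomplete sites are counted.
#' Each site is annotated with its sex-bias direction.
#'
#' @param site_meth Qualifying site methylation (`chrom`, `pos0`,
#'   `sample_id`, `fraction`).
#' @param expr_by_sample Named numeric vector: sample id -> expression.
#' @param sample_sex Named sex map (for the direction annotation).
#' @param min_samples Required complete sample count (default 6).
#' @param alpha Significance threshold flag (default 0.05).
#' @return `data.table` with `chrom`, `pos0`, `r`, `p`, `n`, `significant`,
#'   `direction`; excluded-site count in attribute `n_excluded`.
#' @export
cpg_expression_correlation <- function(site_meth, expr_by_sample, sample_sex,
                                       min_samples = 6L, alpha = 0.05) {
  dt <- data.table::as.data.table(site_meth)
  dt <- dt[sample_id %in% names(expr_by_sample)]
  counts <- dt[, .N, by = .(chrom, pos0)]
  complete <- counts[N >= min_samples]
  n_excluded <- nrow(counts) - nrow(complete)
  dt <- dt[complete, on = c("chrom", "pos0")]
  if (nrow(dt) == 0L) {
    out <- data.table::data.table(
      chrom = character(), pos0 = integer(), r = numeric(), p = numeric(),
      n = integer(), direction = character(), significant = logical())
    data.table::setattr(out, "n_excluded", n_excluded)
    return(out[])
  }
  out <- dt[, {
    e <- unname(expr_by_sample[sample_id])
    sx <- unname(sample_sex[sample_id])
    dir_delta <- mean(fraction[sx == "F"]) - mean(fraction[sx == "M"])
    if (stats::sd(fraction) == 0) {
      list(r = NA_real_, p = NA_real_, n = .N,
           direction = data.table::fifelse(dir_delta < 0, "female_hypo",
                                           data.table::fifelse(dir_delta > 0,
                                                               "male_hypo",
                                                               "none")))
    } else {
      ct <- stats::cor.test(fraction, e)
      list(r = unname(ct$estimate), p = ct$p.value, n = .N,
           direction = data.table::fifelse(dir_delta < 0, "female_hypo",
                                           data.table::fifelse(dir_delta > 0,
                                                               "male_hypo",
                                                               "none")))
    }
  }, by = .(chrom, pos0)]
  out[, significant := !is.na(p) & p < alpha]
  data.table::setattr(out, "n_excluded", n_excluded)
  out[]
}

#' Per-CpG sex means and delta track over a region
#'
#' Region-specific inclusion rule: a site is kept when its pooled coverage
#' reaches `min_reads` in females OR in males (deliberately looser than the
#' genome-wide filter, for locus plots). Sex means are unweighted averages of
#' per-sample fractions over samples with any coverage; a sex without
#' coverage gets NA but the site stays.
#'
#' @param table Merged multi-sample site table.
#' @param sample_sex Named sex map.
#' @param region List with `chrom`, `start0`, `end0`.
#' @param flank Flank added on both sides (default 30000).
#' @param min_reads Pooled-coverage inclusion threshold (default 2).
#' @return `data.table` with `chrom`, `pos0`, `mean_f`, `mean_m`,
#'   `delta_fm`, `cov_f`, `cov_m`.
#' @export
region_delta_track <- function(table, sample_sex, region, flank = 30000L,
                               min_reads = 2L) {
  dt <- data.table::as.data.table(table)
  lo <- region$start0 - flank
  hi <- region$end0 + flank
  dt <- dt[chrom == region$chrom & pos0 >= lo & pos0 < hi]
  dt <- data.table::copy(dt)[, `:=`(coverage = m + u,
                                    sex = unname(sample_sex[sample_id]))]
  dt <- dt[coverage > 0L]
  out <- dt[, {
    cf <- sum(coverage[sex == "F"]); cm <- sum(coverage[sex == "M"])
    mf <- if (any(sex == "F")) mean((m / coverage)[sex == "F"]) else NA_real_
    mm <- if (any(sex == "M")) mean((m / coverage)[sex == "M"]) else NA_real_
    list(mean_f = mf, mean_m = mm, cov_f = cf, cov_m = cm)
  }, by = .(chrom, pos0)]
  out <- out[cov_f >= min_reads | cov_m >= min_reads]
  out[, delta_fm := mean_f - mean_m]
  data.table::setorder(out, pos0)
  out[]
}
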