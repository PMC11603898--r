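# Core methylation quantification: strand merging of symmetric CpGs,
# coverage-filtered site methylation, region summaries (weighted and mean),
# and binomial count thinning.

#' Merge symmetric CpG records into strand-combined CpG sites
#'
#' CpG methylation is symmetric across strands: a (+) cytosine at position p
#' and a (-) cytosine at p+1 report the same CpG. Their counts are summed
#' into one site at the (+)-strand C coordinate p. Unpaired records are kept,
#' with lone (-)-strand records mapped to their (+)-coordinate p-1. Total
#' methylated and unmethylated counts are conserved.
#'
#' @param records `data.table` of pre-merge CG-context records with `chrom`,
#'   `pos0`, `strand`, `m`, `u` and optionally `sample_id`.
#' @return `data.table` with `chrom`, `pos0` (merged site), `m`, `u`
#'   (and `sample_id` if present), ordered by position within chrom.
#' @export
merge_symmetric_cpgs <- function(records) {
  rec <- data.table::as.data.table(records)
  if ("context" %in% names(rec)) rec <- rec[context == "CG"]
  has_sample <- "sample_id" %in% names(rec)
  keycols <- c(if (has_sample) "sample_id", "chrom", "pos0", "strand")
  if (anyDuplicated(rec, by = keycols)) {
    d <- rec[duplicated(rec, by = keycols)][1]
    stop("duplicate record at ", d$chrom, ":", d$pos0, " strand ", d$strand)
  }
  if (nrow(rec[strand == "-" & pos0 == 0L])) {
    stop("(-)-strand record at position 0 has no (+)-strand coordinate")
  }
  rec[, site_pos := ifelse(strand == "-", pos0 - 1L, pos0)]
  bycols <- c(if (has_sample) "sample_id", "chrom", "site_pos")
  out <- rec[, .(m = sum(m), u = sum(u)), by = bycols]
  data.table::setnames(out, "site_pos", "pos0")
  data.table::setorderv(out, c(if (has_sample) "sample_id", "chrom", "pos0"))
  out[]
}

#' Site-level fractional methylation with a coverage filter
#'
#' Fractional methylation (methylated reads / total reads) is emitted only
#' for sites covered by at least `min_coverage` reads in that sample.
#'
#' @param table Merged CpG site table (`chrom`, `pos0`, `m`, `u`, optionally
#'   `sample_id`).
#' @param min_coverage Minimum reads per site (default 5).
#' @return `data.table` of qualifying sites with `coverage` and `fraction`
#'   columns; the proportion of input rows qualifying is attached as
#'   attribute `prop_qualifying`.
#' @export
site_fractional_methylation <- function(table, min_coverage = 5L) {
  dt <- data.table::as.data.table(table)
  dt[, coverage := m + u]
  n_total <- nrow(dt)
  out <- dt[coverage >= min_coverage]
  out[, fraction := m / coverage]
  data.table::setattr(out, "prop_qualifying",
                      if (n_total > 0L) nrow(out) / n_total else NA_real_)
  out[]
}

# Overlap-join sites onto regions; returns site rows with a region_id column.
.sites_in_regions <- function(sites, regions) {
  s <- data.table::copy(data.table::as.data.table(sites))
  r <- data.table::as.data.table(regions)[, .(region_id, chrom, start0, end0)]
  s[, `:=`(start0 = pos0, end0 = pos0 + 1L)]
  data.table::setkey(r, chrom, start0, end0)
  ov <- data.table::foverlaps(s, r, type = "within", nomatch = NULL)
  ov[, `:=`(start0 = NULL, end0 = NULL, i.start0 = NULL, i.end0 = NULL)]
  ov
}

#' Region methylation summaries (weighted and mean)
#'
#' Two region statistics per sample: the weighted methylation level
#' `sum(m) / sum(m + u)` over all covered sites in the region, and the mean
#' methylation level, the unweighted average of the fractional methylation of
#' qualifying sites (coverage >= `min_coverage`). The mean is reported only
#' when the number of qualifying sites exceeds `min_sites`.
#'
#' @param table Merged site table with optional `sample_id`.
#' @param regions `data.table` with `region_id`, `chrom`, `start0`, `end0`
#'   (0-based half-open).
#' @param min_coverage Per-site read filter for the mean statistic (default 5).
#' @param min_sites Strict lower bound on qualifying sites for the mean
#'   (default 3, i.e. >= 4 sites required).
#' @return `data.table` with one row per region (x sample), columns
#'   `weighted_meth`, `mean_meth`, `n_sites_qualifying`, `n_sites_total`,
#'   `reason`. Regions with no covered sites get NA values and a reason code.
#' @export
region_methylation <- function(table, regions, min_coverage = 5L,
                               min_sites = 3L) {
  dt <- data.table::as.data.table(table)
  has_sample <- "sample_id" %in% names(dt)
  if (!has_sample) dt <- data.table::copy(dt)[, sample_id := "pooled"]
  ov <- .sites_in_regions(dt, regions)
  ov[, coverage := m + u]
  ov <- ov[coverage > 0L]
  summ <- ov[, {
    q <- coverage >= min_coverage
    nq <- sum(q)
    list(weighted_meth = sum(m) / sum(m + u),
         mean_meth = if (nq > min_sites) mean(m[q] / coverage[q]) else NA_real_,
         n_sites_qualifying = nq,
         n_sites_total = .N)
  }, by = .(region_id, sample_id)]
  grid <- data.table::CJ(region_id = unique(regions$region_id),
                         sample_id = unique(dt$sample_id))
  out <- summ[grid, on = c("region_id", "sample_id")]
  out[is.na(n_sites_total),
      `:=`(n_sites_qualifying = 0L, n_sites_total = 0L)]
  out[, reason := data.table::fifelse(
    n_sites_total == 0L, "no_covered_sites",
    data.table::fifelse(is.na(mean_meth), "too_few_qualifying_sites", "ok"))]
  if (!has_sample) out[, sample_id := NULL]
  out[]
}

#' Region methylation pooled to sex level
#'
#' The weighted statistic pools raw counts across same-sex samples; the mean
#' statistic first averages per-sample fractional methylation at each
#' qualifying site across the sex's samples, then averages over sites.
#'
#' @param table Merged multi-sample site table (`sample_id` required).
#' @param regions Region table as in [region_methylation()].
#' @param sample_sex Named character vector mapping sample id to "F"/"M".
#' @param min_coverage,min_sites As in [region_methylation()].
#' @return `data.table` with one row per region x sex.
#' @export
region_methylation_by_sex <- function(table, regions, sample_sex,
                                      min_coverage = 5L, min_sites = 3L) {
  dt <- data.table::as.data.table(table)
  if (!all(unique(dt$sample_id) %in% names(sample_sex))) {
    stop("sample_sex is missing labels for some samples")
  }
  if (!all(sample_sex %in% c("F", "M"))) stop("sex labels must be 'F' or 'M'")
  ov <- .sites_in_regions(dt, regions)
  ov[, `:=`(coverage = m + u, sex = unname(sample_sex[sample_id]))]
  ov <- ov[coverage > 0L]
  summ <- ov[, {
    q <- coverage >= min_coverage
    site_means <- if (any(q)) {
      fr <- m[q] / coverage[q]
      tapply(fr, pos0[q], mean)
    } else numeric(0)
    nq <- length(site_means)
    list(weighted_meth = sum(m) / sum(m + u),
         mean_meth = if (nq > min_sites) mean(site_means) else NA_real_,
         n_sites_qualifying = nq,
         n_sites_total = length(unique(pos0)))
  }, by = .(region_id, sex)]
  summ[, reason := data.table::fifelse(is.na(mean_meth),
                                       "too_few_qualifying_sites", "ok")]
  summ[]
}

#' Binomial thinning of methylation counts
#'
#' Each read is retained independently with probability `keep_fraction`
#' (methylated and unmethylated counts thinned separately), emulating read
#' downsampling at the count level. Deterministic under `seed`.
#'
#' @param table Merged site table.
#' @param keep_fraction Retention probability in (0, 1].
#' @param seed Integer seed.
#' @return Table of the same shape with thinned `m`, `u`.
#' @export
downsample_counts <- function(table, keep_fraction = 0.5, seed = 1L) {
  if (keep_fraction <= 0 || keep_fraction > 1) {
    stop("keep_fraction must be in (0, 1]")
  }
  dt <- data.table::copy(data.table::as.data.table(table))
  if (keep_fraction == 1) return(dt[])
  set.seed(as.integer(seed))
  dt[, `:=`(m = stats::rbinom(.N, m, keep_fraction),
            u = stats::rbinom(.N, u, keep_fraction))]
  dt[]
}
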