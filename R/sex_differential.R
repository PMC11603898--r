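# Female-male methylation differences at site and gene level, sex-bias
# classification, CpG-count dependence, and expression fold-change
# comparisons.

#' Per-site female-male methylation delta
#'
#' The sex mean at a site is the unweighted mean of per-sample fractional
#' methylation (samples are biological replicates). Sites lacking a
#' qualifying sample in either sex are skipped and counted.
#'
#' @param site_meth Qualifying site methylation (output of
#'   [site_fractional_methylation()] on a multi-sample table): `chrom`,
#'   `pos0`, `sample_id`, `fraction`.
#' @param sample_sex Named vector mapping sample id to "F"/"M".
#' @param min_samples_per_sex Minimum qualifying samples per sex (default 1).
#' @return `data.table` with `chrom`, `pos0`, `mean_f`, `mean_m`, `n_f`,
#'   `n_m`, `delta_fm` (female - male); skipped-site count in attribute
#'   `n_skipped`.
#' @export
per_site_delta <- function(site_meth, sample_sex, min_samples_per_sex = 1L) {
  dt <- data.table::as.data.table(site_meth)
  if (!all(unique(dt$sample_id) %in% names(sample_sex))) {
    stop("sample_sex is missing labels for some samples")
  }
  dt <- data.table::copy(dt)[, sex := unname(sample_sex[sample_id])]
  agg <- dt[, .(mean_f = mean(fraction[sex == "F"]),
                mean_m = mean(fraction[sex == "M"]),
                n_f = sum(sex == "F"), n_m = sum(sex == "M")),
            by = .(chrom, pos0)]
  keep <- agg[n_f >= min_samples_per_sex & n_m >= min_samples_per_sex]
  keep[, delta_fm := mean_f - mean_m]
  data.table::setattr(keep, "n_skipped", nrow(agg) - nrow(keep))
  keep[]
}

#' Summarise a per-site delta distribution by chromosome
#'
#' @param deltas Output of [per_site_delta()].
#' @return Per-chromosome `n`, mean, median and quartiles of `delta_fm`.
#' @export
delta_distribution_summary <- function(deltas) {
  data.table::as.data.table(deltas)[, .(
    n = .N, mean = mean(delta_fm), median = stats::median(delta_fm),
    q25 = stats::quantile(delta_fm, 0.25), q75 = stats::quantile(delta_fm, 0.75)
  ), by = chrom]
}

#' Per-gene sex methylation deltas and bias classes
#'
#' Joins promoter and gene-body sex-level mean methylation with the external
#' differential-expression table. `delta_mf` is male minus female; a gene is
#' `female_hypo` when promoter `delta_mf` exceeds `delta_threshold`,
#' `female_hyper` below the negative threshold, else `unbiased`.
#'
#' @param promoter_by_sex,body_by_sex Outputs of
#'   [region_methylation_by_sex()] with `region_id` = gene id.
#' @param de_table Differential-expression labels from [read_de_table()]
#'   (optional).
#' @param delta_threshold Class boundary on the promoter delta (default 0.05).
#' @return `data.table` with one row per gene having both sexes' promoter
#'   means: `prom_delta_mf`, `body_delta_mf`, `sex_bias_class`, `log2fc_fm`,
#'   `significant`. Attributes: `n_missing_sex` (genes dropped),
#'   `unmatched_de_ids`.
#' @export
per_gene_delta <- function(promoter_by_sex, body_by_sex, de_table = NULL,
                           delta_threshold = 0.05) {
  wide <- function(x, prefix) {
    dt <- data.table::as.data.table(x)
    w <- data.table::dcast(dt, region_id ~ sex, value.var = "mean_meth")
    for (cc in c("F", "M")) if (!cc %in% names(w)) w[, (cc) := NA_real_]
    data.table::setnames(w, c("F", "M"),
                         paste0(prefix, c("_f", "_m")))
    w
  }
  p <- wide(promoter_by_sex, "prom")
  b <- wide(body_by_sex, "body")
  g <- merge(p, b, by = "region_id", all = TRUE)
  data.table::setnames(g, "region_id", "gene_id")
  n_all <- nrow(g)
  g <- g[!is.na(prom_f) & !is.na(prom_m)]
  g[, prom_delta_mf := prom_m - prom_f]
  g[, body_delta_mf := body_m - body_f]
  g[, sex_bias_class := data.table::fifelse(
    prom_delta_mf > delta_threshold, "female_hypo",
    data.table::fifelse(prom_delta_mf < -delta_threshold, "female_hyper",
                        "unbiased"))]
  unmatched <- character(0)
  if (!is.null(de_table)) {
    de <- data.table::as.data.table(de_table)
    unmatched <- setdiff(de$gene_id, g$gene_id)
    g <- merge(g, de[, .(gene_id, log2fc_fm, significant)], by = "gene_id",
               all.x = TRUE)
  } else {
    g[, `:=`(log2fc_fm = NA_real_, significant = NA)]
  }
  data.table::setattr(g, "n_missing_sex", n_all - nrow(g))
  data.table::setattr(g, "unmatched_de_ids", unmatched)
  g[]
}

#' Mean methylation and sex delta by promoter CpG-count bin
#'
#' Bins promoter CpG counts in steps of `bin_width`, with an open-ended top
#' bin above `top_open`. Reports per-bin mean male and female promoter
#' methylation and the male-female delta. Empty bins are omitted.
#'
#' @param gene_deltas Output of [per_gene_delta()] (needs `prom_f`, `prom_m`).
#' @param cpg_counts Output of [promoter_cpg_count()].
#' @param bin_width Bin width in CpGs (default 5).
#' @param top_open Lower edge of the open top bin (default 80).
#' @return `data.table` with `bin_low`, `bin_high` (Inf for the top bin),
#'   `mean_meth_m`, `mean_meth_f`, `mean_delta_mf`, `n_genes`.
#' @export
cpg_count_binning <- function(gene_deltas, cpg_counts, bin_width = 5L,
                              top_open = 80L) {
  g <- merge(data.table::as.data.table(gene_deltas),
             data.table::as.data.table(cpg_counts)[, .(gene_id, cpg_count)],
             by = "gene_id")
  g[, bin_low := pmin(as.integer(cpg_count %/% bin_width) * bin_width,
                      as.integer(top_open))]
  out <- g[, .(mean_meth_m = mean(prom_m), mean_meth_f = mean(prom_f),
               mean_delta_mf = mean(prom_delta_mf), n_genes = .N),
           by = bin_low]
  out[, bin_high := data.table::fifelse(bin_low >= top_open, Inf,
                                        bin_low + bin_width)]
  data.table::setorder(out, bin_low)
  data.table::setcolorder(out, c("bin_low", "bin_high"))
  out[]
}

#' Compare expression fold-change distributions between chromosome classes
#'
#' @param log2fc Numeric vector of log2 female/male fold-changes.
#' @param chrom_class Character vector ("autosome"/"X") parallel to `log2fc`.
#' @return List with `group_means` (named) and `test` (a [mann_whitney()]
#'   result comparing the two classes).
#' @export
expression_fc_comparison <- function(log2fc, chrom_class) {
  keep <- !is.na(log2fc) & !is.na(chrom_class)
  log2fc <- log2fc[keep]; chrom_class <- chrom_class[keep]
  cls <- sort(unique(chrom_class))
  if (length(cls) != 2L) stop("need exactly two chromosome classes")
  ga <- log2fc[chrom_class == cls[1]]
  gb <- log2fc[chrom_class == cls[2]]
  means <- stats::setNames(c(mean(ga), mean(gb)), cls)
  list(group_means = means, test = mann_whitney(ga, gb))
}

#' Spearman correlation of methylation delta with expression fold-change
#'
#' Four correlations: (promoter, gene body) x (all genes, significant-only).
#'
#' @param gene_deltas Output of [per_gene_delta()] with `log2fc_fm` and
#'   `significant` filled.
#' @return `data.table` with `region`, `subset`, `rho`, `p`, `n`.
#' @export
delta_expression_correlation <- function(gene_deltas) {
  g <- data.table::as.data.table(gene_deltas)
  if (anyDuplicated(g$gene_id)) stop("duplicated gene rows")
  one <- function(delta, fc, region, subset) {
    keep <- !is.na(delta) & !is.na(fc)
    st <- spearman_test(delta[keep], fc[keep])
    data.table::data.table(region = region, subset = subset,
                           rho = st$value, p = st$p, n = st$n)
  }
  sig <- g[significant %in% TRUE]
  rbind(
    one(g$prom_delta_mf, g$log2fc_fm, "promoter", "all"),
    one(g$body_delta_mf, g$log2fc_fm, "gene_body", "all"),
    one(sig$prom_delta_mf, sig$log2fc_fm, "promoter", "significant"),
    one(sig$body_delta_mf, sig$log2fc_fm, "gene_body", "significant")
  )
}
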