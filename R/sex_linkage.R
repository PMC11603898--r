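# Read-depth-ratio classification of contigs into autosome/X/Y linkage and
# windowed sex-specific depth-anomaly scanning.
#
# The metric is D = 1 - (mean read-depth in females)/(mean read-depth in
# males), computed over CG-context cytosines (pre-merge, both strands).
# Expected values: ~0 for autosomal contigs, ~-1 for X-linked (females carry
# two X copies), ~1 for Y-linked (females carry none).

#' Per-contig sex-averaged cytosine read depth
#'
#' The cytosine universe of a contig is every CG-context cytosine covered in
#' at least one sample; per-sample mean depth is taken over that universe
#' (zero for uncovered cytosines), then averaged over each sex's samples
#' unweighted.
#'
#' @param records Pre-merge CG cytosine records with `chrom`, `pos0`,
#'   `strand`, `m`, `u`, `sample_id`.
#' @param sample_sex Named vector mapping sample id to "F"/"M".
#' @param min_cytosines Contigs with `n_cytosines <= min_cytosines` are
#'   flagged ineligible (default 40).
#' @return `data.table` with `contig`, `n_cytosines`, `mean_depth_female`,
#'   `mean_depth_male`, `eligible`.
#' @export
contig_depth_summary <- function(records, sample_sex, min_cytosines = 40L) {
  dt <- data.table::as.data.table(records)
  samples <- unique(dt$sample_id)
  if (!all(samples %in% names(sample_sex))) {
    stop("sample_sex is missing labels for some samples")
  }
  if (!all(sample_sex[samples] %in% c("F", "M"))) {
    stop("unknown sex label; use 'F' or 'M'")
  }
  dt <- dt[m + u > 0L]
  # universe size per contig: distinct covered cytosines across samples
  uni <- dt[, .(n_cytosines = data.table::uniqueN(paste(pos0, strand))),
            by = .(contig = chrom)]
  depth_sum <- dt[, .(total_depth = sum(m + u)),
                  by = .(contig = chrom, sample_id)]
  grid <- data.table::CJ(contig = uni$contig, sample_id = samples)
  depth_sum <- depth_sum[grid, on = c("contig", "sample_id")]
  depth_sum[is.na(total_depth), total_depth := 0]
  depth_sum <- merge(depth_sum, uni, by = "contig")
  depth_sum[, mean_depth := total_depth / n_cytosines]
  depth_sum[, sex := unname(sample_sex[sample_id])]
  out <- depth_sum[, .(
    n_cytosines = n_cytosines[1],
    mean_depth_female = mean(mean_depth[sex == "F"]),
    mean_depth_male = mean(mean_depth[sex == "M"])
  ), by = contig]
  out[, eligible := n_cytosines > min_cytosines]
  out[]
}

#' Classify contigs by the sex depth-ratio metric
#'
#' D = 1 - F/M. Classes: `Y` iff D > `y_min`; `A` iff
#' `a_bounds[1] <= D <= a_bounds[2]`; `X` iff D < `a_bounds[1]`... strictly,
#' X iff D < -0.5, A on the closed interval, Y strictly above 0.95, and the
#' gap (0.5, 0.95] is `unclassified`, as are contigs with zero male depth or
#' too few cytosines.
#'
#' @param depth_records Output of [contig_depth_summary()].
#' @param y_min Y threshold (default 0.95, strict).
#' @param a_bounds Closed autosomal interval (default c(-0.5, 0.5)).
#' @return `data.table` with `contig`, `D`, `class_label`
#'   (A/X/Y/unclassified), `reason`.
#' @export
classify_contig <- function(depth_records, y_min = 0.95,
                            a_bounds = c(-0.5, 0.5)) {
  dt <- data.table::copy(data.table::as.data.table(depth_records))
  dt[, D := data.table::fifelse(mean_depth_male > 0,
                                1 - mean_depth_female / mean_depth_male,
                                NA_real_)]
  dt[, `:=`(class_label = "unclassified", reason = "")]
  dt[eligible == FALSE, reason := "too_few_cytosines"]
  dt[eligible & is.na(D), reason := "zero_male_depth"]
  ok <- dt$eligible & !is.na(dt$D)
  dt[ok & D > y_min, `:=`(class_label = "Y", reason = "ok")]
  dt[ok & D >= a_bounds[1] & D <= a_bounds[2],
     `:=`(class_label = "A", reason = "ok")]
  dt[ok & D < a_bounds[1], `:=`(class_label = "X", reason = "ok")]
  dt[ok & class_label == "unclassified", reason := "gap_interval"]
  dt[, .(contig, n_cytosines, mean_depth_female, mean_depth_male, D,
         class_label, reason)]
}

#' Windowed sex-specific depth-anomaly scan along a chromosome
#'
#' Tiles one assembled chromosome with fixed windows and flags each as
#' `female_absent` (mean female depth below `absent_threshold` while male
#' depth is at least `present_threshold`; the signature of misassembled
#' Y-linked sequence), `PAR_like` (female:male depth ratio within `par_tol`
#' of 1 on a sex chromosome), or `normal`. Contiguous flagged windows are
#' merged into exclusion intervals. Windows without cytosines are skipped.
#'
#' @param records Pre-merge cytosine records (as in
#'   [contig_depth_summary()]) for the chromosome of interest.
#' @param sample_sex Named sex map.
#' @param target_chrom Chromosome to scan.
#' @param window Window size in bp (default 100000).
#' @param absent_threshold,present_threshold Female-absent rule (defaults
#'   0.5 and 5).
#' @param par_tol PAR rule: |1 - F/M| < par_tol (default 0.2).
#' @param chrom_length Optional length; defaults to the last covered
#'   position + 1.
#' @return List: `windows` (per-window `start0`, `end0`, `mean_f`, `mean_m`,
#'   `flag`), `female_absent_intervals`, `par_like_intervals` (merged).
#' @export
windowed_depth_scan <- function(records, sample_sex, target_chrom,
                                window = 100000L, absent_threshold = 0.5,
                                present_threshold = 5, par_tol = 0.2,
                                chrom_length = NULL) {
  dt <- data.table::as.data.table(records)
  dt <- dt[chrom == target_chrom]
  if (nrow(dt) == 0L) stop("no records on chromosome ", target_chrom)
  if (is.null(chrom_length)) chrom_length <- max(dt$pos0) + 1L
  dt <- dt[m + u > 0L]
  dt[, window_id := pos0 %/% as.integer(window)]
  nF <- sum(sample_sex[unique(dt$sample_id)] == "F")
  nM <- sum(sample_sex[unique(dt$sample_id)] == "M")
  dt[, sex := unname(sample_sex[sample_id])]
  win <- dt[, {
    n_cyt <- data.table::uniqueN(paste(pos0, strand))
    list(n_cytosines = n_cyt,
         mean_f = sum((m + u)[sex == "F"]) / (n_cyt * nF),
         mean_m = sum((m + u)[sex == "M"]) / (n_cyt * nM))
  }, by = window_id]
  win[, `:=`(start0 = window_id * as.integer(window),
             end0 = pmin((window_id + 1L) * as.integer(window),
                         as.integer(chrom_length)))]
  win[, flag := data.table::fifelse(
    mean_f < absent_threshold & mean_m >= present_threshold, "female_absent",
    data.table::fifelse(mean_m > 0 & abs(1 - mean_f / mean_m) < par_tol,
                        "PAR_like", "normal"))]
  data.table::setorder(win, start0)
  merge_flag <- function(f) {
    w <- win[flag == f]
    if (nrow(w) == 0L) {
      return(data.table::data.table(chrom = character(), start0 = integer(),
                                    end0 = integer()))
    }
    grp <- cumsum(c(1L, diff(w$window_id) != 1L))
    w[, .(chrom = target_chrom, start0 = min(start0), end0 = max(end0)),
      by = .(grp = grp)][, grp := NULL][]
  }
  list(windows = win[, .(chrom = target_chrom, start0, end0, n_cytosines,
                         mean_f, mean_m, flag)],
       female_absent_intervals = merge_flag("female_absent"),
       par_like_intervals = merge_flag("PAR_like"))
}

#' Methylation distributions by contig linkage class
#'
#' For each classified contig, computes the per-sample weighted methylation
#' over sites with at least `min_coverage` reads, then summarises per
#' class x sample (mean over contigs). Female samples contribute no values on
#' Y-class contigs (zero coverage).
#'
#' @param site_table Merged multi-sample CpG site table.
#' @param calls Output of [classify_contig()].
#' @param min_coverage Site read filter (default 5).
#' @return List: `per_contig` (contig x sample weighted methylation with
#'   class), `per_class` (class x sample mean over contigs, with n).
#' @export
contig_class_methylation <- function(site_table, calls, min_coverage = 5L) {
  dt <- data.table::as.data.table(site_table)
  dt[, coverage := m + u]
  q <- dt[coverage >= min_coverage]
  per_contig <- q[, .(weighted_meth = sum(m) / sum(m + u), n_sites = .N),
                  by = .(contig = chrom, sample_id)]
  per_contig <- merge(per_contig,
                      data.table::as.data.table(calls)[, .(contig, class_label)],
                      by = "contig")
  per_class <- per_contig[, .(mean_meth = mean(weighted_meth),
                              n_contigs = .N),
                          by = .(class_label, sample_id)]
  data.table::setorder(per_class, class_label, sample_id)
  list(per_contig = per_contig[], per_class = per_class[])
}
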