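# End-to-end orchestration: reads a sample sheet plus annotation/expression
# inputs, runs the stages in dependency order, and writes tables and JSON
# reports with reproducibility metadata. The numbered scripts under analysis/
# drive the same functions stage by stage.

#' Default pipeline thresholds
#' @return Named list of tunable parameters.
#' @export
pipeline_params <- function() {
  list(min_coverage = 5L, min_sites = 3L, delta_threshold = 0.05,
       flank_bp = 2000L, body_bins = 60L, flank_bin_bp = 100L,
       n_rank_bins = 20L, oe_window = 1000L, oe_step = 500L,
       min_cytosines = 40L, y_min = 0.95, a_bounds = c(-0.5, 0.5),
       scan_window = 2000L, absent_threshold = 0.5,
       # present_threshold must sit below the single-copy male depth of the
       # data being scanned; 2 suits the bundled generator's depth scale
       present_threshold = 2,
       par_tol = 0.2, min_sites_per_read = 3L, low_cut = 0.25,
       high_cut = 0.75, extreme_min = 0.8, mode_min = 5L,
       asm_flank = 2000L, cpg_bin_width = 5L, cpg_top_open = 80L)
}

#' Run the full analysis pipeline
#'
#' Stages in dependency order: input parsing, CpG merging and filtering,
#' region summaries, metagene/rank profiles, sex-differential statistics,
#' sex-linkage classification and depth-anomaly scan, and ASM analysis.
#' Sex-comparison stages are skipped with a notice when a sex has no
#' samples. Outputs are written as TSV/JSON under `outdir` together with a
#' metadata file carrying the package version and a hash of the
#' configuration; a rerun with the same inputs reproduces identical tables.
#'
#' @param inputs List with paths: `sample_sheet` (TSV: sample_id, sex, path),
#'   `gtf`, `expression`, `de_table`, optionally `fasta`, `read_calls`,
#'   `asm_region` (list chrom/start0/end0), `x_chrom` (chromosome to scan),
#'   `assembled_chroms` (character; the rest are treated as unplaced
#'   contigs).
#' @param outdir Output directory.
#' @param params Thresholds; see [pipeline_params()].
#' @return Invisible list of in-memory stage results and output paths.
#' @export
run_pipeline <- function(inputs, outdir, params = pipeline_params()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  notices <- character(0)
  for (f in c("sample_sheet", "gtf", "expression", "de_table")) {
    if (is.null(inputs[[f]]) || !file.exists(inputs[[f]])) {
      stop("stage io: missing required input '", f, "'")
    }
  }
  sheet <- data.table::fread(inputs$sample_sheet)
  if (!all(c("sample_id", "sex", "path") %in% names(sheet))) {
    stop("stage io: sample sheet needs sample_id, sex, path")
  }
  # report paths may be relative to the sheet's directory
  sheet[, path := data.table::fifelse(
    file.exists(path), path,
    file.path(dirname(inputs$sample_sheet), path))]
  sample_sex <- stats::setNames(sheet$sex, sheet$sample_id)
  have_both_sexes <- all(c("F", "M") %in% sheet$sex)
  if (!have_both_sexes) {
    notices <- c(notices,
                 "sex-comparison stages skipped: need >=1 sample per sex")
  }
  records <- data.table::rbindlist(lapply(seq_len(nrow(sheet)), function(i) {
    r <- read_cytosine_report(sheet$path[i], contexts = "CG")
    r[, sample_id := sheet$sample_id[i]]
    r
  }))
  genes <- read_gene_annotation(inputs$gtf, format = "gtf")
  expr <- read_expression_table(inputs$expression)
  de <- read_de_table(inputs$de_table)

  # core ---------------------------------------------------------------------
  merged <- merge_symmetric_cpgs(records)
  site_meth <- site_fractional_methylation(merged, params$min_coverage)
  promoters <- genes[, .(region_id = gene_id, chrom, start0 = prom_start0,
                         end0 = prom_end0)]
  bodies <- genes[, .(region_id = gene_id, chrom, start0 = body_start0,
                      end0 = body_end0)]
  prom_sample <- region_methylation(merged, promoters, params$min_coverage,
                                    params$min_sites)
  body_sample <- region_methylation(merged, bodies, params$min_coverage,
                                    params$min_sites)
  data.table::fwrite(prom_sample, file.path(outdir, "promoter_methylation.tsv"),
                     sep = "\t")
  data.table::fwrite(body_sample, file.path(outdir, "body_methylation.tsv"),
                     sep = "\t")

  # profiles -----------------------------------------------------------------
  mean_tpm <- expr[, .(tpm = mean(tpm)), by = gene_id]
  ranks <- assign_expression_ranks(
    stats::setNames(mean_tpm$tpm, mean_tpm$gene_id), params$n_rank_bins)
  profile <- metagene_profile(merged, genes, params$flank_bp,
                              params$body_bins, params$flank_bin_bp)
  rank_profiles <- rank_methylation_profile(merged, genes, ranks,
                                            flank_bp = params$flank_bp,
                                            body_bins = params$body_bins,
                                            flank_bin_bp = params$flank_bin_bp)
  data.table::fwrite(profile, file.path(outdir, "metagene_profile.tsv"),
                     sep = "\t")
  data.table::fwrite(rank_profiles, file.path(outdir, "rank_profiles.tsv"),
                     sep = "\t")

  results <- list(genes = genes, merged = merged, site_meth = site_meth,
                  ranks = ranks, profile = profile,
                  rank_profiles = rank_profiles, notices = notices)

  # sex-differential + sex-linkage + ASM -------------------------------------
  if (have_both_sexes) {
    prom_sex <- region_methylation_by_sex(merged, promoters, sample_sex,
                                          params$min_coverage, params$min_sites)
    body_sex <- region_methylation_by_sex(merged, bodies, sample_sex,
                                          params$min_coverage, params$min_sites)
    deltas <- per_site_delta(site_meth, sample_sex)
    gene_deltas <- per_gene_delta(prom_sex, body_sex, de,
                                  params$delta_threshold)
    cpg_counts <- promoter_cpg_count(merged, genes, mode = "sites")
    bins <- cpg_count_binning(gene_deltas, cpg_counts,
                              params$cpg_bin_width, params$cpg_top_open)
    corr <- delta_expression_correlation(gene_deltas)
    data.table::fwrite(deltas, file.path(outdir, "site_deltas.tsv"), sep = "\t")
    data.table::fwrite(gene_deltas, file.path(outdir, "gene_deltas.tsv"),
                       sep = "\t")
    data.table::fwrite(bins, file.path(outdir, "cpg_count_bins.tsv"),
                       sep = "\t")
    data.table::fwrite(corr, file.path(outdir, "delta_expression_corr.tsv"),
                       sep = "\t")
    results$deltas <- deltas
    results$gene_deltas <- gene_deltas
    results$cpg_bins <- bins
    results$delta_expr_corr <- corr

    assembled <- inputs$assembled_chroms
    if (is.null(assembled)) assembled <- unique(genes$chrom)
    unplaced <- records[!chrom %in% assembled]
    if (nrow(unplaced)) {
      depth <- contig_depth_summary(unplaced, sample_sex,
                                    params$min_cytosines)
      calls <- classify_contig(depth, params$y_min, params$a_bounds)
      cls_meth <- contig_class_methylation(
        merged[!chrom %in% assembled], calls, params$min_coverage)
      data.table::fwrite(calls, file.path(outdir, "contig_classes.tsv"),
                         sep = "\t")
      data.table::fwrite(cls_meth$per_class,
                         file.path(outdir, "contig_class_methylation.tsv"),
                         sep = "\t")
      results$contig_calls <- calls
      results$contig_class_meth <- cls_meth
    }
    if (!is.null(inputs$x_chrom)) {
      scan <- windowed_depth_scan(records, sample_sex, inputs$x_chrom,
                                  window = params$scan_window,
                                  absent_threshold = params$absent_threshold,
                                  present_threshold = params$present_threshold,
                                  par_tol = params$par_tol)
      data.table::fwrite(scan$windows, file.path(outdir, "depth_scan.tsv"),
                         sep = "\t")
      data.table::fwrite(scan$female_absent_intervals,
                         file.path(outdir, "female_absent_intervals.bed"),
                         sep = "\t", col.names = FALSE)
      results$depth_scan <- scan
    }
    if (!is.null(inputs$read_calls) && !is.null(inputs$asm_region)) {
      calls_rd <- read_read_calls(inputs$read_calls)
      profs <- per_read_profiles(calls_rd, inputs$asm_region,
                                 params$min_sites_per_read)
      asm <- call_asm(profs, params$low_cut, params$high_cut,
                      params$extreme_min, params$mode_min)
      track <- region_delta_track(merged, sample_sex, inputs$asm_region,
                                  flank = params$asm_flank)
      data.table::fwrite(profs, file.path(outdir, "asm_read_profiles.tsv"),
                         sep = "\t")
      data.table::fwrite(track, file.path(outdir, "asm_delta_track.tsv"),
                         sep = "\t")
      jsonlite::write_json(asm[c("n_reads_used", "n_low_mode", "n_high_mode",
                                 "frac_extreme", "is_asm", "reason")],
                           file.path(outdir, "asm_call.json"),
                           auto_unbox = TRUE, digits = NA)
      results$asm <- asm
      results$asm_track <- track
    }
  }

  meta <- list(
    package_version = as.character(utils::packageVersion("methylsex")),
    config_hash = sum(utf8ToInt(paste(
      names(unlist(params)), unlist(params), collapse = ";"))),
    inputs = inputs[vapply(inputs, is.character, logical(1))],
    notices = notices)
  jsonlite::write_json(meta, file.path(outdir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
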