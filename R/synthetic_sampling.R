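# Sampling layers of the synthetic generator: per-sample cytosine reports,
# expression tables with planted sex effects, and per-read methylation calls
# at the ASM locus.

# allele copy number per (contig class, sex), with the PAR carrying two
# copies in males and the misassembled Y-in-X interval carrying none in
# females
.allele_copies <- function(truth, chrom, pos0, sex) {
  cls <- unname(truth$contig_class[chrom])
  copies <- ifelse(cls == "A", 2L,
                   ifelse(cls == "X", ifelse(sex == "F", 2L, 1L),
                          ifelse(sex == "F", 0L, 1L)))
  pr <- truth$par_region
  if (!is.null(pr) && sex == "M") {
    copies[chrom == pr$chrom & pos0 >= pr$start0 & pos0 < pr$end0] <- 2L
  }
  mr <- truth$misassembled_region
  if (!is.null(mr)) {
    inmis <- chrom == mr$chrom & pos0 >= mr$start0 & pos0 < mr$end0
    copies[inmis] <- if (sex == "F") 0L else 1L
  }
  copies
}

#' Simulate per-sample cytosine reports from the ground truth
#'
#' Per CpG site and sample, each strand's coverage is Poisson with mean
#' (allele copies x per_allele_depth / 2), so merged site coverage is Poisson
#' with mean copies x per_allele_depth; methylated counts are Binomial at the
#' sex's true site methylation. At the ASM island, female reads are drawn per
#' allele at the allele-specific rates. Records are emitted pre-merge (both
#' strands), CG context.
#'
#' @param config A [sim_config()].
#' @param truth Truth record from [generate_genome()].
#' @return List: `samples` (`sample_id`, `sex`), `records` (long pre-merge
#'   cytosine table with `sample_id`).
#' @export
simulate_methylomes <- function(config, truth) {
  set.seed(config$seed + 1L)
  samples <- data.table::data.table(
    sample_id = c(sprintf("F%d", seq_len(config$n_female)),
                  sprintf("M%d", seq_len(config$n_male))),
    sex = c(rep("F", config$n_female), rep("M", config$n_male))
  )
  sites <- truth$sites
  dep <- config$per_allele_depth
  recs <- list()
  for (si in seq_len(nrow(samples))) {
    sx <- samples$sex[si]
    copies <- .allele_copies(truth, sites$chrom, sites$pos0, sx)
    meth <- if (sx == "F") sites$meth_f else sites$meth_m
    asm_f <- sx == "F" & sites$is_asm & copies == 2L
    n <- nrow(sites)
    draw_strand <- function() {
      cov <- stats::rpois(n, copies * dep / 2)
      m <- stats::rbinom(n, cov, meth)
      if (any(asm_f)) {
        ca <- stats::rpois(sum(asm_f), dep / 2)
        cb <- stats::rpois(sum(asm_f), dep / 2)
        cov[asm_f] <- ca + cb
        m[asm_f] <- stats::rbinom(sum(asm_f), ca, truth$asm_locus$rate_a) +
          stats::rbinom(sum(asm_f), cb, truth$asm_locus$rate_b)
      }
      list(cov = cov, m = m)
    }
    plus <- draw_strand()
    minus <- draw_strand()
    recs[[si]] <- data.table::data.table(
      chrom = rep(sites$chrom, 2L),
      pos0 = c(sites$pos0, sites$pos0 + 1L),
      strand = rep(c("+", "-"), each = n),
      context = "CG",
      m = c(plus$m, minus$m),
      u = c(plus$cov - plus$m, minus$cov - minus$m),
      sample_id = samples$sample_id[si]
    )
  }
  records <- data.table::rbindlist(recs)
  records <- records[m + u > 0L]
  data.table::setorder(records, sample_id, chrom, pos0)
  list(samples = samples, records = records[])
}

#' Simulate expression tables and differential-expression labels
#'
#' Per-gene mean abundance follows the monotone-decreasing link
#' `expr_scale * exp(-expr_slope * p_base)` of the gene's baseline promoter
#' methylation (sex-independent, so female-X hypomethylation does not move
#' expression); per-sample values carry lognormal noise. A `frac_silent`
#' subset is fully silent (rank 0), a `de_frac` subset carries a planted sex
#' effect of at least `de_log2fc`, and the Xist-like gene is expressed only
#' in females. DE labels mark planted-effect genes.
#'
#' @param config A [sim_config()].
#' @param truth Truth record (updated copy is returned).
#' @return List: `expression` (long table), `de_table`, `truth`.
#' @export
simulate_expression <- function(config, truth) {
  set.seed(config$seed + 2L)
  genes <- data.table::copy(truth$genes)
  samples <- c(sprintf("F%d", seq_len(config$n_female)),
               sprintf("M%d", seq_len(config$n_male)))
  sex <- c(rep("F", config$n_female), rep("M", config$n_male))
  genes[, mu := config$expr_scale * exp(-config$expr_slope * p_base)]
  ng <- nrow(genes)
  is_xist <- genes$gene_id == truth$xist_gene_id
  pool <- which(!is_xist)
  silent <- rep(FALSE, ng)
  silent[sample(pool, round(config$frac_silent * length(pool)))] <- TRUE
  de_pool <- setdiff(pool, which(silent))
  n_de <- round(config$de_frac * length(pool))
  de_idx <- if (n_de > 0L) sample(de_pool, min(n_de, length(de_pool))) else integer(0)
  effect <- rep(0, ng)
  effect[de_idx] <- sample(c(-1, 1), length(de_idx), replace = TRUE) *
    stats::runif(length(de_idx), config$de_log2fc, config$de_log2fc + 1)
  rows <- list()
  for (j in seq_along(samples)) {
    tpm <- genes$mu * stats::rlnorm(ng, 0, config$noise_sd)
    if (sex[j] == "F") tpm <- tpm * 2^effect
    tpm[silent] <- 0
    tpm[is_xist] <- if (sex[j] == "F") {
      config$xist_female_tpm * stats::rlnorm(1, 0, config$noise_sd / 2)
    } else 0
    rows[[j]] <- data.table::data.table(
      gene_id = genes$gene_id, sample_id = samples[j], tpm = tpm,
      count = stats::rpois(ng, tpm * 10))
  }
  expression <- data.table::rbindlist(rows)
  wide <- expression[, .(mean_f = mean(tpm[sample_id %in% samples[sex == "F"]]),
                         mean_m = mean(tpm[sample_id %in% samples[sex == "M"]])),
                     by = gene_id]
  wide[, log2fc_fm := log2((mean_f + 0.01) / (mean_m + 0.01))]
  de_table <- wide[, .(gene_id, log2fc_fm)]
  de_table[, significant := gene_id %in% c(genes$gene_id[de_idx],
                                           truth$xist_gene_id)]
  truth$expression <- data.table::data.table(
    gene_id = genes$gene_id, mu = genes$mu, silent = silent,
    effect_log2fc = effect)
  truth$de_genes <- c(genes$gene_id[de_idx], truth$xist_gene_id)
  list(expression = expression[], de_table = de_table[], truth = truth)
}

#' Simulate per-read methylation calls at the ASM locus
#'
#' Fixed-length reads with uniform starts over the locus (plus one read
#' length of margin); in females each read comes from one allele, and CpG
#' calls inside the island follow that allele's methylation rate (outside,
#' the female site truth). Only reads covering at least `min_sites` CpGs are
#' kept; drawing repeats until `n_reads` such reads exist.
#'
#' @param config A [sim_config()].
#' @param truth Truth record with `asm_locus` set.
#' @param n_reads Number of qualifying reads to emit (default 200).
#' @param sample_id Label written to read ids (a female sample by default).
#' @param rate_a,rate_b Allele methylation rates (default from the truth).
#' @return `data.table` of calls: `read_id`, `strand`, `chrom`, `pos0`,
#'   `methylated`.
#' @export
simulate_reads_at_locus <- function(config, truth, n_reads = 200L,
                                    sample_id = "F1",
                                    rate_a = NULL, rate_b = NULL) {
  if (is.null(truth$asm_locus)) stop("no ASM locus in truth")
  loc <- truth$asm_locus
  clen <- truth$contig_lengths[loc$chrom]
  if (loc$start0 < 0 || loc$end0 > clen) stop("locus outside contig bounds")
  if (is.null(rate_a)) rate_a <- loc$rate_a
  if (is.null(rate_b)) rate_b <- loc$rate_b
  set.seed(config$seed + 3L)
  rl <- config$read_len
  sites <- truth$sites[chrom == loc$chrom]
  data.table::setorder(sites, pos0)
  min_sites <- 3L
  lo <- max(0L, loc$start0 - rl + 1L)
  hi <- min(clen - rl, loc$end0 - 1L)
  out <- list()
  got <- 0L
  iter <- 0L
  while (got < n_reads && iter < 50L) {
    iter <- iter + 1L
    nb <- 2L * (n_reads - got)
    starts <- lo + sample.int(hi - lo + 1L, nb, replace = TRUE) - 1L
    for (st in starts) {
      if (got >= n_reads) break
      cov <- sites[pos0 >= st & pos0 < st + rl]
      if (nrow(cov) < min_sites) next
      got <- got + 1L
      allele <- sample(c("a", "b"), 1L)
      rate <- if (allele == "a") rate_a else rate_b
      in_isl <- cov$pos0 >= loc$start0 & cov$pos0 < loc$end0
      pm <- ifelse(in_isl, rate, cov$meth_f)
      out[[got]] <- data.table::data.table(
        read_id = sprintf("%s_read%04d_%s", sample_id, got, allele),
        strand = "+", chrom = loc$chrom, pos0 = cov$pos0,
        methylated = stats::runif(nrow(cov)) < pm)
    }
  }
  data.table::rbindlist(out)
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits everything the pipeline consumes: FASTA genome, GTF annotation,
#' per-sample cytosine reports, sample sheet, expression and DE tables,
#' ASM read calls, and a JSON ground-truth summary. Outputs are
#' byte-identical under a fixed seed.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisible list of paths plus the in-memory objects.
#' @export
simulate_bundle <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_genome(config)
  meth <- simulate_methylomes(config, gen$truth)
  expr <- simulate_expression(config, gen$truth)
  truth <- expr$truth
  reads <- simulate_reads_at_locus(config, truth)

  fasta <- file.path(outdir, "genome.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(gen$sequences), fasta)
  gtf <- file.path(outdir, "genes.gtf")
  write_gtf(gen$transcripts, gtf)
  report_paths <- stats::setNames(
    file.path(outdir, paste0(meth$samples$sample_id, ".CpG_report.txt")),
    meth$samples$sample_id)
  for (s in meth$samples$sample_id) {
    write_cytosine_report(meth$records[sample_id == s], report_paths[[s]])
  }
  # paths are stored relative to the sheet so the bundle is relocatable
  sheet <- data.table::copy(meth$samples)[, path := basename(report_paths[sample_id])]
  sheet_path <- file.path(outdir, "sample_sheet.tsv")
  data.table::fwrite(sheet, sheet_path, sep = "\t")
  expr_path <- file.path(outdir, "expression.tsv")
  write_expression_table(expr$expression, expr_path)
  de_path <- file.path(outdir, "de_table.tsv")
  data.table::fwrite(expr$de_table, de_path, sep = "\t")
  reads_path <- file.path(outdir, "asm_read_calls.tsv")
  write_read_calls(reads, reads_path)
  truth_path <- file.path(outdir, "truth.json")
  truth_json <- list(
    contig_class = as.list(truth$contig_class),
    contig_lengths = as.list(truth$contig_lengths),
    asm_locus = truth$asm_locus, par_region = truth$par_region,
    misassembled_region = truth$misassembled_region,
    xist_gene_id = truth$xist_gene_id, de_genes = truth$de_genes,
    femaleX_hypo_base = config$femaleX_hypo_base, seed = config$seed)
  jsonlite::write_json(truth_json, truth_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(
    paths = list(fasta = fasta, gtf = gtf, reports = report_paths,
                 sample_sheet = sheet_path, expression = expr_path,
                 de_table = de_path, read_calls = reads_path,
                 truth = truth_path),
    genome = gen, methylomes = meth, expression = expr, reads = reads,
    truth = truth))
}
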