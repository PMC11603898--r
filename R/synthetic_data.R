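# Synthetic diploid WGBS study generator. Emulates the statistical structure
# the downstream analyses assume: 3+3 female/male samples; autosomal, X and Y
# contigs with per-allele Poisson coverage (female X depth ~2x male X, zero
# female Y coverage); female-X hypomethylation whose magnitude shrinks with
# promoter CpG count; promoter methylation inversely linked to expression; an
# Xist-like gene with female-restricted expression and an allele-specifically
# methylated 5' CpG island; a PAR-like interval and a misassembled Y-in-X
# interval on the X chromosome. A ground-truth record accompanies every
# output for parameter-recovery tests.

#' Default contig specification for the synthetic genome
#'
#' Three assembled chromosomes (two autosomal, one X) that carry genes, and
#' six unplaced contigs (2 A, 2 X, 2 Y) for the sex-linkage classifier.
#'
#' @return `data.frame` with `name`, `class` (A/X/Y), `length`,
#'   `cpg_density` (CpG per bp).
#' @export
default_contig_specs <- function() {
  data.frame(
    name = c("chrA1", "chrA2", "chrX",
             "contigA1", "contigA2", "contigX1", "contigX2",
             "contigY1", "contigY2"),
    class = c("A", "A", "X", "A", "A", "X", "X", "Y", "Y"),
    length = c(60000L, 60000L, 60000L, rep(12000L, 6L)),
    cpg_density = 0.02,
    stringsAsFactors = FALSE
  )
}

#' Build and validate a simulation configuration
#'
#' Defaults are the reference study conditions: 3 female + 3 male samples at
#' ~15x merged autosomal CpG coverage (per-allele depth 7.5), CpG methylation
#' ~0.8, female-X hypomethylation of 0.15 attenuated by promoter CpG count
#' with zero-crossing at 80 CpGs, a monotone-decreasing promoter
#' methylation -> expression link, and an allele-specifically methylated
#' island (allele rates 0.95/0.05) at the Xist-like gene's 5' end.
#'
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @param n_female,n_male Sample counts per sex.
#' @param contig_specs Contig table as in [default_contig_specs()].
#' @param per_allele_depth Mean reads per CpG per allele copy (Poisson).
#' @param autosomal_meth_mean,maleX_meth_mean,y_meth_mean Intergenic
#'   methylation means by contig class.
#' @param femaleX_hypo_base Methylation subtracted on the female X.
#' @param cpg_count_attenuation Per-CpG slope shrinking promoter
#'   hypomethylation (default 1/80).
#' @param expr_scale,expr_slope Expression link
#'   `TPM = expr_scale * exp(-expr_slope * promoter_meth)`.
#' @param noise_sd Lognormal sdlog of per-sample expression noise.
#' @param frac_silent Fraction of genes with zero expression.
#' @param de_frac Fraction of genes given a planted sex effect.
#' @param de_log2fc Minimum |log2 fold-change| of planted sex effects.
#' @param asm_rate_a,asm_rate_b,asm_male_meth Allele methylation rates at the
#'   ASM island in females, and the male rate there.
#' @param xist_female_tpm Female expression of the Xist-like gene (male = 0).
#' @param island_density,island_len CpG island placement parameters.
#' @param par_bp Length of the PAR-like interval at the start of the X.
#' @param misassembly Misassembled Y-in-X interval on the X chromosome as
#'   `c(start0, end0)`, or NULL to disable.
#' @param read_len Read length for ASM read simulation (default 150).
#' @return Validated config list (class `sim_config`).
#' @export
sim_config <- function(seed = 1L, n_female = 3L, n_male = 3L,
                       contig_specs = default_contig_specs(),
                       per_allele_depth = 7.5,
                       autosomal_meth_mean = 0.8, maleX_meth_mean = 0.8,
                       y_meth_mean = 0.3,
                       femaleX_hypo_base = 0.15,
                       cpg_count_attenuation = 1 / 80,
                       expr_scale = 100, expr_slope = 3, noise_sd = 0.8,
                       frac_silent = 0.1, de_frac = 0.03, de_log2fc = 2,
                       asm_rate_a = 0.95, asm_rate_b = 0.05,
                       asm_male_meth = 0.9, xist_female_tpm = 300,
                       island_density = 0.08, island_len = 1200L,
                       par_bp = 5000L, misassembly = c(20000L, 32000L),
                       read_len = 150L) {
  cfg <- as.list(environment())
  cs <- as.data.frame(contig_specs)
  if (!all(c("name", "class", "length", "cpg_density") %in% names(cs))) {
    stop("invalid config: contig_specs needs name, class, length, cpg_density")
  }
  if (!all(cs$class %in% c("A", "X", "Y"))) {
    stop("invalid config: contig classes must be in {A, X, Y}")
  }
  if (any(cs$length < 1000L)) {
    stop("invalid config: contig length < 1000 bp")
  }
  if (any(cs$cpg_density < 0) || any(cs$cpg_density > 0.4)) {
    stop("invalid config: cpg_density out of range")
  }
  fracs <- c(autosomal_meth_mean, maleX_meth_mean, y_meth_mean,
             femaleX_hypo_base, asm_rate_a, asm_rate_b, asm_male_meth,
             frac_silent, de_frac)
  if (any(fracs < 0) || any(fracs > 1)) {
    stop("invalid config: fractions must lie in [0, 1]")
  }
  if (per_allele_depth <= 0) stop("invalid config: per_allele_depth must be > 0")
  cfg$seed <- as.integer(seed)
  cfg$contig_specs <- cs
  class(cfg) <- "sim_config"
  cfg
}

# Lay gene cassettes (2 kb promoter + body) along a contig, skipping reserved
# intervals. Returns a data.table of gene geometries. Promoter CpG density is
# a per-gene multiplier (0.25-1.75x, mean 1) of the contig's background
# density: promoter CpG counts span the range the CpG-content analyses bin
# over while the contig-wide realized density stays at its specification.
.layout_genes <- function(contig, len, reserved, dens) {
  res <- list()
  pos <- 500L
  i <- 0L
  repeat {
    body_len <- sample(3000:8000, 1L)
    cassette <- 2000L + body_len
    if (pos + cassette + 500L > len) break
    hit <- which(reserved$start0 < pos + cassette & reserved$end0 > pos)
    if (length(hit)) {
      pos <- max(reserved$end0[hit]) + 200L
      next
    }
    i <- i + 1L
    strand <- sample(c("+", "-"), 1L)
    if (strand == "+") {
      prom <- c(pos, pos + 2000L)
      body <- c(pos + 2000L, pos + cassette)
    } else {
      body <- c(pos, pos + body_len)
      prom <- c(pos + body_len, pos + cassette)
    }
    res[[i]] <- data.table::data.table(
      gene_id = sprintf("%s_g%03d", contig, i), chrom = contig,
      strand = strand,
      biotype = sample(c("protein_coding", "lncRNA"), 1L, prob = c(0.8, 0.2)),
      body_start0 = body[1], body_end0 = body[2],
      prom_start0 = prom[1], prom_end0 = prom[2],
      prom_density = dens * stats::runif(1L, 0.25, 1.75)
    )
    pos <- pos + cassette + sample(1000:3000, 1L)
  }
  data.table::rbindlist(res)
}

#' Generate the synthetic genome, gene models and ground truth
#'
#' Builds per-contig sequences with Bernoulli CpG placement at the specified
#' density (promoters get gene-specific densities; the Xist-like gene's 5'
#' island gets `island_density` on a GC-rich background), lays out genes on
#' every autosomal/X contig, and records per-site true methylation for each
#' sex, per-allele rates at the ASM island, the PAR-like and misassembled
#' intervals, and contig classes.
#'
#' @param config A [sim_config()].
#' @return List with `sequences` (named character vector), `genes` (gene
#'   model table as from [read_gene_annotation()]), `transcripts`, and
#'   `truth` (list: `contig_class`, `contig_lengths`, `sites`, `genes`,
#'   `asm_locus`, `par_region`, `misassembled_region`, `xist_gene_id`).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cs <- config$contig_specs
  contig_class <- stats::setNames(cs$class, cs$name)
  contig_lengths <- stats::setNames(as.integer(cs$length), cs$name)

  # -- gene layout ----------------------------------------------------------
  x_host <- cs$name[cs$class == "X" & cs$length >= 50000L][1]
  xist <- NULL
  gene_list <- list()
  for (k in seq_len(nrow(cs))) {
    if (cs$class[k] == "Y") next
    reserved <- data.table::data.table(start0 = integer(), end0 = integer())
    if (!is.na(x_host) && cs$name[k] == x_host) {
      # Xist-like cassette and (if set) the misassembled interval are
      # kept free of the regular gene walk
      reserved <- data.table::data.table(start0 = 37500L, end0 = 46500L)
      if (!is.null(config$misassembly)) {
        reserved <- rbind(reserved, data.table::data.table(
          start0 = as.integer(config$misassembly[1]),
          end0 = as.integer(config$misassembly[2])))
      }
    }
    g <- .layout_genes(cs$name[k], cs$length[k], reserved, cs$cpg_density[k])
    gene_list[[cs$name[k]]] <- g
  }
  genes <- data.table::rbindlist(gene_list)
  if (nrow(genes) == 0L) {
    genes <- data.table::data.table(
      gene_id = character(), chrom = character(), strand = character(),
      biotype = character(), body_start0 = integer(), body_end0 = integer(),
      prom_start0 = integer(), prom_end0 = integer(),
      prom_density = numeric())
  }
  if (!is.na(x_host)) {
    island <- c(40000L - config$island_len %/% 2L,
                40000L + config$island_len - config$island_len %/% 2L)
    xist <- data.table::data.table(
      gene_id = "gXIST", chrom = x_host, strand = "+", biotype = "lncRNA",
      body_start0 = 40000L, body_end0 = 46000L,
      prom_start0 = 38000L, prom_end0 = 40000L,
      prom_density = 0.03
    )
    genes <- rbind(genes, xist)
  }
  genes[, `:=`(tss0 = data.table::fifelse(strand == "+", body_start0,
                                          body_end0 - 1L),
               prom_truncated = FALSE)]

  # transcripts: the longest is the gene body; extras are nested, shorter
  tx_list <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i]
    blen <- g$body_end0 - g$body_start0
    n_extra <- sample(0:2, 1L)
    extra <- if (n_extra > 0L) {
      st <- g$body_start0 + sample.int(blen %/% 2L, n_extra, replace = TRUE)
      en <- pmin(st + sample(1000:(max(blen %/% 2L, 1001L)), n_extra,
                             replace = TRUE), g$body_end0 - 1L)
      data.table::data.table(start0 = st, end0 = pmax(en, st + 100L))
    } else NULL
    out <- rbind(data.table::data.table(start0 = g$body_start0,
                                        end0 = g$body_end0), extra)
    out[, `:=`(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
               biotype = g$biotype,
               transcript_id = sprintf("%s.t%d", g$gene_id, seq_len(.N)))]
    out
  })
  transcripts <- data.table::rbindlist(tx_list)
  if (nrow(transcripts) == 0L) {
    transcripts <- data.table::data.table(
      start0 = integer(), end0 = integer(), gene_id = character(),
      chrom = character(), strand = character(), biotype = character(),
      transcript_id = character())
  }

  # -- sequences and CpG placement ------------------------------------------
  sequences <- character(0)
  site_list <- list()
  for (k in seq_len(nrow(cs))) {
    nm <- cs$name[k]; len <- cs$length[k]; dens <- cs$cpg_density[k]
    v <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                prob = c(0.3, 0.2, 0.2, 0.3))
    in_island <- rep(FALSE, len)
    if (!is.null(xist) && nm == x_host) {
      isl <- (island[1] + 1L):island[2]
      v[isl] <- sample(c("A", "C", "G", "T"), length(isl), replace = TRUE,
                       prob = c(0.2, 0.3, 0.3, 0.2))
      in_island[isl] <- TRUE
    }
    # remove accidental CG dinucleotides so density is fully controlled
    cg <- which(v[-len] == "C" & v[-1] == "G")
    if (length(cg)) v[cg + 1L] <- "A"
    # Bernoulli placement on alternate positions; promoter and island
    # densities override the background
    slots <- seq(2L, len - 1L, by = 2L)
    p <- rep(2 * dens, length(slots))
    gsub <- genes[chrom == nm]
    if (nrow(gsub)) {
      for (i in seq_len(nrow(gsub))) {
        inprom <- slots > gsub$prom_start0[i] & slots <= gsub$prom_end0[i]
        p[inprom] <- 2 * gsub$prom_density[i]
      }
    }
    p[in_island[slots]] <- 2 * config$island_density
    keep <- slots[stats::runif(length(slots)) < p]
    v[keep] <- "C"; v[keep + 1L] <- "G"
    sequences[nm] <- paste(v, collapse = "")
    if (length(keep)) {
      site_list[[nm]] <- data.table::data.table(chrom = nm,
                                                pos0 = as.integer(keep - 1L))
    }
  }
  sites <- data.table::rbindlist(site_list)

  # -- per-site truth methylation -------------------------------------------
  genes[, cpg_count := promoter_cpg_count(
    as.list(sequences), genes, mode = "sequence")$cpg_count]
  genes[, p_base := stats::runif(.N, 0.05, 0.95)]
  genes[, body_meth := stats::runif(.N, 0.6, 0.9)]
  genes[gene_id == "gXIST", p_base := config$asm_male_meth]

  sites[, `:=`(region_type = "intergenic", gene_id = NA_character_)]
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    sites[chrom == g$chrom & pos0 >= g$body_start0 & pos0 < g$body_end0 &
            region_type == "intergenic",
          `:=`(region_type = "body", gene_id = g$gene_id)]
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    sites[chrom == g$chrom & pos0 >= g$prom_start0 & pos0 < g$prom_end0,
          `:=`(region_type = "promoter", gene_id = g$gene_id)]
  }
  cls <- contig_class[sites$chrom]
  base <- data.table::fifelse(cls == "Y", config$y_meth_mean,
                              data.table::fifelse(cls == "X",
                                                  config$maleX_meth_mean,
                                                  config$autosomal_meth_mean))
  gi <- match(sites$gene_id, genes$gene_id)
  base <- ifelse(sites$region_type == "promoter", genes$p_base[gi],
                 ifelse(sites$region_type == "body", genes$body_meth[gi],
                        base))
  # female-X hypomethylation, attenuated by promoter CpG count in promoters
  genes[, hypo := config$femaleX_hypo_base *
          (1 - config$cpg_count_attenuation * cpg_count)]
  hypo_site <- ifelse(sites$region_type == "promoter" & !is.na(gi),
                      genes$hypo[gi], config$femaleX_hypo_base)
  hypo <- data.table::fifelse(cls == "X", hypo_site, 0)
  sites[, meth_m := pmin(pmax(base, 0), 1)]
  sites[, meth_f := pmin(pmax(base - hypo, 0), 1)]

  asm_locus <- NULL
  par_region <- NULL
  mis_region <- NULL
  if (!is.na(x_host)) {
    asm_locus <- list(chrom = x_host, start0 = island[1], end0 = island[2],
                      rate_a = config$asm_rate_a, rate_b = config$asm_rate_b)
    sites[, is_asm := chrom == x_host & pos0 >= island[1] & pos0 < island[2]]
    sites[is_asm == TRUE,
          `:=`(meth_m = config$asm_male_meth,
               meth_f = (config$asm_rate_a + config$asm_rate_b) / 2)]
    if (config$par_bp > 0L) {
      par_region <- list(chrom = x_host, start0 = 0L,
                         end0 = as.integer(config$par_bp))
      sites[chrom == x_host & pos0 < config$par_bp, meth_f := meth_m]
    }
    if (!is.null(config$misassembly)) {
      mis_region <- list(chrom = x_host,
                         start0 = as.integer(config$misassembly[1]),
                         end0 = as.integer(config$misassembly[2]))
    }
  } else {
    sites[, is_asm := FALSE]
  }

  truth <- list(contig_class = contig_class, contig_lengths = contig_lengths,
                sites = sites[], genes = genes[], asm_locus = asm_locus,
                par_region = par_region, misassembled_region = mis_region,
                xist_gene_id = if (!is.na(x_host)) "gXIST" else NA_character_)
  ntx <- transcripts[, .(n_transcripts = .N), by = gene_id]
  gm <- merge(genes[, .(gene_id, chrom, strand, biotype, body_start0,
                        body_end0, tss0, prom_start0, prom_end0,
                        prom_truncated)],
              ntx, by = "gene_id")
  list(sequences = sequences, genes = gm, transcripts = transcripts[],
       truth = truth)
}
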