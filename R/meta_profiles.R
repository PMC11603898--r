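# Metagene/TSS methylation profiles, expression-rank binning, and
# rank-methylation correlation.

#' Metagene methylation profile
#'
#' Each gene body is scaled into `body_bins` equal fractions; upstream and
#' downstream flanks of `flank_bp` are split into fixed `flank_bin_bp` bins.
#' Minus-strand genes are reversed so bin 0 is always the most upstream bin.
#' The per-bin value is the weighted methylation (pooled counts over all
#' genes' sites falling in that bin, and over samples if present). Genes with
#' bodies shorter than `body_bins` bp are skipped and counted in the
#' `n_genes_skipped` attribute.
#'
#' @param table Merged CpG site table.
#' @param genes Gene model table.
#' @param flank_bp Flank width (default 2000).
#' @param body_bins Number of gene-body bins (default 60).
#' @param flank_bin_bp Width of each flank bin (default 100).
#' @return `data.table` with `bin`, `zone` (upstream/body/downstream),
#'   `weighted_meth`, `n_sites`, `m`, `u`.
#' @export
metagene_profile <- function(table, genes, flank_bp = 2000L, body_bins = 60L,
                             flank_bin_bp = 100L) {
  flank_bins <- as.integer(flank_bp / flank_bin_bp)
  g <- data.table::as.data.table(genes)
  g <- g[, .(gene_id, chrom, gene_strand = strand,
             body_start0, body_end0, body_len = body_end0 - body_start0)]
  skipped <- g[body_len < body_bins]
  g <- g[body_len >= body_bins]
  sites <- data.table::as.data.table(table)[, .(m = sum(m), u = sum(u)),
                                            by = .(chrom, pos0)]
  # overlap sites with gene intervals extended by the flanks
  g[, `:=`(start0 = body_start0 - flank_bp, end0 = body_end0 + flank_bp)]
  s <- data.table::copy(sites)[, `:=`(start0 = pos0, end0 = pos0 + 1L)]
  data.table::setkey(g, chrom, start0, end0)
  ov <- data.table::foverlaps(s, g, type = "within", nomatch = NULL)
  n_bins <- 2L * flank_bins + body_bins
  out_empty <- data.table::data.table(
    bin = seq_len(n_bins) - 1L,
    zone = rep(c("upstream", "body", "downstream"),
               c(flank_bins, body_bins, flank_bins)))
  if (nrow(ov) == 0L) {
    out <- out_empty[, `:=`(weighted_meth = NA_real_, n_sites = 0L,
                            m = 0L, u = 0L)]
    data.table::setattr(out, "n_genes_skipped", nrow(skipped))
    return(out[])
  }
  # signed distance from the TSS in the direction of transcription
  ov[, s_rel := data.table::fifelse(gene_strand == "+",
                                    pos0 - body_start0,
                                    (body_end0 - 1L) - pos0)]
  ov[, bin := data.table::fifelse(
    s_rel < 0L, (s_rel + flank_bp) %/% flank_bin_bp,
    data.table::fifelse(
      s_rel < body_len,
      flank_bins + pmin(as.integer((s_rel * body_bins) %/% body_len),
                        body_bins - 1L),
      flank_bins + body_bins +
        pmin((s_rel - body_len) %/% flank_bin_bp, flank_bins - 1L)))]
  ov <- ov[bin >= 0L & bin < n_bins]
  prof <- ov[, .(m = sum(m), u = sum(u), n_sites = .N), by = bin]
  out <- prof[out_empty, on = "bin"]
  out[is.na(m), `:=`(m = 0L, u = 0L, n_sites = 0L)]
  out[, weighted_meth := data.table::fifelse(m + u > 0, m / (m + u),
                                             NA_real_)]
  data.table::setcolorder(out, c("bin", "zone", "weighted_meth", "n_sites",
                                 "m", "u"))
  data.table::setorder(out, bin)
  data.table::setattr(out, "n_genes_skipped", nrow(skipped))
  out[]
}

#' Assign genes to expression ranks 0-20
#'
#' Rank 0 holds exactly the zero-expression genes. Non-zero genes are sorted
#' ascending (ties broken by gene id for determinism) and split into `n_bins`
#' contiguous, equal-size (+-1) quantile groups ranked 1 (lowest) to
#' `n_bins` (highest).
#'
#' @param expression Named numeric vector: gene id -> abundance (>= 0).
#' @param n_bins Number of non-zero ranks (default 20).
#' @return `data.table` with `gene_id`, `rank_bin`.
#' @export
assign_expression_ranks <- function(expression, n_bins = 20L) {
  if (is.null(names(expression))) stop("expression must be a named vector")
  if (any(expression < 0, na.rm = TRUE)) stop("negative expression")
  dt <- data.table::data.table(gene_id = names(expression),
                               value = as.numeric(expression))
  zero <- dt[value == 0][, rank_bin := 0L]
  nz <- dt[value > 0]
  if (nrow(nz) == 0L) {
    warning("all genes have zero expression; every rank is 0")
    return(zero[, .(gene_id, rank_bin)])
  }
  data.table::setorder(nz, value, gene_id)
  nz[, rank_bin := as.integer(ceiling(seq_len(.N) * n_bins / .N))]
  out <- rbind(zero[, .(gene_id, rank_bin)], nz[, .(gene_id, rank_bin)])
  data.table::setkey(out, gene_id)
  out[]
}

#' Metagene profiles per expression rank
#'
#' One [metagene_profile()] per populated rank. Empty ranks are omitted and
#' listed in the `empty_ranks` attribute.
#'
#' @param table Merged site table.
#' @param genes Gene model table.
#' @param ranks Output of [assign_expression_ranks()].
#' @param ... Passed to [metagene_profile()].
#' @return `data.table` of stacked profiles with a `rank_bin` column.
#' @export
rank_methylation_profile <- function(table, genes, ranks, ...) {
  g <- data.table::as.data.table(genes)
  r <- data.table::as.data.table(ranks)
  levels_present <- sort(unique(r$rank_bin))
  profs <- list()
  empty <- integer(0)
  for (rk in levels_present) {
    gsub <- g[gene_id %in% r[rank_bin == rk, gene_id]]
    if (nrow(gsub) == 0L) { empty <- c(empty, rk); next }
    p <- metagene_profile(table, gsub, ...)
    p[, rank_bin := rk]
    profs[[as.character(rk)]] <- p
  }
  out <- data.table::rbindlist(profs)
  data.table::setattr(out, "empty_ranks", empty)
  out[]
}

#' Spearman correlation of region methylation with expression, by group
#'
#' @param gene_stats `data.table` with one row per gene: `gene_id`, `meth`
#'   (region methylation), `expr` (abundance or rank), and optional grouping
#'   columns named in `by`.
#' @param by Character vector of grouping columns (default none).
#' @return `data.table` with one row per group: `rho`, `p`, `n`, `method`.
#'   Groups with fewer than 3 complete genes get NA with a note.
#' @export
spearman_meth_expression <- function(gene_stats, by = character(0)) {
  dt <- data.table::as.data.table(gene_stats)
  if (anyDuplicated(dt, by = c("gene_id", by))) stop("duplicated gene rows")
  res <- dt[, {
    st <- spearman_test(meth, expr)
    list(rho = st$value, p = st$p, n = st$n, method = st$method)
  }, by = by]
  res[]
}
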