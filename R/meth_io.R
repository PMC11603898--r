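# Readers and writers for the external formats the pipeline consumes and
# emits. All internal coordinates are 0-based half-open; every reader applies
# its dialect shift on ingest (cytosine reports and GTF are 1-based, BED is
# already 0-based half-open).

#' Read a Bismark-style per-cytosine report
#'
#' Expected columns (tab-separated, no header): chrom, 1-based position of the
#' cytosine, strand (+/-), methylated count, unmethylated count, context
#' (CG/CHG/CHH), trinucleotide context (optional 7th column). Gzipped files
#' are read transparently.
#'
#' @param path File path.
#' @param contexts Character vector of contexts to keep (default CG only).
#' @return A `data.table` with columns `chrom`, `pos0` (0-based position of
#'   the C), `strand`, `context`, `m`, `u`.
#' @export
read_cytosine_report <- function(path, contexts = "CG") {
  if (!file.exists(path)) stop("file not found: ", path)
  empty <- data.table::data.table(chrom = character(), pos0 = integer(),
                                  strand = character(), context = character(),
                                  m = integer(), u = integer())
  if (file.size(path) == 0L) return(empty)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (nrow(dt) == 0L) return(empty)
  if (ncol(dt) < 6L) stop("cytosine report needs >= 6 columns: ", path)
  out <- dt[, 1:6]
  data.table::setnames(out, c("chrom", "pos", "strand", "m", "u", "context"))
  bad_strand <- which(!out$strand %in% c("+", "-"))
  if (length(bad_strand)) {
    stop("unknown strand '", out$strand[bad_strand[1]], "' at line ",
         bad_strand[1], " of ", path)
  }
  bad_count <- which(out$m < 0 | out$u < 0 | is.na(out$m) | is.na(out$u))
  if (length(bad_count)) {
    stop("negative or missing count at line ", bad_count[1], " of ", path)
  }
  bad_pos <- which(is.na(out$pos) | out$pos < 1)
  if (length(bad_pos)) {
    stop("invalid position at line ", bad_pos[1], " of ", path)
  }
  out[, `:=`(pos0 = as.integer(pos) - 1L, m = as.integer(m),
             u = as.integer(u))]
  out <- out[context %in% contexts,
             .(chrom, pos0, strand, context, m, u)]
  data.table::setkey(out, chrom, pos0)
  out[]
}

#' Write a per-cytosine report (inverse of [read_cytosine_report()])
#'
#' @param records `data.table` with `chrom`, `pos0`, `strand`, `context`,
#'   `m`, `u`.
#' @param path Output path (`.gz` suffix compresses).
#' @export
write_cytosine_report <- function(records, path) {
  out <- data.table::data.table(
    chrom = records$chrom, pos = records$pos0 + 1L, strand = records$strand,
    m = records$m, u = records$u, context = records$context,
    tri = paste0(records$context, "N")
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# Strand-aware promoter and TSS for a gene body in 0-based half-open
# coordinates. Promoters are truncated (never extended) at contig edges.
.derive_promoter <- function(chrom, strand, body_start0, body_end0,
                             promoter_bp, seqlens = NULL) {
  n <- length(chrom)
  tss0 <- ifelse(strand == "+", body_start0, body_end0 - 1L)
  ps <- ifelse(strand == "+", body_start0 - promoter_bp, body_end0)
  pe <- ifelse(strand == "+", body_start0, body_end0 + promoter_bp)
  trunc <- rep(FALSE, n)
  low <- ps < 0L
  trunc <- trunc | low
  ps[low] <- 0L
  if (!is.null(seqlens)) {
    lim <- unname(seqlens[chrom])
    high <- !is.na(lim) & pe > lim
    trunc <- trunc | high
    pe[high] <- lim[high]
  }
  list(tss0 = as.integer(tss0), prom_start0 = as.integer(ps),
       prom_end0 = as.integer(pe), prom_truncated = trunc)
}

#' Read gene models from GTF or BED12
#'
#' One model per gene: the gene body is the longest transcript, the promoter
#' is the `promoter_bp` region immediately upstream of the body start on the
#' gene's strand (truncated at contig edges, flagged). Records without strand
#' are excluded and counted in the `n_strandless_excluded` attribute.
#'
#' @param path Annotation file.
#' @param format `"gtf"` (1-based inclusive) or `"bed12"` (0-based half-open;
#'   the `name` column is the gene id, rows sharing a name are transcripts of
#'   one gene).
#' @param promoter_bp Promoter length in bp upstream of the TSS (default 2000).
#' @param seqlens Optional named vector of contig lengths for promoter
#'   truncation at the upper edge.
#' @return `data.table` with columns `gene_id`, `chrom`, `strand`, `biotype`,
#'   `body_start0`, `body_end0`, `tss0`, `prom_start0`, `prom_end0`,
#'   `prom_truncated`, `n_transcripts`.
#' @export
read_gene_annotation <- function(path, format = c("gtf", "bed12"),
                                 promoter_bp = 2000L, seqlens = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    tx <- gr[as.character(gr$type) %in% c("transcript", "mRNA")]
    if (length(tx) == 0L) stop("no transcript records in ", path)
    tdt <- data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(tx)),
      start0 = GenomicRanges::start(tx) - 1L,   # GTF is 1-based inclusive
      end0 = GenomicRanges::end(tx),
      strand = as.character(GenomicRanges::strand(tx)),
      gene_id = as.character(tx$gene_id),
      biotype = if (!is.null(tx$gene_biotype)) as.character(tx$gene_biotype)
                else "other"
    )
  } else {
    bed <- data.table::fread(path, header = FALSE, sep = "\t")
    if (ncol(bed) < 6L) stop("BED12 requires >= 6 columns: ", path)
    tdt <- data.table::data.table(
      chrom = as.character(bed[[1]]), start0 = as.integer(bed[[2]]),
      end0 = as.integer(bed[[3]]), strand = as.character(bed[[6]]),
      gene_id = as.character(bed[[4]]), biotype = "other"
    )
  }
  tdt[is.na(biotype), biotype := "other"]
  strandless <- tdt[!strand %in% c("+", "-")]
  tdt <- tdt[strand %in% c("+", "-")]
  if (nrow(tdt) == 0L) stop("no stranded transcripts in ", path)
  if (!is.null(seqlens)) {
    bad <- tdt[end0 > seqlens[chrom] | start0 < 0L]
    if (nrow(bad)) stop("transcript outside contig bounds: ", bad$gene_id[1])
  }
  tdt[, body_len := end0 - start0]
  genes <- tdt[order(-body_len, start0),
               .(chrom = chrom[1], strand = strand[1], biotype = biotype[1],
                 body_start0 = start0[1], body_end0 = end0[1],
                 n_transcripts = .N),
               by = gene_id]
  pr <- .derive_promoter(genes$chrom, genes$strand, genes$body_start0,
                         genes$body_end0, as.integer(promoter_bp), seqlens)
  genes[, `:=`(tss0 = pr$tss0, prom_start0 = pr$prom_start0,
               prom_end0 = pr$prom_end0, prom_truncated = pr$prom_truncated)]
  data.table::setcolorder(genes, c("gene_id", "chrom", "strand", "biotype",
                                   "body_start0", "body_end0", "tss0",
                                   "prom_start0", "prom_end0",
                                   "prom_truncated", "n_transcripts"))
  data.table::setattr(genes, "n_strandless_excluded", nrow(strandless))
  genes[]
}

#' Write a transcript table as GTF
#'
#' @param transcripts `data.table` with `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start0`, `end0`, `biotype` (0-based half-open).
#' @param path Output path.
#' @export
write_gtf <- function(transcripts, path) {
  attrs <- sprintf(
    'gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
    transcripts$gene_id, transcripts$transcript_id, transcripts$biotype
  )
  out <- data.table::data.table(
    seqname = transcripts$chrom, source = "methylsex",
    feature = "transcript", start = transcripts$start0 + 1L,
    end = transcripts$end0, score = ".", strand = transcripts$strand,
    frame = ".", attribute = attrs
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format expression table
#'
#' Tab-separated with header: `gene_id`, `sample_id`, `tpm`, `count`.
#' Every gene must carry the identical sample set; duplicate
#' (gene, sample) rows are an error.
#'
#' @param path File path.
#' @return Keyed `data.table`.
#' @export
read_expression_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("gene_id", "sample_id", "tpm", "count")
  if (!all(need %in% names(dt))) {
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  }
  dup <- dt[duplicated(dt, by = c("gene_id", "sample_id"))]
  if (nrow(dup)) stop("duplicate expression rows for gene ", dup$gene_id[1])
  samples <- sort(unique(dt$sample_id))
  bad <- dt[, .(ok = identical(sort(sample_id), samples)), by = gene_id][ok == FALSE]
  if (nrow(bad)) {
    stop("gene ", bad$gene_id[1], " is missing sample columns; expected: ",
         paste(samples, collapse = ", "))
  }
  if (any(dt$tpm < 0) || any(dt$count < 0)) stop("negative expression values")
  data.table::setkey(dt, gene_id, sample_id)
  dt[]
}

#' Write a long-format expression table
#' @param expr `data.table` with `gene_id`, `sample_id`, `tpm`, `count`.
#' @param path Output path.
#' @export
write_expression_table <- function(expr, path) {
  data.table::fwrite(expr[, .(gene_id, sample_id, tpm, count)], path, sep = "\t")
  invisible(path)
}

#' Read a differential-expression label table (external caller output)
#'
#' Tab-separated with header: `gene_id`, `log2fc_fm` (log2 female/male),
#' `significant` (logical). Duplicate gene ids are an error.
#'
#' @param path File path.
#' @return `data.table` keyed by `gene_id`.
#' @export
read_de_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("gene_id", "log2fc_fm", "significant")
  if (!all(need %in% names(dt))) {
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(dt$gene_id)) {
    stop("duplicate gene_id in DE table: ",
         dt$gene_id[duplicated(dt$gene_id)][1])
  }
  dt[, significant := as.logical(significant)]
  data.table::setkey(dt, gene_id)
  dt[]
}

#' Read per-read methylation calls (methylation-extractor dialect)
#'
#' Tab-separated, no header: read id, strand flag (+/-), chrom, 1-based
#' position, call (`Z` methylated CpG / `z` unmethylated CpG).
#'
#' @param path File path.
#' @return `data.table` with `read_id`, `strand`, `chrom`, `pos0`,
#'   `methylated` (logical).
#' @export
read_read_calls <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("read_id", "strand", "chrom", "pos", "call"))
  if (nrow(dt) == 0L) {
    return(data.table::data.table(read_id = character(), strand = character(),
                                  chrom = character(), pos0 = integer(),
                                  methylated = logical()))
  }
  bad <- which(!dt$call %in% c("Z", "z"))
  if (length(bad)) stop("unknown call '", dt$call[bad[1]], "' at line ", bad[1])
  out <- dt[, .(read_id, strand, chrom, pos0 = as.integer(pos) - 1L,
                methylated = call == "Z")]
  out[]
}

#' Write per-read methylation calls
#' @param calls `data.table` with `read_id`, `strand`, `chrom`, `pos0`,
#'   `methylated`.
#' @param path Output path.
#' @export
write_read_calls <- function(calls, path) {
  out <- data.table::data.table(
    read_id = calls$read_id, strand = calls$strand, chrom = calls$chrom,
    pos = calls$pos0 + 1L, call = ifelse(calls$methylated, "Z", "z")
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
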