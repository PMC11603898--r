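# CpG content statistics: sliding-window observed/expected ratio with
# promoter/gene-body annotation, promoter CpG counts, and a
# Gardiner-Garden-style CpG island scan.

# Per-base indicator cumsums for one sequence; the workhorse for all window
# statistics. CpG indicator at i means a CG dinucleotide starts at 0-based i.
.seq_cums <- function(seq) {
  s <- toupper(as.character(seq))
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  isC <- v == "C"
  isG <- v == "G"
  isN <- !(v %in% c("A", "C", "G", "T"))
  n <- length(v)
  isCpG <- c(isC[-n] & isG[-1], FALSE)
  list(n = n,
       C = cumsum(isC), G = cumsum(isG),
       CpG = cumsum(isCpG), N = cumsum(isN))
}

.win_count <- function(cs, start0, end0) {
  # counts over [start0, end0) from a cumsum vector (0-based half-open)
  cs0 <- c(0, cs)
  cs0[end0 + 1L] - cs0[start0 + 1L]
}

#' Sliding-window CpG observed/expected ratio
#'
#' O/E per window is `(n_CpG * L) / (n_C * n_G)` with `L` the non-N window
#' length (Gardiner-Garden normalisation). Windows advance by `step`; a
#' trailing partial window is emitted iff it is at least `window/2` long,
#' flagged `partial`. CpG dinucleotides are counted when fully inside the
#' window. Windows with no C or no G have undefined O/E (NA, flagged).
#'
#' @param seq A `DNAString`/character sequence over A,C,G,T,N.
#' @param chrom Name recorded in the output.
#' @param window Window size in bp (default 1000).
#' @param step Step between window starts (default 500); must be <= window.
#' @return `data.table` with `chrom`, `start0`, `end0`, `n_C`, `n_G`,
#'   `n_CpG`, `oe_ratio`, `partial`, `undefined`.
#' @export
sliding_window_oe <- function(seq, chrom = "seq", window = 1000L,
                              step = 500L) {
  window <- as.integer(window); step <- as.integer(step)
  if (window < step) stop("window must be >= step")
  cs <- .seq_cums(seq)
  n <- cs$n
  starts <- seq.int(0L, max(0L, n - 1L), by = step)
  ends <- pmin(starts + window, n)
  keep <- (ends - starts) == window | (ends - starts) >= window / 2
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) return(data.table::data.table(
    chrom = character(), start0 = integer(), end0 = integer(),
    n_C = integer(), n_G = integer(), n_CpG = integer(),
    oe_ratio = numeric(), partial = logical(), undefined = logical()))
  nC <- .win_count(cs$C, starts, ends)
  nG <- .win_count(cs$G, starts, ends)
  # CpG fully inside: its C at positions [start, end-2]
  nCpG <- .win_count(cs$CpG, starts, pmax(starts, ends - 1L))
  L <- (ends - starts) - .win_count(cs$N, starts, ends)
  undef <- nC == 0 | nG == 0
  oe <- ifelse(undef, NA_real_, (nCpG * L) / (nC * nG))
  data.table::data.table(
    chrom = chrom, start0 = starts, end0 = ends,
    n_C = as.integer(nC), n_G = as.integer(nG), n_CpG = as.integer(nCpG),
    oe_ratio = oe, partial = (ends - starts) < window, undefined = undef)
}

#' Annotate O/E windows by their centre position
#'
#' A window is a `promoter` if its centre falls inside any gene's promoter,
#' else `gene_body` if inside any gene body, else `intergenic`. Promoter
#' takes precedence on overlap.
#'
#' @param stats Output of [sliding_window_oe()] (any table with `chrom`,
#'   `start0`, `end0`).
#' @param genes Gene model table from [read_gene_annotation()].
#' @return Input with an `annotation` column added.
#' @export
annotate_window <- function(stats, genes) {
  st <- data.table::copy(data.table::as.data.table(stats))
  g <- data.table::as.data.table(genes)
  st[, centre := start0 + (end0 - start0) %/% 2L]
  in_any <- function(pos, chr, ivs) {
    q <- data.table::data.table(chrom = chr, start0 = pos, end0 = pos + 1L)
    data.table::setkey(ivs, chrom, start0, end0)
    ov <- data.table::foverlaps(q, ivs, type = "within", which = TRUE,
                                nomatch = NA)
    !is.na(ov$yid[match(seq_len(nrow(q)), ov$xid)])
  }
  prom <- g[, .(chrom, start0 = prom_start0, end0 = prom_end0)]
  body <- g[, .(chrom, start0 = body_start0, end0 = body_end0)]
  in_prom <- in_any(st$centre, st$chrom, prom)
  in_body <- in_any(st$centre, st$chrom, body)
  st[, annotation := data.table::fifelse(
    in_prom, "promoter", data.table::fifelse(in_body, "gene_body",
                                             "intergenic"))]
  st[, centre := NULL]
  st[]
}

#' Count CpGs per promoter
#'
#' Sequence mode counts CG dinucleotides whose C lies inside the promoter
#' interval; site-table mode counts merged CpG sites (the (+)-strand C
#' coordinate) inside the interval. With every genomic CpG emitted in the
#' site table the two modes agree.
#'
#' @param x Either a named `DNAStringSet`/character vector of contig
#'   sequences, or a merged CpG site table.
#' @param genes Gene model table.
#' @param mode `"sequence"` or `"sites"`.
#' @return `data.table` with `gene_id`, `cpg_count`, `mode`.
#' @export
promoter_cpg_count <- function(x, genes, mode = c("sequence", "sites")) {
  mode <- match.arg(mode)
  g <- data.table::as.data.table(genes)
  if (mode == "sequence") {
    seqs <- x
    counts <- vapply(seq_len(nrow(g)), function(i) {
      s <- as.character(seqs[[g$chrom[i]]])
      cs <- .seq_cums(s)
      lo <- g$prom_start0[i]
      hi <- min(g$prom_end0[i], cs$n)   # C inside [lo, hi); partner G may lie outside
      if (hi <= lo) return(0L)
      as.integer(.win_count(cs$CpG, lo, hi))
    }, integer(1))
  } else {
    sites <- unique(data.table::as.data.table(x)[, .(chrom, pos0)])
    counts <- vapply(seq_len(nrow(g)), function(i) {
      nrow(sites[chrom == g$chrom[i] & pos0 >= g$prom_start0[i] &
                   pos0 < g$prom_end0[i]])
    }, integer(1))
  }
  data.table::data.table(gene_id = g$gene_id, cpg_count = counts, mode = mode)
}

#' Scan a sequence for CpG islands
#'
#' Gardiner-Garden-style criteria evaluated in 1-bp-shift windows of
#' `scan_window` bp: GC fraction >= `min_gc` and CpG O/E >= `min_oe`. Bases
#' covered by any passing window are merged into maximal intervals; intervals
#' shorter than `min_len` are dropped.
#'
#' @param seq Sequence (`DNAString` or character).
#' @param chrom Name recorded in the output.
#' @param min_len Minimum island length (default 200).
#' @param min_gc Minimum GC fraction (default 0.5).
#' @param min_oe Minimum CpG O/E (default 0.6).
#' @param scan_window Window used for the scan (default 200).
#' @return `data.table` of islands: `chrom`, `start0`, `end0`.
#' @export
cpg_island_scan <- function(seq, chrom = "seq", min_len = 200L,
                            min_gc = 0.5, min_oe = 0.6, scan_window = 200L) {
  cs <- .seq_cums(seq)
  n <- cs$n
  w <- as.integer(scan_window)
  empty <- data.table::data.table(chrom = character(), start0 = integer(),
                                  end0 = integer())
  if (n < w) return(empty)
  starts <- 0L:(n - w)
  ends <- starts + w
  nC <- .win_count(cs$C, starts, ends)
  nG <- .win_count(cs$G, starts, ends)
  nCpG <- .win_count(cs$CpG, starts, ends - 1L)
  gc <- (nC + nG) / w
  oe <- ifelse(nC == 0 | nG == 0, 0, (nCpG * w) / (nC * nG))
  pass <- gc >= min_gc & oe >= min_oe
  if (!any(pass)) return(empty)
  covered <- logical(n)
  for (i in which(pass)) covered[(starts[i] + 1L):ends[i]] <- TRUE
  r <- rle(covered)
  stops <- cumsum(r$lengths)
  begins <- stops - r$lengths + 1L
  isl <- data.table::data.table(start0 = begins[r$values] - 1L,
                                end0 = stops[r$values])
  isl <- isl[end0 - start0 >= min_len]
  if (!nrow(isl)) return(empty)
  data.table::data.table(chrom = chrom, start0 = isl$start0, end0 = isl$end0)
}
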