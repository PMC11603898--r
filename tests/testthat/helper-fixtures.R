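# Shared in-code fixtures for the test suite.

# A tiny deterministic pre-merge cytosine table: paired +/- records plus one
# lone minus-strand record.
tiny_cg_records <- function() {
  data.table::data.table(
    chrom = "chr1",
    pos0 = c(100L, 101L, 200L, 201L, 301L),
    strand = c("+", "-", "+", "-", "-"),
    context = "CG",
    m = c(3L, 1L, 9L, 0L, 2L),
    u = c(2L, 4L, 1L, 1L, 0L)
  )
}

# Random pre-merge records over paired CpG sites for conservation checks.
random_cg_records <- function(n_sites = 500L, seed = 42L) {
  set.seed(seed)
  pos <- sort(sample.int(1e6, n_sites)) * 2L
  plus <- data.table::data.table(chrom = "chr1", pos0 = pos, strand = "+",
                                 context = "CG",
                                 m = rpois(n_sites, 4), u = rpois(n_sites, 4))
  minus <- data.table::data.table(chrom = "chr1", pos0 = pos + 1L,
                                  strand = "-", context = "CG",
                                  m = rpois(n_sites, 4), u = rpois(n_sites, 4))
  rbind(plus, minus)
}

# Wide-X study for gene-level CpG-content analyses: one large X contig so
# tens of X-linked genes span the promoter CpG-count range; no PAR or
# misassembled interval (those are exercised by the default study).
get_xwide_study <- function() {
  if (is.null(study_cache$xwide)) {
    specs <- data.frame(name = c("chrA1", "chrX"), class = c("A", "X"),
                        length = c(60000L, 200000L), cpg_density = 0.02)
    cfg <- sim_config(seed = 151L, contig_specs = specs,
                      misassembly = NULL, par_bp = 0L)
    gen <- generate_genome(cfg)
    meth <- simulate_methylomes(cfg, gen$truth)
    study_cache$xwide <- list(
      cfg = cfg, gen = gen, meth = meth, truth = gen$truth,
      sample_sex = stats::setNames(meth$samples$sex, meth$samples$sample_id),
      merged = merge_symmetric_cpgs(meth$records)
    )
  }
  study_cache$xwide
}

# Small default-condition synthetic study, generated once per test run.
study_cache <- new.env(parent = emptyenv())
get_study <- function() {
  if (is.null(study_cache$study)) {
    cfg <- sim_config(seed = 101L)
    gen <- generate_genome(cfg)
    meth <- simulate_methylomes(cfg, gen$truth)
    expr <- simulate_expression(cfg, gen$truth)
    study_cache$study <- list(
      cfg = cfg, gen = gen, meth = meth, expr = expr,
      truth = expr$truth,
      sample_sex = stats::setNames(meth$samples$sex, meth$samples$sample_id),
      merged = merge_symmetric_cpgs(meth$records)
    )
  }
  study_cache$study
}
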