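# Shared fixtures, built in code. The small planted study is generated once
# per test run and memoized; individual tests treat it as read-only.

gr <- function(chrom, start, end, strand = "*", ...) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
  m <- list(...)
  for (nm in names(m)) S4Vectors::mcols(g)[[nm]] <- m[[nm]]
  g
}

# 0-based half-open convenience constructor (file convention)
gr0 <- function(chrom, start0, end0, ...) gr(chrom, start0 + 1L, end0, ...)

# a handful of stranded genes on a 1 Mb toy chromosome
toy_genes <- function() {
  gr("chr1",
     start = c(200000, 500000, 820000),
     end   = c(210000, 540000, 830000),
     strand = c("+", "-", "+"),
     name = c("gA", "gB", "gC"),
     tss = c(200000, 540000, 820000))
}

toy_chrom_sizes <- c(chr1 = 1e6)

small_config <- function(...) {
  args <- list(
    chrom_sizes = c(chr1 = 4e5, chr2 = 4e5),
    n_subfamilies = 12,
    instances_per_subfamily = c(60, 120),
    n_genes = 80, gene_length = c(1500, 6000),
    enrichment = data.frame(subfamily = c(1L, 2L),
                            cell_type = c("H7", "K562"),
                            fold = c(10, 6)),
    chip_factors = data.frame(tf = "TF1", cell_type = "H7",
                              subfamily = 1L, bind_prob = 0.8),
    motif_plants = data.frame(motif = 1L, subfamily = 1L,
                              plant_fraction = 0.8),
    n_motifs = 2, n_cnee = 300, n_dsqtl = 80,
    datasets = transform(darcall:::default_datasets(), n_peaks = 60L))
  over <- list(...)
  args[names(over)] <- over
  do.call(study_config, args)
}

.fixture_env <- new.env(parent = emptyenv())

small_bundle <- function() {
  if (is.null(.fixture_env$bundle))
    .fixture_env$bundle <- generate_study(small_config(), seed = 404)
  .fixture_env$bundle
}

small_dars <- function() {
  if (is.null(.fixture_env$dars)) {
    b <- small_bundle()
    .fixture_env$dars <- call_dars(b$datasets, b$repeats, b$genes,
                                   b$chrom_sizes,
                                   dar_config(n_random = 30000, seed = 11))
  }
  .fixture_env$dars
}

# random non-degenerate interval set for property tests
random_intervals <- function(n, chrom = "chr1", max_pos = 1e5, seed = 1) {
  withr::with_seed(seed, {
    s <- sample.int(max_pos, n, replace = TRUE)
    w <- sample.int(200, n, replace = TRUE)
    gr(chrom, s, s + w)
  })
}
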