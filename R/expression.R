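# Cell-type-specific expression of DAR-proximal genes: per-gene Z-based
# up-regulation calls, permutation Z-scores over the gene universe, and the
# tag-density 50-kb-window variant.

#' Genes up-regulated in a cell type
#'
#' For every gene and every focal dataset of the cell type, computes
#' `z = (x_focal - mean(x_other)) / sd(x_other)` over the datasets outside
#' the cell type; the gene is called up-regulated when the maximum z across
#' focal datasets exceeds `z_threshold`. Genes with zero spread outside the
#' cell type get no call.
#'
#' @param expr Expression list as from [read_expression_matrix()] (fields
#'   `values`, `cell_types`).
#' @param cell_type Focal cell type (must have >= 1 dataset; >= 2 datasets
#'   must lie outside it).
#' @param z_threshold Default 2.
#' @return Character vector of up-regulated gene names; per-gene max z in
#'   `attr(, "max_z")`.
#' @export
upregulated_genes <- function(expr, cell_type, z_threshold = 2) {
  foc <- which(expr$cell_types == cell_type)
  oth <- which(expr$cell_types != cell_type)
  if (!length(foc)) stop("no datasets for cell type ", cell_type)
  if (length(oth) < 2) stop("need >= 2 datasets outside the cell type")
  x <- expr$values
  m <- rowMeans(x[, oth, drop = FALSE])
  s <- apply(x[, oth, drop = FALSE], 1, stats::sd)
  z <- (x[, foc, drop = FALSE] - m) / s
  max_z <- apply(z, 1, max)
  max_z[s == 0] <- NA_real_
  up <- rownames(x)[!is.na(max_z) & max_z > z_threshold]
  attr(up, "max_z") <- max_z
  up
}

#' Genes associated with open repeat instances
#'
#' Returns the distinct genes whose body overlaps a window of `window_bp`
#' centered on the midpoint of any open instance.
#'
#' @param open_instances Open repeat instances (`GRanges`).
#' @param genes Gene models (`GRanges` with `name`).
#' @param window_bp Window width (default 50000).
#' @return Character vector of distinct gene names.
#' @export
dar_gene_set <- function(open_instances, genes, window_bp = 50000) {
  if (window_bp <= 0) stop("window_bp must be > 0")
  if (!length(open_instances)) return(character(0))
  win <- resize_to_center(open_instances, window_bp)
  ov <- GenomicRanges::findOverlaps(win, genes, ignore.strand = TRUE)
  nm <- genes$name
  if (is.null(nm)) nm <- as.character(seq_along(genes))
  unique(nm[S4Vectors::subjectHits(ov)])
}

#' Permutation Z-score of cell-type-specific expression
#'
#' Draws `n_perm` random gene sets of the associated-gene count from the
#' gene universe (without replacement within a draw), counts members of the
#' up-regulated set, and standardises the observed count against the
#' permutation distribution (population SD).
#'
#' @param observed_up Observed number of associated genes that are
#'   up-regulated.
#' @param n_assoc_genes Number of genes associated with the DAR.
#' @param upregulated_set Character vector of up-regulated gene names.
#' @param gene_universe Character vector of all gene names (e.g. the 35,865
#'   array gene names in a full-scale study).
#' @param n_perm Number of draws (default 10000, >= 100).
#' @param seed Integer seed.
#' @return One-row data.frame: `observed`, `perm_mean`, `perm_sd`, `z`,
#'   `n_perm`, `seed`. Zero permutation SD yields a signed-infinity z with
#'   a warning.
#' @export
expression_permutation_z <- function(observed_up, n_assoc_genes,
                                     upregulated_set, gene_universe,
                                     n_perm = 10000, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  N <- length(gene_universe)
  if (n_assoc_genes > N) stop("n_assoc_genes exceeds the gene universe")
  K <- sum(gene_universe %in% upregulated_set)
  counts <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    sum(sample.int(N, n_assoc_genes) <= K), numeric(1)))
  mu <- mean(counts)
  sdev <- stats::sd(counts) * sqrt((n_perm - 1) / n_perm)  # population SD
  if (sdev == 0) {
    warning("degenerate permutation distribution: z set to +/-Inf")
    z <- sign(observed_up - mu) * Inf
    if (observed_up == mu) z <- 0
  } else z <- (observed_up - mu) / sdev
  data.frame(observed = observed_up, perm_mean = mu, perm_sd = sdev, z = z,
             n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' Window-based expression Z from tag densities
#'
#' Segments the genome into non-overlapping `window_bp` windows, computes
#' each dataset's tag density per window, and calls a window up-regulated in
#' a cell type when `z > z_threshold` for at least one of that cell type's
#' datasets against the others. The open instances' centered windows are
#' then compared with random draws of the same number of background windows.
#'
#' @param open_instances Open repeat instances (`GRanges`).
#' @param tags Named list (dataset_id -> `GRanges` of tag positions).
#' @param cell_types Named character vector: dataset_id -> cell type.
#' @param cell_type Focal cell type.
#' @param chrom_sizes Named chromosome lengths.
#' @param window_bp Window size (default 50000).
#' @param n_perm Permutation draws (default 10000).
#' @param seed Integer seed.
#' @param z_threshold Per-window up-regulation threshold (default 2).
#' @return One-row data.frame as in [expression_permutation_z()].
#' @export
rnaseq_window_z <- function(open_instances, tags, cell_types, cell_type,
                            chrom_sizes, window_bp = 50000, n_perm = 10000,
                            seed = 1L, z_threshold = 2) {
  stopifnot(length(tags) >= 3)
  wins <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    n <- len %/% window_bp
    if (n == 0) return(NULL)
    GenomicRanges::GRanges(ch, IRanges::IRanges(
      start = (seq_len(n) - 1L) * window_bp + 1L, width = window_bp))
  })
  wins <- wins[!vapply(wins, is.null, logical(1))]
  if (!length(wins)) stop("no chromosome can host windows of ", window_bp, " bp")
  wins <- suppressWarnings(do.call(c, wins))
  dens <- vapply(tags, function(tg)
    GenomicRanges::countOverlaps(wins, tg, ignore.strand = TRUE) / window_bp,
    numeric(length(wins)))
  foc <- which(cell_types[colnames(dens)] == cell_type)
  oth <- which(cell_types[colnames(dens)] != cell_type)
  if (!length(foc) || length(oth) < 2)
    stop("need focal datasets and >= 2 others")
  m <- rowMeans(dens[, oth, drop = FALSE])
  s <- apply(dens[, oth, drop = FALSE], 1, stats::sd)
  z <- (dens[, foc, drop = FALSE] - m) / s
  up <- apply(z, 1, function(v) any(v > z_threshold, na.rm = TRUE)) & s > 0
  # windows carrying the open instances: nearest tiling window of each midpoint
  mid <- region_midpoints(open_instances)
  ov <- GenomicRanges::findOverlaps(mid, wins, ignore.strand = TRUE)
  inst_win <- unique(S4Vectors::subjectHits(ov))
  observed <- sum(up[inst_win])
  n_draw <- length(inst_win)
  if (n_draw == 0) stop("no open instance falls inside a tiling window")
  counts <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    sum(up[sample.int(length(wins), n_draw)]), numeric(1)))
  mu <- mean(counts)
  sdev <- stats::sd(counts) * sqrt((n_perm - 1) / n_perm)
  z_out <- if (sdev == 0) {
    warning("degenerate permutation distribution: z set to +/-Inf")
    if (observed == mu) 0 else sign(observed - mu) * Inf
  } else (observed - mu) / sdev
  data.frame(observed = observed, n_windows = n_draw, perm_mean = mu,
             perm_sd = sdev, z = z_out, n_perm = as.integer(n_perm),
             seed = as.integer(seed))
}
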