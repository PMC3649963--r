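# Chromatin-state assignment, conserved-element (CNEE) enrichment, and
# dsQTL enrichment.

#' Assign regions to chromatin states by majority overlap
#'
#' A region is assigned to the state covering strictly more than
#' `min_overlap_fraction` of its length; ties at the threshold (e.g. a
#' 50/50 split at the default 0.5) yield no assignment.
#'
#' @param regions `GRanges`.
#' @param segmentation `GRanges` with a `state` metadata column
#'   (non-overlapping segments).
#' @param min_overlap_fraction Default 0.5.
#' @return Character vector of state labels (NA = unassigned).
#' @export
assign_state <- function(regions, segmentation, min_overlap_fraction = 0.5) {
  st <- segmentation$state
  if (is.null(st)) stop("segmentation needs a 'state' metadata column")
  ov <- GenomicRanges::findOverlaps(regions, segmentation, ignore.strand = TRUE)
  out <- rep(NA_character_, length(regions))
  if (!length(ov)) return(out)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  inter_w <- BiocGenerics::width(IRanges::pintersect(
    IRanges::ranges(regions)[qi], IRanges::ranges(segmentation)[si]))
  cov <- inter_w / BiocGenerics::width(regions)[qi]
  # per (region, state) coverage, then the best state per region
  key <- paste(qi, st[si], sep = "\r")
  agg <- tapply(cov, key, sum)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  q <- as.integer(vapply(parts, `[`, "", 1))
  lab <- vapply(parts, `[`, "", 2)
  o <- order(q, -agg)
  first <- !duplicated(q[o])
  win_q <- q[o][first]; win_lab <- lab[o][first]; win_cov <- agg[o][first]
  ok <- win_cov > min_overlap_fraction
  out[win_q[ok]] <- win_lab[ok]
  out
}

#' Chromatin-state proportions for repeat-split DHS and random regions
#'
#' Computes the proportion of regions assigned to each combined state (plus
#' unassigned) for DHS overlapping repeats, DHS not overlapping repeats,
#' and a random set of matched-length regions drawn uniformly from the
#' genome.
#'
#' @param regions DHS regions (`GRanges`).
#' @param repeat_overlap Logical per region.
#' @param segmentation `GRanges` with `state`.
#' @param grouping Named character vector mapping raw states to combined
#'   states (identity for missing states).
#' @param chrom_sizes Named chromosome lengths.
#' @param n_random Random regions (default 10000).
#' @param seed Integer seed.
#' @param min_overlap_fraction Passed to [assign_state()].
#' @return Matrix: rows = combined states + "unassigned", columns =
#'   `in_repeat`, `out_repeat`, `random`; each column sums to 1.
#' @export
state_proportions <- function(regions, repeat_overlap, segmentation, grouping,
                              chrom_sizes, n_random = 10000, seed = 1L,
                              min_overlap_fraction = 0.5) {
  stopifnot(length(repeat_overlap) == length(regions))
  rnd <- with_seed(seed, {
    w <- sample(BiocGenerics::width(regions), n_random, replace = TRUE)
    ci <- sample.int(length(chrom_sizes), n_random, replace = TRUE,
                     prob = as.numeric(chrom_sizes) / sum(as.numeric(chrom_sizes)))
    len <- as.numeric(chrom_sizes)[ci]
    st <- floor(stats::runif(n_random) * pmax(1, len - w)) + 1
    GenomicRanges::GRanges(names(chrom_sizes)[ci],
                           IRanges::IRanges(start = st, width = w))
  })
  combine <- function(x) {
    y <- unname(grouping[x])
    y[is.na(y) & !is.na(x)] <- x[is.na(y) & !is.na(x)]
    y[is.na(x)] <- "unassigned"
    y
  }
  lv <- unique(c(sort(unique(unname(grouping))), "unassigned"))
  prop <- function(gr) {
    g <- combine(assign_state(gr, segmentation, min_overlap_fraction))
    tab <- table(factor(g, levels = lv))
    as.numeric(tab) / length(gr)
  }
  out <- cbind(in_repeat = prop(regions[repeat_overlap]),
               out_repeat = prop(regions[!repeat_overlap]),
               random = prop(rnd))
  rownames(out) <- lv
  out
}

#' Conservation enrichment of open repeat instances
#'
#' An instance is conserved iff it overlaps at least one conserved
#' non-exonic element (CNEE). Tests whether the open instances are
#' conserved more often than all instances, with a one-sided binomial
#' (p0 = the all-instance conserved fraction).
#'
#' @param all_instances All repeat instances (`GRanges`).
#' @param open_instances Subset contributing open chromatin (`GRanges`).
#' @param cnee CNEE intervals (`GRanges`).
#' @return One-row data.frame: `n_total`, `n_open`, `frac_all`,
#'   `frac_open`, `log10_p`.
#' @export
conservation_enrichment <- function(all_instances, open_instances, cnee) {
  cons_all <- GenomicRanges::countOverlaps(all_instances, cnee,
                                           ignore.strand = TRUE) > 0L
  cons_open <- GenomicRanges::countOverlaps(open_instances, cnee,
                                            ignore.strand = TRUE) > 0L
  p0 <- mean(cons_all)
  k <- sum(cons_open); n <- length(open_instances)
  lp <- if (n > 0) binomial_sf(k, n, p0, log10 = TRUE) else 0
  data.frame(n_total = length(all_instances), n_open = n,
             frac_all = p0, frac_open = if (n > 0) k / n else NA_real_,
             log10_p = lp)
}

#' dsQTL enrichment in DAR-contributed DHS clusters
#'
#' Population = all DHS clusters (N), successes = DAR-contributed clusters
#' (K), draw = clusters overlapped by a dsQTL (n), observed = dsQTL-
#' overlapped DAR clusters (k); one-sided hypergeometric upper tail. Each
#' dsQTL is assigned to at most one cluster (largest overlap, ties to the
#' leftmost). The point probability P(X = k) is reported alongside the
#' tail.
#'
#' @param dsqtls dsQTL intervals (`GRanges`).
#' @param clusters All DHS clusters (`GRanges`).
#' @param dar_flag Logical per cluster: contributed by a DAR instance.
#' @return One-row data.frame: `N`, `K`, `n`, `k`, `log10_p` (upper tail),
#'   `log10_p_point`.
#' @export
dsqtl_enrichment <- function(dsqtls, clusters, dar_flag) {
  stopifnot(length(dar_flag) == length(clusters))
  ov <- GenomicRanges::findOverlaps(dsqtls, clusters, ignore.strand = TRUE)
  assigned <- integer(0)
  if (length(ov)) {
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    w <- BiocGenerics::width(IRanges::pintersect(
      IRanges::ranges(dsqtls)[qi], IRanges::ranges(clusters)[si]))
    o <- order(qi, -w, BiocGenerics::start(clusters)[si])
    first <- !duplicated(qi[o])
    assigned <- si[o][first]
  }
  N <- length(clusters); K <- sum(dar_flag)
  hit_clusters <- unique(assigned)
  n <- length(hit_clusters)
  k <- sum(dar_flag[hit_clusters])
  data.frame(N = N, K = K, n = n, k = k,
             log10_p = hypergeom_sf(k, N, K, n, log10 = TRUE),
             log10_p_point = hypergeom_point(k, N, K, n, log10 = TRUE))
}
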