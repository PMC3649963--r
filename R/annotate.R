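# Six-category gene-proximity annotation and annotation-matched random
# background sampling. Categories (precedence order): TSS (within 1 kb of a
# TSS), promoter (up to 5 kb upstream of a TSS, strand-aware), intragenic
# (inside a gene body), proximal (up to 10 kb from a gene boundary), distal
# (up to 100 kb), desert (beyond 100 kb from any gene). Distances are
# measured from the region midpoint.

annotation_categories <- c("TSS", "promoter", "intragenic", "proximal",
                           "distal", "desert")

# Precompute the category interval sets for a gene model.
annotation_index <- function(genes,
                             tss_bp = 1000, promoter_bp = 5000,
                             proximal_bp = 10000, distal_bp = 100000) {
  if (length(genes) == 0L) stop("genes must be non-empty")
  tss <- S4Vectors::mcols(genes)$tss
  if (is.null(tss)) tss <- gene_tss(genes)
  chrom <- as.character(GenomeInfoDb::seqnames(genes))
  plus <- as.character(BiocGenerics::strand(genes)) == "+"
  mk <- function(chr, s, e) {
    keep <- e >= s
    GenomicRanges::GRanges(chr[keep], IRanges::IRanges(pmax(1L, s[keep]), e[keep]))
  }
  list(
    TSS = mk(chrom, tss - tss_bp, tss + tss_bp),
    promoter = mk(chrom,
                  ifelse(plus, tss - promoter_bp, tss + 1L),
                  ifelse(plus, tss - 1L, tss + promoter_bp)),
    intragenic = GenomicRanges::granges(genes),
    proximal = mk(chrom, BiocGenerics::start(genes) - proximal_bp,
                  BiocGenerics::end(genes) + proximal_bp),
    distal = mk(chrom, BiocGenerics::start(genes) - distal_bp,
                BiocGenerics::end(genes) + distal_bp)
  )
}

# Midpoints of regions as width-1 GRanges (0-based floor midpoint).
region_midpoints <- function(gr) {
  mid0 <- (BiocGenerics::start(gr) - 1L + BiocGenerics::end(gr)) %/% 2L
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                         IRanges::IRanges(mid0 + 1L, width = 1L))
}

annotate_points <- function(points, index) {
  cat <- rep("desert", length(points))
  for (lv in rev(c("TSS", "promoter", "intragenic", "proximal", "distal"))) {
    hit <- GenomicRanges::countOverlaps(points, index[[lv]], ignore.strand = TRUE) > 0L
    cat[hit] <- lv
  }
  factor(cat, levels = annotation_categories)
}

#' Annotate regions by gene proximity
#'
#' Assigns each region to exactly one of six categories based on the
#' distance from its midpoint to the nearest TSS / gene boundary, with
#' precedence TSS > promoter > intragenic > proximal > distal > desert.
#'
#' @param regions `GRanges` of regions (midpoints are used).
#' @param genes Stranded gene models (`GRanges`, e.g. from [read_genes()]).
#' @return Factor of categories, one per region.
#' @export
annotate_region <- function(regions, genes) {
  annotate_points(region_midpoints(regions), annotation_index(genes))
}

#' Category proportions of a region set
#'
#' @inheritParams annotate_region
#' @return Named numeric vector over the six categories, summing to 1.
#' @export
annotation_distribution <- function(regions, genes) {
  if (length(regions) == 0L) stop("regions must be non-empty")
  tab <- table(annotate_region(regions, genes))
  p <- as.numeric(tab) / length(regions)
  names(p) <- names(tab)
  p
}

# Largest-remainder apportionment of n over target fractions.
apportion_counts <- function(n, target) {
  target <- target[annotation_categories]
  target[is.na(target)] <- 0
  names(target) <- annotation_categories
  base <- floor(n * target)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * target - base
    o <- order(-frac, -target)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Sample annotation-matched random background regions
#'
#' Draws `n` fixed-width regions whose six-category annotation distribution
#' matches a target exactly (largest-remainder apportionment of per-category
#' counts; every sampled region re-annotates to its assigned category).
#' Eligible genomic space is found by tiling each chromosome at
#' `region_width / 4` steps, annotating tile centers, then
#' rejection-sampling jittered positions within eligible tiles.
#'
#' @param genes Stranded gene models (`GRanges`).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param target Named fractions over the six categories (e.g. from
#'   [annotation_distribution()]).
#' @param n Number of regions (default 200000).
#' @param region_width Region width in bp (default 200).
#' @param seed Integer seed; identical seeds give identical region lists.
#' @return Sorted `GRanges` of `n` regions with a `category` metadata column
#'   and attributes `seed`, `n`, `target`.
#' @export
sample_matched_random <- function(genes, chrom_sizes, target, n = 200000,
                                  region_width = 200, seed = 1L) {
  if (n <= 0) stop("n must be > 0")
  w <- as.integer(region_width)
  step <- max(1L, w %/% 4L)
  index <- annotation_index(genes)

  # tile centers (0-based) keeping the whole window on-chromosome
  half <- w %/% 2L
  tiles <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    if (len < w) return(NULL)
    centers <- seq.int(half, len - (w - half), by = step)
    data.frame(chrom = ch, center0 = centers, stringsAsFactors = FALSE)
  })
  tiles <- do.call(rbind, tiles)
  if (is.null(tiles) || nrow(tiles) == 0L)
    stop("no chromosome can host regions of width ", w)
  tile_pts <- GenomicRanges::GRanges(tiles$chrom,
                                     IRanges::IRanges(tiles$center0 + 1L, width = 1L))
  tile_cat <- annotate_points(tile_pts, index)
  counts <- apportion_counts(n, target)
  names(counts) <- annotation_categories

  chrom_len <- unname(chrom_sizes[tiles$chrom])
  out <- with_seed(seed, {
    parts <- vector("list", length(annotation_categories))
    for (ci in seq_along(annotation_categories)) {
      cat_name <- annotation_categories[ci]
      need <- counts[ci]
      if (need == 0L) next
      pool <- which(tile_cat == cat_name)
      if (length(pool) == 0L)
        stop("no eligible genomic space for category '", cat_name, "'")
      got_chrom <- character(0); got_c0 <- integer(0)
      guard <- 0L
      while (length(got_c0) < need) {
        guard <- guard + 1L
        if (guard > 1000L)
          stop("rejection sampling failed to fill category '", cat_name, "'")
        b <- max(need - length(got_c0), 32L)
        idx <- pool[sample.int(length(pool), ceiling(b * 1.4), replace = TRUE)]
        jitter <- sample.int(step, length(idx), replace = TRUE) - 1L - step %/% 2L
        c0 <- tiles$center0[idx] + jitter
        ok <- c0 - half >= 0L & c0 - half + w <= chrom_len[idx]
        idx <- idx[ok]; c0 <- c0[ok]
        if (!length(c0)) next
        pts <- GenomicRanges::GRanges(tiles$chrom[idx],
                                      IRanges::IRanges(c0 + 1L, width = 1L))
        keep <- annotate_points(pts, index) == cat_name
        got_chrom <- c(got_chrom, tiles$chrom[idx][keep])
        got_c0 <- c(got_c0, c0[keep])
      }
      got_chrom <- got_chrom[seq_len(need)]
      got_c0 <- got_c0[seq_len(need)]
      g <- granges_0based(got_chrom, got_c0 - half, got_c0 - half + w)
      S4Vectors::mcols(g)$category <- cat_name
      parts[[ci]] <- g
    }
    suppressWarnings(do.call(c, parts[!vapply(parts, is.null, logical(1))]))
  })
  out <- sort_granges(out)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n") <- as.integer(n)
  attr(out, "target") <- target
  out
}
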