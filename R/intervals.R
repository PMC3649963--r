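# Interval algebra on top of GenomicRanges: resizing to fixed-width windows,
# gap-based clustering, repeat-instance overlap bookkeeping, tag GC QC and
# strand-oriented aggregate tag profiles.

#' Resize regions to a fixed width around their midpoint
#'
#' The midpoint is `floor((start0 + end0) / 2)` in 0-based coordinates and
#' the window is `[mid - floor(width/2), mid - floor(width/2) + width)`.
#' Windows running off a chromosome end are shifted back inside
#' `[0, chrom length)`; a chromosome shorter than `width` yields the whole
#' chromosome.
#'
#' @param gr Regions (`GRanges`); metadata columns are preserved.
#' @param width Target width in bp (> 0).
#' @param chrom_sizes Optional named vector of chromosome lengths used for
#'   right-edge clipping; defaults to `seqlengths(gr)` when set.
#' @return `GRanges` of width `width` (or chromosome length when shorter).
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 301))
#' resize_to_center(gr, 200)
#' @export
resize_to_center <- function(gr, width, chrom_sizes = NULL) {
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop("width must be a positive number")
  width <- as.integer(width)
  if (is.null(chrom_sizes)) {
    sl <- GenomeInfoDb::seqlengths(gr)
    if (!all(is.na(sl))) chrom_sizes <- sl
  }
  s0 <- BiocGenerics::start(gr) - 1L
  e0 <- BiocGenerics::end(gr)
  mid <- (s0 + e0) %/% 2L
  new_s0 <- mid - width %/% 2L
  new_e0 <- new_s0 + width
  # clip: shift to stay within [0, chrom length)
  shift_right <- pmax(0L, -new_s0)
  new_s0 <- new_s0 + shift_right
  new_e0 <- new_e0 + shift_right
  if (!is.null(chrom_sizes)) {
    len <- unname(chrom_sizes[as.character(GenomeInfoDb::seqnames(gr))])
    over <- pmax(0L, new_e0 - ifelse(is.na(len), new_e0, len))
    new_s0 <- pmax(0L, new_s0 - over)
    new_e0 <- new_e0 - over
  }
  out <- gr
  IRanges::ranges(out) <- IRanges::IRanges(start = new_s0 + 1L, end = new_e0)
  out
}

#' Cluster regions separated by less than a maximum gap
#'
#' Two regions fall in the same cluster iff they are connected by a chain of
#' pairs whose inter-interval gap is strictly less than `max_gap`
#' (overlapping or adjacent regions have gap 0). Clusters are maximal.
#'
#' @param gr Regions (`GRanges`).
#' @param max_gap Non-negative gap threshold in bp (default 100, i.e. merge
#'   regions "within less than 100 bp").
#' @return A `GRanges` of merged cluster spans with a `revmap` metadata
#'   column (IntegerList of member indices into `gr`).
#' @export
cluster_regions <- function(gr, max_gap = 100) {
  if (max_gap < 0) stop("max_gap must be >= 0")
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap,
                               with.revmap = TRUE, ignore.strand = TRUE)
  red
}

#' Per-subfamily sets of repeat instances overlapped by regions
#'
#' Overlap is any shared base (>= 1 bp); each instance is counted at most
#' once however many regions hit it.
#'
#' @param regions Query regions (`GRanges`), already resized if desired.
#' @param instances Repeat instances (`GRanges` with a `subfamily` column).
#' @return A list with `hit_ids` (named list: subfamily -> integer indices of
#'   overlapped instances), `region_hit` (logical per region: overlaps any
#'   instance) and `instance_hit` (logical per instance).
#' @export
overlapping_instance_sets <- function(regions, instances) {
  ov <- GenomicRanges::findOverlaps(regions, instances, ignore.strand = TRUE)
  inst_idx <- sort(unique(S4Vectors::subjectHits(ov)))
  instance_hit <- logical(length(instances))
  instance_hit[inst_idx] <- TRUE
  region_hit <- logical(length(regions))
  region_hit[unique(S4Vectors::queryHits(ov))] <- TRUE
  sf <- instances$subfamily
  if (is.null(sf)) stop("instances must carry a 'subfamily' metadata column")
  hit_ids <- split(inst_idx, sf[inst_idx])
  list(hit_ids = hit_ids, region_hit = region_hit, instance_hit = instance_hit)
}

#' GC-content quality control for sequencing tags
#'
#' Datasets whose tags show GC bias are excluded; the default window keeps
#' mean GC within \[0.45, 0.55\].
#'
#' @param tags Character vector of tag sequences, or numeric vector of
#'   per-tag GC fractions.
#' @param low,high Acceptance bounds on the mean GC fraction.
#' @return A list with `mean_gc` and `pass`.
#' @export
qc_tag_gc <- function(tags, low = 0.45, high = 0.55) {
  if (length(tags) == 0L) stop("empty tag set")
  if (is.character(tags)) {
    s <- Biostrings::DNAStringSet(tags)
    fr <- Biostrings::letterFrequency(s, letters = c("G", "C"))
    gc <- rowSums(fr) / Biostrings::width(s)
  } else if (is.numeric(tags)) {
    gc <- tags
  } else stop("tags must be sequences or GC fractions")
  m <- mean(gc)
  list(mean_gc = m, pass = (m >= low && m <= high))
}

#' Strand-oriented aggregate tag-density profile over repeat instances
#'
#' Anchors every instance at its (strand-oriented) start, counts tags at each
#' offset and divides by the number of instances. Minus-strand instances are
#' coordinate-reversed so that offset 0 is always the repeat's 5' end.
#'
#' @param tags `GRanges` of width-1 tag positions (or any `GRanges`; the
#'   start is used), or a data.frame with `chrom` and `pos` (1-based).
#' @param instances Stranded `GRanges` of repeat instances.
#' @param flank Flanking bp added on both sides (>= 0).
#' @return Numeric vector of per-offset densities of length
#'   `flank + max(width(instances)) + flank`; element 1 corresponds to
#'   offset `-flank` relative to the oriented instance start.
#' @export
aggregate_profile <- function(tags, instances, flank = 0) {
  if (length(instances) == 0L) stop("no instances supplied")
  if (flank < 0) stop("flank must be >= 0")
  if (is.data.frame(tags)) {
    tags <- GenomicRanges::GRanges(tags$chrom, IRanges::IRanges(tags$pos, width = 1L))
  }
  max_len <- max(BiocGenerics::width(instances))
  out_len <- as.integer(flank + max_len + flank)
  dens <- numeric(out_len)
  if (length(tags) == 0L) return(dens)
  win <- instances
  pad <- as.integer(flank) + max_len
  IRanges::ranges(win) <- IRanges::IRanges(
    start = pmax(1L, BiocGenerics::start(instances) - pad),
    end = BiocGenerics::end(instances) + pad
  )
  # offsets are computed against each instance's own coordinates
  ov <- GenomicRanges::findOverlaps(tags, win, ignore.strand = TRUE)
  if (length(ov)) {
    ti <- S4Vectors::queryHits(ov)
    ii <- S4Vectors::subjectHits(ov)
    pos <- BiocGenerics::start(tags)[ti]
    istart <- BiocGenerics::start(instances)[ii]
    iend <- BiocGenerics::end(instances)[ii]
    minus <- as.character(BiocGenerics::strand(instances))[ii] == "-"
    off <- ifelse(minus, iend - pos, pos - istart)  # 0-based offset from oriented start
    idx <- off + as.integer(flank) + 1L
    keep <- idx >= 1L & idx <= out_len
    tab <- tabulate(idx[keep], nbins = out_len)
    dens <- tab / length(instances)
  }
  dens
}
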