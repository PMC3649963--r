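# Cell-type specificity: per-dataset normalized open-instance counts,
# lab-group medians, fold enrichment and cross-cell-type cluster breadth.

#' Cell-type-specificity scores for repeat subfamilies
#'
#' Normalizes the observed open-instance count of every (subfamily,
#' dataset) pair by the dataset's total peak count, computes the median
#' normalized count separately within each lab group (UW and Duke differ in
#' read length, hence mappability), and reports the specificity fold =
#' value / group median. A pair is flagged cell-type specific when its fold
#' exceeds `fold_cutoff` and the pair is a DAR.
#'
#' @param results A `dar_results` object from [call_dars()].
#' @param fold_cutoff Specificity threshold (default 3).
#' @return data.frame per (subfamily, dataset): `subfamily`, `dataset_id`,
#'   `lab_group`, `normalized_count`, `group_median`, `specificity_fold`,
#'   `is_dar`, `is_specific`. Zero median with a positive value gives
#'   `Inf` fold.
#' @export
specificity_scores <- function(results, fold_cutoff = 3) {
  meta <- attr(results, "datasets")
  if (is.null(meta)) stop("results must come from call_dars()")
  grp_sizes <- table(meta$lab_group)
  if (any(grp_sizes < 3))
    stop("each lab group needs >= 3 datasets for a meaningful median")
  df <- as.data.frame(results)[, c("subfamily", "dataset_id", "observed", "is_dar")]
  df$lab_group <- meta$lab_group[match(df$dataset_id, meta$dataset_id)]
  df$n_peaks <- meta$n_peaks[match(df$dataset_id, meta$dataset_id)]
  df$normalized_count <- df$observed / df$n_peaks
  key <- interaction(df$subfamily, df$lab_group, drop = TRUE)
  med <- tapply(df$normalized_count, key, stats::median)
  df$group_median <- as.numeric(med[as.character(key)])
  df$specificity_fold <- ifelse(df$group_median > 0,
                                df$normalized_count / df$group_median,
                                ifelse(df$normalized_count > 0, Inf, 1))
  df$is_specific <- df$is_dar & df$specificity_fold > fold_cutoff
  df[, c("subfamily", "dataset_id", "lab_group", "normalized_count",
         "group_median", "specificity_fold", "is_dar", "is_specific")]
}

#' Cross-dataset DHS cluster breadth histogram
#'
#' Clusters the union of all datasets' peaks (gap < `max_gap`), counts the
#' distinct cell types contributing peaks to each cluster, and reports per
#' breadth bin the number of clusters and the fraction overlapping a repeat
#' instance.
#'
#' @param datasets List of [dhs_dataset()] objects (>= 2).
#' @param repeats Repeat instances (`GRanges`), or NULL to skip the overlap
#'   split.
#' @param max_gap Clustering gap threshold in bp (default 100).
#' @return data.frame per breadth value: `n_cell_types`, `n_clusters`,
#'   `fraction_repeat_overlap` (NA when `repeats` is NULL).
#' @export
cluster_breadth <- function(datasets, repeats = NULL, max_gap = 100) {
  if (length(datasets) < 2) stop("need >= 2 datasets")
  peaks <- lapply(datasets, function(d) GenomicRanges::granges(d$peaks))
  cell <- rep(vapply(datasets, `[[`, "", "cell_type"),
              vapply(peaks, length, integer(1)))
  all_peaks <- suppressWarnings(do.call(c, unname(peaks)))
  cl <- cluster_regions(all_peaks, max_gap = max_gap)
  member <- S4Vectors::mcols(cl)$revmap
  breadth <- vapply(member, function(ix) length(unique(cell[ix])), integer(1))
  if (!is.null(repeats)) {
    rep_hit <- GenomicRanges::countOverlaps(cl, repeats, ignore.strand = TRUE) > 0L
  } else rep_hit <- rep(NA, length(cl))
  bins <- sort(unique(breadth))
  data.frame(
    n_cell_types = bins,
    n_clusters = as.integer(table(factor(breadth, levels = bins))),
    fraction_repeat_overlap = vapply(bins, function(b) {
      v <- rep_hit[breadth == b]
      if (all(is.na(v))) NA_real_ else mean(v)
    }, numeric(1)),
    row.names = NULL
  )
}
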