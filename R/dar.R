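# DAR calling: observed vs annotation-matched expected repeat-subfamily
# overlap, one-sided binomial tests, fold enrichment and open fractions.

#' DHS dataset container
#'
#' @param dataset_id Unique dataset identifier.
#' @param cell_type Cell-type label.
#' @param tissue_group Tissue-group label (one of eight in the default
#'   study design).
#' @param lab_group Producing-lab group, `"UW"` or `"Duke"` (proxy for
#'   36/20 bp read length).
#' @param peaks Peak set (`GRanges`).
#' @return A list of class `dhs_dataset`.
#' @export
dhs_dataset <- function(dataset_id, cell_type, tissue_group, lab_group, peaks) {
  if (!lab_group %in% c("UW", "Duke")) stop("lab_group must be 'UW' or 'Duke'")
  structure(list(dataset_id = dataset_id, cell_type = cell_type,
                 tissue_group = tissue_group, lab_group = lab_group,
                 peaks = peaks, n_peaks = length(peaks)),
            class = "dhs_dataset")
}

#' DAR-calling configuration
#'
#' @param alpha Significance cutoff on the one-sided binomial p (default
#'   1e-5).
#' @param n_random Annotation-matched background size per dataset (default
#'   200000).
#' @param region_width Width peaks are resized to around their midpoint
#'   (default 200 bp).
#' @param seed Master seed; each dataset's background uses a seed derived
#'   from it and the dataset id.
#' @return A list of class `dar_config`.
#' @export
dar_config <- function(alpha = 1e-5, n_random = 200000, region_width = 200,
                       seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_random <= 0) stop("n_random must be > 0")
  structure(list(alpha = alpha, n_random = as.integer(n_random),
                 region_width = as.integer(region_width),
                 seed = as.integer(seed)),
            class = "dar_config")
}

#' Expected subfamily overlap count scaled from a random background
#'
#' @param random_regions Background regions (`GRanges`).
#' @param instances Repeat instances (`GRanges` with `subfamily`).
#' @param subfamily Subfamily name.
#' @param n_true_peaks Number of true peaks in the dataset.
#' @param n_random Number of background regions drawn.
#' @return Real-valued expected count:
#'   (background overlap events in the subfamily) x n_true_peaks / n_random.
#'   Overlap events are (region, instance) pairs, so the estimate stays
#'   linear in `n_random` and does not saturate when background regions
#'   outnumber true peaks.
#' @export
expected_count <- function(random_regions, instances, subfamily,
                           n_true_peaks, n_random) {
  if (n_random <= 0) stop("n_random must be > 0")
  if (n_true_peaks <= 0) stop("n_true_peaks must be > 0")
  hits <- count_overlap_events(random_regions, instances)[subfamily]
  hits <- ifelse(is.na(hits), 0, hits)
  unname(hits) * n_true_peaks / n_random
}

# Overlap events (region x instance pairs) per subfamily.
count_overlap_events <- function(regions, instances) {
  ov <- GenomicRanges::findOverlaps(regions, instances, ignore.strand = TRUE)
  tab <- table(instances$subfamily[S4Vectors::subjectHits(ov)])
  out <- as.numeric(tab)
  names(out) <- names(tab)
  out
}

#' Fold enrichment observed / expected
#'
#' @param observed Observed count(s), >= 0.
#' @param expected Expected count(s), >= 0. Zero expected gives `Inf` (with
#'   a warning) when observed > 0 and 1 when observed = 0.
#' @return Numeric fold(s).
#' @export
fold_enrichment <- function(observed, expected) {
  if (any(observed < 0) || any(expected < 0)) stop("counts must be >= 0")
  out <- ifelse(expected > 0, observed / expected,
                ifelse(observed > 0, Inf, 1))
  if (any(is.infinite(out)))
    warning("zero expected count with positive observed count: fold set to Inf")
  out
}

#' Call DHS-associated repeat subfamilies (DARs)
#'
#' For every (subfamily, dataset) pair, counts the distinct repeat instances
#' overlapped by the dataset's midpoint-resized peaks, estimates the
#' expected count from an annotation-matched random background of
#' `n_random` regions, and applies a one-sided binomial test with trials =
#' subfamily instance count and success probability = expected fraction.
#' Pairs with p below `alpha` are flagged as DARs. Benjamini-Hochberg
#' q-values are reported per dataset as an additional column (not used for
#' the calls).
#'
#' @param datasets List of [dhs_dataset()] objects.
#' @param repeats Repeat instances (`GRanges` with `subfamily`, `repclass`).
#' @param genes Gene models (`GRanges`), for the annotation matching.
#' @param chrom_sizes Named chromosome lengths.
#' @param config A [dar_config()].
#' @return A data.frame of class `dar_results` with one row per
#'   (dataset, subfamily): `dataset_id`, `subfamily`, `repclass`,
#'   `n_instances`, `observed`, `expected`, `p0`, `log10_p`, `q_value`,
#'   `fold`, `is_dar`. Per-dataset overlapped-instance id sets are kept in
#'   `attr(, "hits")`; dataset metadata in `attr(, "datasets")`.
#' @export
call_dars <- function(datasets, repeats, genes, chrom_sizes,
                      config = dar_config()) {
  if (!length(datasets)) stop("no datasets supplied")
  sf_tab <- table(repeats$subfamily)
  empty <- names(sf_tab)[sf_tab == 0]
  if (length(empty)) {
    warning("skipping subfamilies with 0 instances: ", paste(empty, collapse = ", "))
    sf_tab <- sf_tab[sf_tab > 0]
  }
  subfam <- names(sf_tab)
  n_inst <- as.integer(sf_tab)
  names(n_inst) <- subfam
  repclass <- vapply(split(as.character(repeats$repclass), repeats$subfamily),
                     function(x) x[1], character(1))[subfam]

  rows <- list()
  hits <- list()
  for (ds in datasets) {
    if (!length(ds$peaks)) stop("dataset ", ds$dataset_id, " has no peaks")
    resized <- resize_to_center(ds$peaks, config$region_width, chrom_sizes)
    obs_sets <- overlapping_instance_sets(resized, repeats)
    observed <- integer(length(subfam)); names(observed) <- subfam
    got <- lengths(obs_sets$hit_ids)
    observed[names(got)] <- got
    target <- annotation_distribution(resized, genes)
    bg <- sample_matched_random(genes, chrom_sizes, target,
                                n = config$n_random,
                                region_width = config$region_width,
                                seed = derive_seed(config$seed, ds$dataset_id))
    bg_hits <- numeric(length(subfam)); names(bg_hits) <- subfam
    gotb <- count_overlap_events(bg, repeats)
    bg_hits[names(gotb)] <- gotb
    expected <- bg_hits * length(ds$peaks) / config$n_random
    p0 <- pmin(1, expected / n_inst)
    log10_p <- binomial_sf(observed, n_inst, p0, log10 = TRUE)
    q <- stats::p.adjust(10^log10_p, method = "BH")
    rows[[ds$dataset_id]] <- data.frame(
      dataset_id = ds$dataset_id,
      subfamily = subfam,
      repclass = unname(repclass),
      n_instances = unname(n_inst),
      observed = unname(observed),
      expected = unname(expected),
      p0 = unname(p0),
      log10_p = unname(log10_p),
      q_value = unname(q),
      fold = unname(fold_enrichment(observed, expected)),
      is_dar = unname(log10_p < log10(config$alpha)),
      stringsAsFactors = FALSE, row.names = NULL
    )
    hits[[ds$dataset_id]] <- obs_sets$hit_ids
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "hits") <- hits
  attr(out, "n_instances") <- n_inst
  attr(out, "datasets") <- data.frame(
    dataset_id = vapply(datasets, `[[`, "", "dataset_id"),
    cell_type = vapply(datasets, `[[`, "", "cell_type"),
    tissue_group = vapply(datasets, `[[`, "", "tissue_group"),
    lab_group = vapply(datasets, `[[`, "", "lab_group"),
    n_peaks = vapply(datasets, function(d) length(d$peaks), integer(1)),
    stringsAsFactors = FALSE
  )
  attr(out, "config") <- config
  class(out) <- c("dar_results", "data.frame")
  out
}

#' @export
print.dar_results <- function(x, ...) {
  meta <- attr(x, "datasets")
  cat(sprintf("DAR enrichment results: %d subfamilies x %d datasets\n",
              length(unique(x$subfamily)), nrow(meta)))
  cfg <- attr(x, "config")
  cat(sprintf("  alpha = %g, n_random = %d, region_width = %d bp, seed = %d\n",
              cfg$alpha, cfg$n_random, cfg$region_width, cfg$seed))
  cat(sprintf("  DAR calls: %d of %d (subfamily, dataset) pairs\n",
              sum(x$is_dar), nrow(x)))
  top <- x[order(x$log10_p), ][seq_len(min(5L, nrow(x))), ]
  cat("  strongest enrichments:\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %-12s %-14s obs %5d / exp %8.1f  fold %6.1f  log10 p %8.1f\n",
                top$subfamily[i], top$dataset_id[i], top$observed[i],
                top$expected[i], top$fold[i], top$log10_p[i]))
  invisible(x)
}

#' @export
summary.dar_results <- function(object, ...) {
  agg <- stats::aggregate(is_dar ~ dataset_id, data = object, FUN = sum)
  names(agg)[2] <- "n_dars"
  agg$n_tested <- as.integer(table(object$dataset_id)[agg$dataset_id])
  agg
}

#' Fraction of a subfamily's instances open in at least one dataset
#'
#' Unions the per-dataset overlapped-instance sets stored on a
#' [call_dars()] result and divides by the subfamily instance count.
#'
#' @param results A `dar_results` object.
#' @param subfamilies Optional subset of subfamily names.
#' @return Named numeric vector of open fractions.
#' @export
open_fraction <- function(results, subfamilies = NULL) {
  hits <- attr(results, "hits")
  n_inst <- attr(results, "n_instances")
  if (is.null(hits) || is.null(n_inst))
    stop("results must come from call_dars() (missing hit sets)")
  if (is.null(subfamilies)) subfamilies <- names(n_inst)
  out <- vapply(subfamilies, function(sf) {
    ids <- unique(unlist(lapply(hits, function(h) h[[sf]]), use.names = FALSE))
    length(ids) / n_inst[[sf]]
  }, numeric(1))
  names(out) <- subfamilies
  out
}
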