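# Repeat subfamily age from divergence (Jukes-Cantor), primate-specific
# classification, lineage partition bookkeeping and short-read mappability
# simulation.

#' Jukes-Cantor age of a repeat subfamily
#'
#' Converts the mean per-mil divergence from the subfamily consensus
#' (milliDiv) into a Jukes-Cantor distance
#' `d = -(3/4) ln(1 - 4p/3)` (substitutions/site, `p = milliDiv/1000`) and
#' an age in millions of years `d / rate / 1e6`. Subfamilies younger than
#' `primate_cutoff_myrs` are classified primate-specific.
#'
#' @param mean_milli_div Mean milliDiv (vectorised), in \[0, 1000); `p` must
#'   stay below 0.75 where the JC correction is defined.
#' @param substitution_rate Substitutions/site/year (default 2.2e-9).
#' @param primate_cutoff_myrs Primate-specific age cutoff (default 95 Myr).
#' @return data.frame with `jc_distance`, `age_myrs`, `primate_specific`.
#' @examples
#' jukes_cantor_age(150)   # ~76 Myr, primate-specific
#' @export
jukes_cantor_age <- function(mean_milli_div, substitution_rate = 2.2e-9,
                             primate_cutoff_myrs = 95) {
  if (substitution_rate <= 0) stop("substitution_rate must be > 0")
  p <- mean_milli_div / 1000
  if (any(p < 0 | p >= 0.75))
    stop("milliDiv/1000 must lie in [0, 0.75): Jukes-Cantor undefined beyond")
  d <- -0.75 * log(1 - 4 * p / 3)
  age <- d / substitution_rate / 1e6
  data.frame(jc_distance = d, age_myrs = age,
             primate_specific = age < primate_cutoff_myrs)
}

#' Per-subfamily property profiles
#'
#' Summarises instance count, mean milliDiv, Jukes-Cantor distance and age,
#' primate-specific flag and mean length for each repeat subfamily.
#'
#' @param repeats Repeat instances (`GRanges` with `subfamily`, `milli_div`).
#' @inheritParams jukes_cantor_age
#' @return data.frame, one row per subfamily.
#' @export
subfamily_profiles <- function(repeats, substitution_rate = 2.2e-9,
                               primate_cutoff_myrs = 95) {
  sf <- factor(repeats$subfamily)
  md <- tapply(repeats$milli_div, sf, mean)
  len <- tapply(BiocGenerics::width(repeats), sf, mean)
  age <- jukes_cantor_age(as.numeric(md), substitution_rate, primate_cutoff_myrs)
  data.frame(subfamily = levels(sf),
             n_instances = as.integer(table(sf)),
             mean_milli_div = as.numeric(md),
             mean_length = as.numeric(len),
             age, stringsAsFactors = FALSE, row.names = NULL)
}

#' Partition region clusters by lineage label
#'
#' Given caller-provided per-cluster lineage labels (e.g. pre-mammalian,
#' mammalian, primate, human), tabulates cluster counts per lineage and,
#' within each lineage, the proportion of clusters overlapping each repeat
#' class.
#'
#' @param clusters Region clusters (`GRanges`).
#' @param lineage_labels Character vector, one label per cluster (no NAs).
#' @param repeats Repeat instances (`GRanges` with `repclass`).
#' @return List with `counts` (clusters per lineage) and `class_proportions`
#'   (lineage x repeat-class matrix; rows sum to <= 1, remainder = clusters
#'   overlapping no repeat of any class).
#' @export
lineage_partition <- function(clusters, lineage_labels, repeats) {
  if (length(lineage_labels) != length(clusters) || anyNA(lineage_labels))
    stop("every cluster needs a lineage label")
  lab <- factor(lineage_labels, levels = unique(lineage_labels))
  classes <- sort(unique(as.character(repeats$repclass)))
  prop <- matrix(0, nrow = nlevels(lab), ncol = length(classes),
                 dimnames = list(levels(lab), classes))
  for (cl in classes) {
    sub <- repeats[repeats$repclass == cl]
    hit <- GenomicRanges::countOverlaps(clusters, sub, ignore.strand = TRUE) > 0L
    prop[, cl] <- tapply(hit, lab, mean)
  }
  list(counts = table(lab), class_proportions = prop)
}

#' Mappability ratio of repeat subfamilies from simulated reads
#'
#' Samples `n_reads` fixed-length reads uniformly from the genome (both
#' strands), calls a read uniquely mapped iff its sequence occurs at exactly
#' one genomic position under the mismatch budget (reverse-complement
#' matches count as positions), and reports, per subfamily, the fraction of
#' reads originating inside its instances that map uniquely. A read
#' originates in a subfamily iff its interval lies fully within an instance.
#'
#' @param genome `DNAStringSet` of chromosomes (named).
#' @param repeats Repeat instances (`GRanges` with `subfamily`).
#' @param read_length Read length in bp (>= 10); 36 and 20 mirror typical
#'   UW / Duke read lengths.
#' @param n_reads Number of reads to sample.
#' @param max_mismatches Mismatch budget for a mapping position (default 0).
#' @param seed Integer seed.
#' @return data.frame per subfamily: `subfamily`, `n_sampled`, `n_unique`,
#'   `ratio` (NA when no read originated there), plus the simulation
#'   parameters.
#' @export
mappability_ratio <- function(genome, repeats, read_length = 36, n_reads = 1000,
                              max_mismatches = 0, seed = 1L) {
  if (read_length < 10) stop("read_length must be >= 10")
  if (n_reads <= 0) stop("n_reads must be > 0")
  lens <- Biostrings::width(genome)
  if (read_length > min(lens))
    stop("read_length exceeds the shortest chromosome")
  chroms <- names(genome)
  n_pos <- lens - read_length + 1L
  sim <- with_seed(seed, {
    ci <- sample.int(length(chroms), n_reads, replace = TRUE,
                     prob = n_pos / sum(n_pos))
    st <- as.integer(floor(stats::runif(n_reads) * n_pos[ci])) + 1L
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    list(ci = ci, st = st, strand = strand)
  })
  reads_gr <- GenomicRanges::GRanges(chroms[sim$ci],
                                     IRanges::IRanges(sim$st, width = read_length))
  seqs <- Biostrings::DNAStringSet(rep("", n_reads))
  for (i in seq_along(chroms)) {
    idx <- which(sim$ci == i)
    if (!length(idx)) next
    seqs[idx] <- Biostrings::extractAt(
      genome[[i]], IRanges::IRanges(sim$st[idx], width = read_length))
  }
  minus <- sim$strand == "-"
  seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  n_hits <- genome_match_counts(seqs, genome, max_mismatches)
  unique_map <- n_hits == 1L

  ov <- GenomicRanges::findOverlaps(reads_gr, repeats, type = "within",
                                    ignore.strand = TRUE)
  origin <- rep(NA_character_, n_reads)
  origin[S4Vectors::queryHits(ov)] <- repeats$subfamily[S4Vectors::subjectHits(ov)]

  subfam <- sort(unique(as.character(repeats$subfamily)))
  n_sampled <- vapply(subfam, function(s) sum(origin %in% s), integer(1))
  n_unique <- vapply(subfam, function(s) sum(unique_map[origin %in% s]), integer(1))
  data.frame(subfamily = subfam, n_sampled = n_sampled, n_unique = n_unique,
             ratio = ifelse(n_sampled > 0, n_unique / n_sampled, NA_real_),
             read_length = read_length, max_mismatches = max_mismatches,
             n_reads = n_reads, seed = as.integer(seed),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Number of genomic positions (forward + reverse-complement) matching each
# read under the mismatch budget. Exact matching uses a PDict fast path.
genome_match_counts <- function(reads, genome, max_mismatches) {
  rc <- Biostrings::reverseComplement(genome)
  if (max_mismatches == 0) {
    pd <- Biostrings::PDict(reads)
    fwd <- Biostrings::vcountPDict(pd, genome)
    rev <- Biostrings::vcountPDict(pd, rc)
    rowSums(fwd) + rowSums(rev)
  } else {
    vapply(seq_along(reads), function(i) {
      p <- reads[[i]]
      sum(Biostrings::vcountPattern(p, genome, max.mismatch = max_mismatches)) +
        sum(Biostrings::vcountPattern(p, rc, max.mismatch = max_mismatches))
    }, numeric(1))
  }
}
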