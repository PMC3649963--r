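# Seeded generator of a complete synthetic study: genome, diverged repeat
# subfamilies, genes, per-cell-type DHS/ChIP peaks with planted subfamily
# enrichments, motif plants, expression matrices, chromatin states, CNEEs
# and dsQTLs — plus a truth table for recovery tests.

#' Synthetic study configuration
#'
#' Defaults describe the desk-scale study design: a 2 x 5 Mb genome, 40
#' repeat subfamilies of 100-500 instances, 12 DHS datasets spanning 8
#' tissue groups and the two lab groups, ~500 peaks per dataset (giving a
#' ~2.5% background instance-hit rate), open-chromatin enrichments of fold
#' 10/8/6/5 planted into four subfamilies in specific cell types, two ChIP
#' factors and three motifs co-planted with them, and a 3-SD expression
#' shift for genes near active instances.
#'
#' @param chrom_sizes Named chromosome lengths.
#' @param n_subfamilies Number of repeat subfamilies.
#' @param instances_per_subfamily Range (min, max) of instances.
#' @param instance_length Range (min, max) instance length in bp.
#' @param milli_div_mean_range Range of per-subfamily mean milliDiv.
#' @param milli_div_spread Per-instance SD around the subfamily mean.
#' @param n_genes Number of genes.
#' @param gene_length Range of gene lengths in bp.
#' @param datasets data.frame (dataset_id, cell_type, tissue_group,
#'   lab_group, n_peaks).
#' @param peak_width Range of raw peak widths in bp.
#' @param enrichment data.frame (subfamily index, cell_type, fold) of
#'   planted open-chromatin enrichments; fold 1 everywhere else.
#' @param chip_factors data.frame (tf, cell_type, subfamily index,
#'   bind_prob).
#' @param motif_plants data.frame (motif index, subfamily index,
#'   plant_fraction).
#' @param n_motifs,motif_length Motif complement of the study.
#' @param expression_effect Shift (in noise-SD units) for genes near active
#'   instances.
#' @param expression_window_bp Gene-instance proximity window.
#' @param n_chip_background Background ChIP peaks per factor.
#' @param n_cnee,cnee_open_prob CNEE count and the probability a CNEE is
#'   planted on an active instance.
#' @param n_dsqtl,dsqtl_open_prob dsQTL count and the probability a dsQTL is
#'   planted inside an active lymphoblastoid peak.
#' @param gc GC content of the background genome (default 0.41).
#' @return A list of class `study_config`.
#' @export
study_config <- function(
    chrom_sizes = c(chr1 = 5e6, chr2 = 5e6),
    n_subfamilies = 40,
    instances_per_subfamily = c(100, 500),
    instance_length = c(150, 450),
    milli_div_mean_range = c(30, 250),
    milli_div_spread = 25,
    n_genes = 600,
    gene_length = c(2000, 15000),
    datasets = default_datasets(),
    peak_width = c(150, 300),
    enrichment = data.frame(
      subfamily = c(1L, 2L, 3L, 4L),
      cell_type = c("H7", "K562", "GM12878", "H7"),
      fold = c(10, 8, 6, 5)),
    chip_factors = data.frame(
      tf = c("TF1", "TF2"),
      cell_type = c("H7", "K562"),
      subfamily = c(1L, 2L),
      bind_prob = c(0.8, 0.8)),
    motif_plants = data.frame(
      motif = c(1L, 2L, 3L, 1L),
      subfamily = c(1L, 2L, 3L, 4L),
      plant_fraction = c(0.8, 0.8, 0.8, 0.8)),
    n_motifs = 3,
    motif_length = 10,
    expression_effect = 3,
    expression_window_bp = 50000,
    n_chip_background = 200,
    n_cnee = 1500,
    cnee_open_prob = 0.3,
    n_dsqtl = 300,
    dsqtl_open_prob = 0.5,
    gc = 0.41) {
  cfg <- as.list(environment())
  if (any(cfg$enrichment$fold < 1)) stop("planted folds must be >= 1")
  if (any(cfg$chip_factors$bind_prob < 0 | cfg$chip_factors$bind_prob > 1))
    stop("bind probabilities must lie in [0, 1]")
  structure(cfg, class = "study_config")
}

# 12 datasets over the 8 tissue groups; 7 UW + 5 Duke.
default_datasets <- function() {
  data.frame(
    dataset_id = sprintf("ds%02d", 1:12),
    cell_type = c("H7", "H1", "GM12878", "GM12865", "K562", "HL60",
                  "FibroA", "Myotube", "SAEC", "HepG2", "HUVEC", "FibroB"),
    tissue_group = c("hESC", "hESC", "Lymphoblastoid", "Lymphoblastoid",
                     "Leukemia", "Leukemia", "Fibroblast", "Muscle",
                     "Epithelial", "Solid_tumor", "Others", "Fibroblast"),
    lab_group = c("UW", "UW", "UW", "Duke", "UW", "Duke",
                  "UW", "UW", "UW", "Duke", "Duke", "Duke"),
    n_peaks = rep(500L, 12),
    stringsAsFactors = FALSE
  )
}

# Non-overlapping placement of n segments of given lengths on one linear
# space of size total via random stick-breaking; returns 0-based starts.
place_segments <- function(lengths, total) {
  n <- length(lengths)
  if (n == 0L) return(integer(0))
  slack <- total - sum(lengths)
  if (slack < 0) stop("genome too small: need at least ", sum(lengths), " bp")
  gaps <- stats::runif(n + 1)
  gaps <- floor(gaps / sum(gaps) * slack)
  starts <- cumsum(c(0, lengths[-n])) + cumsum(gaps[-(n + 1)])
  as.integer(starts)
}

CODE2BASE <- c("A", "C", "G", "T")

#' Generate a complete synthetic study
#'
#' Fully reproducible from `seed`; see [study_config()] for the design.
#' Repeat instances are non-overlapping mutated copies of per-subfamily
#' consensus sequences written into a first-order Markov background genome;
#' DHS peaks mix uniform background peaks with peaks planted on instances
#' of enriched subfamilies so that subfamily s in cell type c is hit at
#' (background rate x planted fold); ChIP peaks sit on bound active
#' instances; motif consensus sequences are written into a fraction of the
#' planted subfamilies' instances; expression of genes near active
#' instances is shifted in the matching cell type.
#'
#' @param config A [study_config()].
#' @param seed Master seed (default 1).
#' @return A list of class `study_bundle` with elements `genome`,
#'   `chrom_sizes`, `repeats`, `genes`, `datasets`, `chip`, `pwms`,
#'   `expression`, `segmentations`, `state_grouping`, `cnee`, `dsqtls`,
#'   `active`, `truth`, `config`, `seed`.
#' @export
generate_study <- function(config = study_config(), seed = 1L) {
  with_seed(seed, generate_study_impl(config, seed))
}

generate_study_impl <- function(cfg, seed) {
  cs <- cfg$chrom_sizes
  G <- sum(as.numeric(cs))

  ## background genome: first-order Markov, stationary GC = cfg$gc
  pi0 <- c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
  a <- 0.2  # mild autocorrelation; stationary distribution stays pi0
  trans <- a * diag(4) + (1 - a) * matrix(pi0, 4, 4, byrow = TRUE)
  genome_codes <- lapply(names(cs), function(ch)
    .markov_chain(as.integer(cs[[ch]]), trans, pi0))
  names(genome_codes) <- names(cs)

  ## repeat subfamilies
  nsf <- cfg$n_subfamilies
  sf_names <- sprintf("SF%02d", seq_len(nsf))
  planted_sf <- unique(cfg$enrichment$subfamily)
  n_inst <- sample(cfg$instances_per_subfamily[1]:cfg$instances_per_subfamily[2],
                   nsf, replace = TRUE)
  lo <- min(max(cfg$instances_per_subfamily[1], 250L),
            cfg$instances_per_subfamily[2])
  n_inst[planted_sf] <- sample(lo:cfg$instances_per_subfamily[2],
                               length(planted_sf), replace = TRUE)
  md_mean <- stats::runif(nsf, cfg$milli_div_mean_range[1], cfg$milli_div_mean_range[2])
  classes <- rep(c("LTR/ERV", "LINE", "SINE", "DNA"), length.out = nsf)
  classes[planted_sf] <- "LTR/ERV"
  consensus_len <- cfg$instance_length[2]
  consensus <- lapply(seq_len(nsf), function(i)
    sample.int(4, consensus_len, replace = TRUE, prob = pi0))

  inst_sf <- rep(seq_len(nsf), n_inst)
  n_total <- length(inst_sf)
  inst_len <- sample(cfg$instance_length[1]:cfg$instance_length[2],
                     n_total, replace = TRUE)
  inst_md <- pmin(400L, pmax(0L, as.integer(round(
    stats::rnorm(n_total, md_mean[inst_sf], cfg$milli_div_spread)))))
  ord <- sample.int(n_total)   # interleave subfamilies along the genome
  inst_sf <- inst_sf[ord]; inst_len <- inst_len[ord]; inst_md <- inst_md[ord]

  # allocate instances to chromosomes proportionally, then place
  chrom_of <- sample(names(cs), n_total, replace = TRUE,
                     prob = as.numeric(cs) / G)
  inst_chrom <- character(n_total); inst_start0 <- integer(n_total)
  for (ch in names(cs)) {
    idx <- which(chrom_of == ch)
    st <- place_segments(inst_len[idx], as.integer(cs[[ch]]))
    inst_chrom[idx] <- ch
    inst_start0[idx] <- st
  }

  # mutate consensus copies and write them into the genome
  inst_strand <- sample(c("+", "-"), n_total, replace = TRUE)
  for (i in seq_len(n_total)) {
    codes <- consensus[[inst_sf[i]]][seq_len(inst_len[i])]
    rate <- inst_md[i] / 1000
    nm <- stats::rbinom(1, inst_len[i], rate)
    if (nm > 0) {
      pos <- sample.int(inst_len[i], nm)
      codes[pos] <- ((codes[pos] - 1L + sample.int(3L, nm, replace = TRUE)) %% 4L) + 1L
    }
    genome_codes[[inst_chrom[i]]][(inst_start0[i] + 1L):(inst_start0[i] + inst_len[i])] <- codes
  }

  repeats <- granges_0based(inst_chrom, inst_start0, inst_start0 + inst_len,
                            strand = inst_strand, seqlengths = cs)
  S4Vectors::mcols(repeats)$subfamily <- sf_names[inst_sf]
  S4Vectors::mcols(repeats)$family <- sf_names[inst_sf]
  S4Vectors::mcols(repeats)$repclass <- classes[inst_sf]
  S4Vectors::mcols(repeats)$milli_div <- inst_md

  ## motifs and motif plants
  pwms <- lapply(seq_len(cfg$n_motifs), function(m) {
    mat <- vapply(seq_len(cfg$motif_length), function(j) {
      v <- rep(0.05, 4); v[sample.int(4, 1)] <- 0.85; v
    }, numeric(4))
    pwm(mat, motif_id = sprintf("M%d", m))
  })
  names(pwms) <- vapply(pwms, `[[`, "", "motif_id")
  truth_motifs <- NULL
  for (r in seq_len(nrow(cfg$motif_plants))) {
    m <- cfg$motif_plants$motif[r]
    s <- cfg$motif_plants$subfamily[r]
    frac <- cfg$motif_plants$plant_fraction[r]
    cons <- apply(pwms[[m]]$prob, 2, which.max)
    Lm <- length(cons)
    idx <- which(inst_sf == s & inst_len >= Lm + 2L)
    pick <- idx[stats::runif(length(idx)) < frac]
    for (i in pick) {
      off <- sample.int(inst_len[i] - Lm, 1L)
      ins <- if (stats::runif(1) < 0.5) cons else rev(5L - cons)  # revcomp
      genome_codes[[inst_chrom[i]]][(inst_start0[i] + off + 1L):(inst_start0[i] + off + Lm)] <- ins
    }
    truth_motifs <- rbind(truth_motifs, data.frame(
      effect = "motif", subfamily = sf_names[s],
      partner = names(pwms)[m], cell_type = NA_character_,
      param = frac, n_planted = length(pick), stringsAsFactors = FALSE))
  }

  ## genes
  g_len <- sample(cfg$gene_length[1]:cfg$gene_length[2], cfg$n_genes, replace = TRUE)
  g_chrom_of <- sample(names(cs), cfg$n_genes, replace = TRUE,
                       prob = as.numeric(cs) / G)
  g_chrom <- character(cfg$n_genes); g_start0 <- integer(cfg$n_genes)
  for (ch in names(cs)) {
    idx <- which(g_chrom_of == ch)
    st <- place_segments(g_len[idx], as.integer(cs[[ch]]))
    g_chrom[idx] <- ch; g_start0[idx] <- st
  }
  genes <- granges_0based(g_chrom, g_start0, g_start0 + g_len,
                          strand = sample(c("+", "-"), cfg$n_genes, TRUE),
                          seqlengths = cs)
  S4Vectors::mcols(genes)$name <- sprintf("gene%04d", seq_len(cfg$n_genes))
  S4Vectors::mcols(genes)$tss <- gene_tss(genes)

  ## DHS peaks with planted subfamily enrichment
  ds <- cfg$datasets
  w_resize <- 200L
  datasets <- vector("list", nrow(ds))
  active <- list()   # cell_type -> instance indices with planted peaks
  truth_dars <- NULL
  for (d in seq_len(nrow(ds))) {
    npk <- ds$n_peaks[d]
    ct <- ds$cell_type[d]
    plant_rows <- cfg$enrichment[cfg$enrichment$cell_type == ct &
                                   cfg$enrichment$fold > 1, , drop = FALSE]
    planted_idx <- integer(0)
    if (nrow(plant_rows)) for (r in seq_len(nrow(plant_rows))) {
      s <- plant_rows$subfamily[r]; f <- plant_rows$fold[r]
      idx <- which(inst_sf == s)
      p_base <- 1 - (1 - (inst_len[idx] + w_resize) / G)^npk
      n_plant <- min(length(idx), max(1L, round(f * sum(p_base))),
                     npk %/% 2L - length(planted_idx))
      if (n_plant <= 0L)
        stop("dataset ", ds$dataset_id[d],
             " has too few peaks to host its planted enrichments")
      pick <- sample(idx, n_plant)
      planted_idx <- c(planted_idx, pick)
      truth_dars <- rbind(truth_dars, data.frame(
        effect = "dar", subfamily = sf_names[s], partner = ds$dataset_id[d],
        cell_type = ct, param = f, n_planted = n_plant,
        stringsAsFactors = FALSE))
    }
    n_uni <- npk - length(planted_idx)
    widths <- sample(cfg$peak_width[1]:cfg$peak_width[2], npk, replace = TRUE)
    mids <- numeric(0); chs <- character(0)
    if (length(planted_idx)) {
      jitter <- sample(-30:30, length(planted_idx), replace = TRUE)
      mids <- inst_start0[planted_idx] + inst_len[planted_idx] %/% 2L + jitter
      chs <- inst_chrom[planted_idx]
    }
    ci <- sample(names(cs), n_uni, replace = TRUE, prob = as.numeric(cs) / G)
    mu <- floor(stats::runif(n_uni) * (as.numeric(cs)[match(ci, names(cs))] - 400)) + 200
    mids <- c(mids, mu); chs <- c(chs, ci)
    s0 <- pmax(0, round(mids - widths / 2))
    e0 <- pmin(unname(cs[chs]), s0 + widths)
    pk <- granges_0based(chs, as.integer(s0), as.integer(e0), seqlengths = cs)
    S4Vectors::mcols(pk) <- S4Vectors::DataFrame(
      name = sprintf("%s_pk%05d", ds$dataset_id[d], seq_len(npk)),
      score = 0L, signalValue = round(stats::rlnorm(npk, 1, 0.5), 3),
      pValue = round(stats::runif(npk, 5, 50), 3), qValue = -1,
      peak = as.integer(e0 - s0) %/% 2L)
    pk <- sort_granges(pk)
    datasets[[d]] <- dhs_dataset(ds$dataset_id[d], ct, ds$tissue_group[d],
                                 ds$lab_group[d], pk)
    if (length(planted_idx))
      active[[ct]] <- sort(unique(c(active[[ct]], planted_idx)))
  }
  names(datasets) <- ds$dataset_id
  all_active <- sort(unique(unlist(active)))

  ## ChIP peaks on bound active instances
  chip <- list(); truth_chip <- NULL
  if (nrow(cfg$chip_factors)) for (r in seq_len(nrow(cfg$chip_factors))) {
    tf <- cfg$chip_factors$tf[r]; ct <- cfg$chip_factors$cell_type[r]
    s <- cfg$chip_factors$subfamily[r]; pb <- cfg$chip_factors$bind_prob[r]
    cand <- intersect(active[[ct]], which(inst_sf == s))
    bound <- cand[stats::runif(length(cand)) < pb]
    widths <- sample(150:250, length(bound) + cfg$n_chip_background, replace = TRUE)
    mids <- inst_start0[bound] + inst_len[bound] %/% 2L
    chs <- inst_chrom[bound]
    ci <- sample(names(cs), cfg$n_chip_background, replace = TRUE,
                 prob = as.numeric(cs) / G)
    mu <- floor(stats::runif(cfg$n_chip_background) *
                  (as.numeric(cs)[match(ci, names(cs))] - 400)) + 200
    mids <- c(mids, mu); chs <- c(chs, ci)
    s0 <- pmax(0, round(mids - widths / 2))
    e0 <- pmin(unname(cs[chs]), s0 + widths)
    g <- sort_granges(granges_0based(chs, as.integer(s0), as.integer(e0),
                                     seqlengths = cs))
    chip[[paste(tf, ct, sep = ".")]] <- list(tf = tf, cell_type = ct, peaks = g)
    truth_chip <- rbind(truth_chip, data.frame(
      effect = "chip", subfamily = sf_names[s], partner = tf, cell_type = ct,
      param = pb, n_planted = length(bound), stringsAsFactors = FALSE))
  }

  ## expression matrix: genes near active instances up in the matching cell type
  n_ds <- nrow(ds)
  baseline <- stats::rnorm(cfg$n_genes, 5, 2)
  vals <- matrix(stats::rnorm(cfg$n_genes * n_ds), cfg$n_genes, n_ds) + baseline
  dimnames(vals) <- list(genes$name, ds$dataset_id)
  truth_expr <- NULL
  for (ct in names(active)) {
    inst <- repeats[active[[ct]]]
    gset <- dar_gene_set(inst, genes, cfg$expression_window_bp)
    cols <- which(ds$cell_type == ct)
    vals[gset, cols] <- vals[gset, cols] + cfg$expression_effect
    truth_expr <- rbind(truth_expr, data.frame(
      effect = "expression", subfamily = NA_character_, partner = NA_character_,
      cell_type = ct, param = cfg$expression_effect, n_planted = length(gset),
      stringsAsFactors = FALSE))
  }
  expression <- list(values = vals, dataset_ids = ds$dataset_id,
                     cell_types = ds$cell_type, genes = genes$name)

  ## chromatin-state segmentations (15 states -> 7 combined)
  states <- sprintf("S%02d", 1:15)
  grouping <- c(S01 = "promoter", S02 = "promoter", S03 = "promoter",
                S04 = "enhancer", S05 = "enhancer", S06 = "enhancer",
                S07 = "enhancer", S08 = "insulator", S09 = "transcribed",
                S10 = "transcribed", S11 = "transcribed", S12 = "repressed",
                S13 = "repressed", S14 = "heterochromatin", S15 = "repetitive")
  segmentations <- lapply(unique(ds$cell_type), function(ct) {
    segs <- lapply(names(cs), function(ch) {
      len <- as.integer(cs[[ch]])
      sl <- pmax(500L, as.integer(stats::rexp(ceiling(len / 4000) + 10, 1 / 4000)))
      ends <- cumsum(sl); ends <- ends[ends < len]
      starts0 <- c(0L, ends); ends0 <- c(ends, len)
      g <- granges_0based(ch, starts0, ends0)
      S4Vectors::mcols(g)$state <- sample(states, length(g), replace = TRUE,
                                          prob = c(2, 1, 1, 3, 3, 2, 2, 2,
                                                   4, 3, 2, 4, 3, 6, 4))
      g
    })
    suppressWarnings(do.call(c, segs))
  })
  names(segmentations) <- unique(ds$cell_type)

  ## CNEEs: planted on active instances with probability cnee_open_prob
  n_open_cnee <- if (length(all_active))
    stats::rbinom(1, cfg$n_cnee, cfg$cnee_open_prob) else 0L
  cne_len <- sample(80:250, cfg$n_cnee, replace = TRUE)
  src <- if (n_open_cnee) sample(all_active, n_open_cnee, replace = TRUE) else integer(0)
  c_chs <- inst_chrom[src]
  c_s0 <- inst_start0[src] +
    pmax(0L, as.integer(floor(stats::runif(n_open_cnee) *
                                pmax(1L, inst_len[src] - cne_len[seq_len(n_open_cnee)]))))
  n_uni <- cfg$n_cnee - n_open_cnee
  ci <- sample(names(cs), n_uni, replace = TRUE, prob = as.numeric(cs) / G)
  u_s0 <- as.integer(floor(stats::runif(n_uni) *
                             (as.numeric(cs)[match(ci, names(cs))] - 300)))
  cnee <- sort_granges(granges_0based(c(c_chs, ci), c(c_s0, u_s0),
                                      c(c_s0, u_s0) + cne_len, seqlengths = cs))

  ## dsQTLs: planted inside lymphoblastoid active peaks with prob dsqtl_open_prob
  lymph_ds <- which(ds$tissue_group == "Lymphoblastoid")
  lymph_active <- sort(unique(unlist(active[ds$cell_type[lymph_ds]])))
  dq_len <- sample(50:150, cfg$n_dsqtl, replace = TRUE)
  n_open_dq <- if (length(lymph_active))
    stats::rbinom(1, cfg$n_dsqtl, cfg$dsqtl_open_prob) else 0L
  src <- if (n_open_dq) sample(lymph_active, n_open_dq, replace = TRUE) else integer(0)
  d_chs <- inst_chrom[src]
  d_s0 <- inst_start0[src] +
    pmax(0L, as.integer(floor(stats::runif(n_open_dq) *
                                pmax(1L, inst_len[src] - dq_len[seq_len(max(0L, n_open_dq))]))))
  n_uni <- cfg$n_dsqtl - n_open_dq
  ci <- sample(names(cs), n_uni, replace = TRUE, prob = as.numeric(cs) / G)
  u_s0 <- as.integer(floor(stats::runif(n_uni) *
                             (as.numeric(cs)[match(ci, names(cs))] - 200)))
  dsqtls <- sort_granges(granges_0based(c(d_chs, ci), c(d_s0, u_s0),
                                        c(d_s0, u_s0) + dq_len, seqlengths = cs))

  genome <- Biostrings::DNAStringSet(vapply(genome_codes, function(cd)
    paste(CODE2BASE[cd], collapse = ""), character(1)))
  names(genome) <- names(cs)

  truth <- rbind(truth_dars, truth_chip, truth_motifs, truth_expr)
  if (is.null(truth))
    truth <- data.frame(effect = character(0), subfamily = character(0),
                        partner = character(0), cell_type = character(0),
                        param = numeric(0), n_planted = integer(0),
                        stringsAsFactors = FALSE)
  structure(list(
    genome = genome, chrom_sizes = cs, repeats = repeats, genes = genes,
    datasets = datasets, chip = chip, pwms = pwms, expression = expression,
    segmentations = segmentations, state_grouping = grouping, cnee = cnee,
    dsqtls = dsqtls, active = active, truth = truth, config = cfg,
    seed = as.integer(seed)), class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic study (seed %d): %s genome, %d repeat instances in %d\n",
    "subfamilies, %d genes, %d DHS datasets, %d ChIP factors, %d motifs\n"),
    x$seed,
    paste(sprintf("%s:%.1fMb", names(x$chrom_sizes), x$chrom_sizes / 1e6),
          collapse = " + "),
    length(x$repeats), length(unique(x$repeats$subfamily)),
    length(x$genes), length(x$datasets), length(x$chip), length(x$pwms)))
  cat(sprintf("  planted effects: %d (see $truth)\n", nrow(x$truth)))
  invisible(x)
}

#' Extract repeat instance sequences from the bundle genome
#'
#' @param bundle A `study_bundle`.
#' @param idx Instance indices (default all).
#' @return `DNAStringSet`, plus-strand genomic sequence of each instance.
#' @export
instance_sequences <- function(bundle, idx = seq_along(bundle$repeats)) {
  r <- bundle$repeats[idx]
  out <- Biostrings::DNAStringSet(rep("", length(r)))
  for (ch in names(bundle$genome)) {
    i <- which(as.character(GenomeInfoDb::seqnames(r)) == ch)
    if (!length(i)) next
    out[i] <- Biostrings::extractAt(
      bundle$genome[[ch]],
      IRanges::IRanges(BiocGenerics::start(r)[i], BiocGenerics::end(r)[i]))
  }
  names(out) <- as.character(idx)
  out
}

#' Write a study bundle to a directory of standard-format files
#'
#' genome.fa, repeats.rmsk, genes.bed, peaks/<dataset>.narrowPeak,
#' chip/<tf>.<cell_type>.narrowPeak, motifs.jaspar, expression.tsv,
#' states/<cell_type>.bed (BED4 with state label), cnee.bed, dsqtl.bed,
#' truth.tsv.
#'
#' @param bundle A `study_bundle`.
#' @param dir Output directory (created).
#' @return Invisibly, `dir`.
#' @export
write_study <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(dir, "chip"), showWarnings = FALSE)
  dir.create(file.path(dir, "states"), showWarnings = FALSE)
  Biostrings::writeXStringSet(bundle$genome, file.path(dir, "genome.fa"))
  write_rmsk(bundle$repeats, file.path(dir, "repeats.rmsk"))
  write_bed(bundle$genes, file.path(dir, "genes.bed"), six = TRUE)
  for (d in bundle$datasets)
    write_narrowpeak(d$peaks, file.path(dir, "peaks", paste0(d$dataset_id, ".narrowPeak")))
  for (nm in names(bundle$chip))
    write_narrowpeak(bundle$chip[[nm]]$peaks,
                     file.path(dir, "chip", paste0(nm, ".narrowPeak")))
  con <- file(file.path(dir, "motifs.jaspar"), "w")
  for (p in bundle$pwms) {
    writeLines(paste0(">", p$motif_id), con)
    counts <- round(p$prob * 100)
    for (b in 1:4)
      writeLines(sprintf("%s [ %s ]", DNA[b],
                         paste(counts[b, ], collapse = " ")), con)
  }
  close(con)
  write_expression_matrix(bundle$expression, file.path(dir, "expression.tsv"))
  for (ct in names(bundle$segmentations)) {
    seg <- bundle$segmentations[[ct]]
    df <- data.frame(as.character(GenomeInfoDb::seqnames(seg)),
                     BiocGenerics::start(seg) - 1L, BiocGenerics::end(seg),
                     seg$state)
    utils::write.table(df, file.path(dir, "states", paste0(ct, ".bed")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  write_bed(bundle$cnee, file.path(dir, "cnee.bed"))
  write_bed(bundle$dsqtls, file.path(dir, "dsqtl.bed"))
  utils::write.table(bundle$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(jsonlite::toJSON(list(seed = bundle$seed,
                                   chrom_sizes = as.list(bundle$chrom_sizes)),
                              auto_unbox = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Recovery metrics against the planted truth
#'
#' Compares pipeline outputs with the generator's truth table: planted DAR
#' effects are detected when the (subfamily, dataset) pair is a DAR; null
#' pairs flagged as DARs count as false positives.
#'
#' @param bundle A `study_bundle`.
#' @param results A `dar_results` from [call_dars()] on the bundle.
#' @return List with `sensitivity`, `fpr`, `n_planted`, `n_null`, and the
#'   per-effect detection table `detail`.
#' @export
truth_report <- function(bundle, results) {
  tr <- bundle$truth[bundle$truth$effect == "dar", , drop = FALSE]
  if (nrow(tr) == 0) {
    fp <- mean(results$is_dar)
    return(list(sensitivity = NA_real_, fpr = fp, n_planted = 0L,
                n_null = nrow(results), detail = NULL))
  }
  key <- paste(results$subfamily, results$dataset_id)
  planted_key <- paste(tr$subfamily, tr$partner)
  if (!all(planted_key %in% key)) stop("truth table names unknown (subfamily, dataset) pairs")
  detected <- results$is_dar[match(planted_key, key)]
  null_mask <- !(key %in% planted_key)
  list(sensitivity = mean(detected),
       fpr = mean(results$is_dar[null_mask]),
       n_planted = nrow(tr), n_null = sum(null_mask),
       detail = cbind(tr, detected = detected))
}
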