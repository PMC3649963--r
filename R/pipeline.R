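# Orchestration: run the whole analysis over a study bundle, writing
# per-stage TSV/BED artifacts and a machine-readable run manifest.

#' Run the full analysis pipeline over a study bundle
#'
#' Executes the stages in dependency order — DAR calling, subfamily age
#' profiles, specificity, TF association, motif classification, expression
#' association, and the auxiliary enrichments (chromatin states,
#' conservation, dsQTLs) — and writes one TSV per stage plus a JSON
#' manifest recording parameters and seeds. Identical inputs and
#' configuration give byte-identical outputs.
#'
#' @param bundle A `study_bundle` (from [generate_study()]).
#' @param outdir Output directory (created).
#' @param config A [dar_config()]; its seed governs every stage.
#' @param stages Character subset of
#'   `c("dar", "age", "specificity", "tf", "motif", "expression", "aux")`.
#' @param n_perm Permutation draws for the expression stage.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(bundle, outdir, config = dar_config(),
                         stages = c("dar", "age", "specificity", "tf",
                                    "motif", "expression", "aux"),
                         n_perm = 10000) {
  stages <- match.arg(stages, several.ok = TRUE)
  need <- setdiff(intersect(stages, c("specificity", "tf", "expression", "aux")), "dar")
  if (length(need) && !("dar" %in% stages))
    stop("stages ", paste(need, collapse = ", "), " require the 'dar' stage")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  tsv <- function(df, name) utils::write.table(
    df, file.path(outdir, name), sep = "\t", quote = FALSE, row.names = FALSE)

  if ("dar" %in% stages) {
    res$dars <- call_dars(bundle$datasets, bundle$repeats, bundle$genes,
                          bundle$chrom_sizes, config)
    tsv(as.data.frame(res$dars), "dars.tsv")
    of <- open_fraction(res$dars)
    tsv(data.frame(subfamily = names(of), open_fraction = as.numeric(of)),
        "open_fraction.tsv")
  }
  if ("age" %in% stages) {
    res$profiles <- subfamily_profiles(bundle$repeats)
    tsv(res$profiles, "subfamily_profiles.tsv")
  }
  if ("specificity" %in% stages) {
    res$specificity <- specificity_scores(res$dars)
    tsv(res$specificity, "specificity.tsv")
  }
  if ("tf" %in% stages) {
    hits <- attr(res$dars, "hits")
    rows <- lapply(names(bundle$chip), function(nm) {
      fac <- bundle$chip[[nm]]
      ds_ids <- names(bundle$datasets)[vapply(bundle$datasets, function(d)
        d$cell_type == fac$cell_type, logical(1))]
      chip_hit <- overlapping_instance_sets(
        resize_to_center(fac$peaks, config$region_width, bundle$chrom_sizes),
        bundle$repeats)$instance_hit
      do.call(rbind, lapply(unique(bundle$repeats$subfamily), function(sf) {
        universe <- which(bundle$repeats$subfamily == sf)
        dhs <- universe %in% unlist(lapply(ds_ids, function(i) hits[[i]][[sf]]))
        joint_association_test(dhs, chip_hit[universe], subfamily = sf,
                               partner = paste(fac$tf, fac$cell_type, sep = "."))
      }))
    })
    res$tf <- do.call(rbind, rows)
    tsv(res$tf, "tf_association.tsv")
  }
  if ("motif" %in% stages) {
    res$motif <- motif_classifier(bundle, n_sim = 5,
                                  seed = derive_seed(config$seed, "motif"))
    tsv(res$motif, "motif_rank.tsv")
  }
  if ("expression" %in% stages) {
    res$expression <- expression_stage(bundle, res$dars, n_perm = n_perm,
                                       seed = derive_seed(config$seed, "expression"))
    tsv(res$expression, "expression_z.tsv")
  }
  if ("aux" %in% stages) {
    hits <- attr(res$dars, "hits")
    open_idx <- sort(unique(unlist(hits)))
    cons <- conservation_enrichment(bundle$repeats, bundle$repeats[open_idx],
                                    bundle$cnee)
    tsv(cons, "conservation.tsv")
    # lymphoblastoid clusters and dsQTL enrichment
    lymph <- Filter(function(d) d$tissue_group == "Lymphoblastoid",
                    bundle$datasets)
    if (length(lymph) >= 1) {
      pk <- suppressWarnings(do.call(c, unname(lapply(lymph, function(d)
        GenomicRanges::granges(d$peaks)))))
      cl <- cluster_regions(pk, max_gap = 100)
      dar_sf <- unique(res$dars$subfamily[res$dars$is_dar])
      dar_inst <- bundle$repeats[bundle$repeats$subfamily %in% dar_sf]
      dar_flag <- GenomicRanges::countOverlaps(cl, dar_inst,
                                               ignore.strand = TRUE) > 0L
      res$dsqtl <- dsqtl_enrichment(bundle$dsqtls, cl, dar_flag)
      tsv(res$dsqtl, "dsqtl.tsv")
    }
    res$conservation <- cons
  }
  manifest <- list(
    package = "darcall",
    version = as.character(utils::packageVersion("darcall")),
    stages = stages,
    config = unclass(config),
    bundle_seed = bundle$seed,
    n_datasets = length(bundle$datasets),
    n_repeats = length(bundle$repeats),
    n_genes = length(bundle$genes)
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(outdir, "manifest.json"))
  invisible(res)
}

#' Five-feature motif classifier over all (motif, subfamily) pairs
#'
#' Scans the bundle genome once per motif for the genome-wide hit rate,
#' computes the classifier features for every (motif, subfamily) pair, and
#' combines them with a weighted rank average.
#'
#' @param bundle A `study_bundle`.
#' @param weights Feature weights (default equal).
#' @param n_sim Markov resamples for f5.
#' @param seed Integer seed.
#' @param p_threshold Hit threshold (default 1e-5).
#' @return data.frame with features, `rank_score` and `top_decile` per
#'   (motif, subfamily) pair.
#' @export
motif_classifier <- function(bundle, weights = c(f1 = 1, f2 = 1, f3 = 1,
                                                 f4 = 1, f5 = 1),
                             n_sim = 5, seed = 1L, p_threshold = 1e-5) {
  subfam <- sort(unique(bundle$repeats$subfamily))
  seqs <- instance_sequences(bundle)
  sf_of <- bundle$repeats$subfamily
  genome_chars <- as.character(bundle$genome)
  rows <- list()
  for (p in bundle$pwms) {
    ghits <- pwm_scan(genome_chars, p, p_threshold)
    gpos <- sum(pmax(0, nchar(genome_chars) - p$length + 1)) * 2
    for (sf in subfam) {
      idx <- which(sf_of == sf)
      feat <- classifier_features(seqs[idx], p, genome_n_hits = nrow(ghits),
                                  genome_n_positions = gpos, n_sim = n_sim,
                                  seed = derive_seed(seed, paste(p$motif_id, sf)),
                                  p_threshold = p_threshold)
      feat$subfamily <- sf
      rows[[paste(p$motif_id, sf)]] <- feat
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  weighted_rank_average(tab, weights = weights)
}

#' Expression association stage over planted cell types
#'
#' For every (subfamily, cell type) with at least one DAR call, collects
#' genes near the subfamily's open instances, counts how many are
#' up-regulated in the cell type, and standardises the count against
#' random gene draws.
#'
#' @param bundle A `study_bundle`.
#' @param results A `dar_results`.
#' @param n_perm Permutation draws.
#' @param seed Integer seed.
#' @param window_bp Gene-instance window (default 50000).
#' @return data.frame, one row per tested (subfamily, cell_type).
#' @export
expression_stage <- function(bundle, results, n_perm = 10000, seed = 1L,
                             window_bp = 50000) {
  meta <- attr(results, "datasets")
  hits <- attr(results, "hits")
  dars <- results[results$is_dar, c("subfamily", "dataset_id")]
  if (!nrow(dars)) return(NULL)
  dars$cell_type <- meta$cell_type[match(dars$dataset_id, meta$dataset_id)]
  pairs <- unique(dars[, c("subfamily", "cell_type")])
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    sf <- pairs$subfamily[i]; ct <- pairs$cell_type[i]
    ds_ids <- meta$dataset_id[meta$cell_type == ct]
    open_idx <- sort(unique(unlist(lapply(ds_ids, function(d) hits[[d]][[sf]]))))
    if (!length(open_idx)) return(NULL)
    up <- upregulated_genes(bundle$expression, ct)
    gset <- dar_gene_set(bundle$repeats[open_idx], bundle$genes, window_bp)
    z <- expression_permutation_z(sum(gset %in% up), length(gset), up,
                                  bundle$expression$genes, n_perm = n_perm,
                                  seed = derive_seed(seed, paste(sf, ct)))
    cbind(data.frame(subfamily = sf, cell_type = ct,
                     n_open_instances = length(open_idx),
                     n_genes = length(gset), stringsAsFactors = FALSE), z)
  })
  do.call(rbind, rows)
}
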