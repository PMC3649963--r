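# Brute-force binomial tail by direct enumeration (independent of pbinom).
enum_binom_sf <- function(k, n, p0) {
  if (k == 0) return(1)
  kk <- k:n
  sum(choose(n, kk) * p0^kk * (1 - p0)^(n - kk))
}

test_that("binomial_sf matches exact tail enumeration for all n <= 25", {
  for (n in c(1, 3, 10, 25)) {
    for (p0 in c(0, 0.1, 0.5, 0.9, 1)) {
      for (k in 0:n) {
        expect_equal(binomial_sf(k, n, p0), enum_binom_sf(k, n, p0),
                     tolerance = 1e-12,
                     label = sprintf("k=%d n=%d p0=%g", k, n, p0))
      }
    }
  }
  # worked small case: P(X >= 7 | n = 10, p = 1/2) = 176/1024
  expect_equal(binomial_sf(7, 10, 0.5), 176 / 1024)
  expect_equal(binomial_sf(0, 10, 0.3), 1)
})

test_that("binomial_sf is monotone in k and exact in log space far below underflow", {
  p <- binomial_sf(0:50, 50, 0.2, log10 = TRUE)
  expect_true(all(diff(p) <= 1e-12))
  lp <- binomial_sf(2000, 2337, 60.5 / 2337, log10 = TRUE)
  expect_true(is.finite(lp) && lp < -300)
  expect_error(binomial_sf(5, 3, 0.5), "k must")
  expect_error(binomial_sf(1, 3, 1.5), "p0")
})

test_that("expected counts scale background overlap events to the peak count", {
  inst <- gr0("chr1", c(100, 500, 900), c(200, 600, 1000),
              subfamily = rep("S1", 3))
  # no random region hits any instance
  rnd <- gr0("chr1", c(2000, 3000), c(2100, 3100))
  expect_equal(expected_count(rnd, inst, "S1", 100, 2), 0)
  # 1 overlap event among 4 random regions, 100 true peaks -> 25
  rnd2 <- gr0("chr1", c(150, 2000, 3000, 4000), c(160, 2100, 3100, 4100))
  expect_equal(expected_count(rnd2, inst, "S1", 100, 4), 25)
  expect_error(expected_count(rnd2, inst, "S1", 100, 0), "n_random")
})

test_that("fold enrichment handles the boundary conventions", {
  expect_equal(fold_enrichment(1237, 60.5), 1237 / 60.5)   # ~20.45
  expect_equal(fold_enrichment(5, 5), 1)
  expect_equal(fold_enrichment(0, 3), 0)
  expect_warning(f <- fold_enrichment(2, 0), "Inf")
  expect_identical(f, Inf)
  expect_equal(fold_enrichment(0, 0), 1)
  expect_error(fold_enrichment(-1, 2), ">= 0")
})

test_that("call_dars recovers planted subfamilies and stays calibrated on nulls", {
  b <- small_bundle()
  r <- small_dars()
  expect_s3_class(r, "dar_results")
  expect_true(all(r$observed <= r$n_instances))
  expect_true(all(r$p0 >= 0 & r$p0 <= 1))
  # is_dar consistent with stored fields
  expect_identical(r$is_dar, r$log10_p < log10(attr(r, "config")$alpha))
  tr <- b$truth[b$truth$effect == "dar", ]
  key <- paste(r$subfamily, r$dataset_id)
  planted <- match(paste(tr$subfamily, tr$partner), key)
  expect_true(all(r$is_dar[planted]))
  expect_true(all(r$fold[planted] > 3))
  # null pairs: no false calls at alpha = 1e-5 in this study
  null_rows <- setdiff(seq_len(nrow(r)), planted)
  expect_lte(mean(r$is_dar[null_rows]), 10 * 1e-5 + 1 / length(null_rows))
  # generator calibration: mean observed/expected near 1 over null pairs
  ratio <- r$observed[null_rows] / r$expected[null_rows]
  expect_gt(mean(ratio), 0.8)
  expect_lt(mean(ratio), 1.2)
})

test_that("a null study yields a false-positive rate <= 10x nominal", {
  cfg <- study_config(
    chrom_sizes = c(chr1 = 5e5, chr2 = 5e5),
    n_subfamilies = 50, instances_per_subfamily = c(40, 90),
    n_genes = 100, gene_length = c(1500, 6000),
    enrichment = data.frame(subfamily = integer(0), cell_type = character(0),
                            fold = numeric(0)),
    chip_factors = data.frame(tf = character(0), cell_type = character(0),
                              subfamily = integer(0), bind_prob = numeric(0)),
    motif_plants = data.frame(motif = integer(0), subfamily = integer(0),
                              plant_fraction = numeric(0)),
    n_motifs = 1, n_cnee = 100, n_dsqtl = 40,
    datasets = transform(darcall:::default_datasets()[1:6, ], n_peaks = 150L))
  b <- generate_study(cfg, seed = 2024)
  r <- call_dars(b$datasets, b$repeats, b$genes, b$chrom_sizes,
                 dar_config(n_random = 30000, seed = 3))
  expect_equal(nrow(r), 50 * 6)
  expect_lte(mean(r$is_dar), 10 * 1e-5 + 1 / nrow(r))
  ratio <- r$observed / r$expected
  expect_gt(mean(ratio[is.finite(ratio)]), 0.8)
  expect_lt(mean(ratio[is.finite(ratio)]), 1.2)
})

test_that("open fractions union per-dataset hit sets over the subfamily", {
  r <- small_dars()
  b <- small_bundle()
  of <- open_fraction(r)
  expect_true(all(of >= 0 & of <= 1))
  # independent recomputation for one subfamily
  hits <- attr(r, "hits")
  sf <- "SF01"
  ids <- unique(unlist(lapply(hits, `[[`, sf)))
  expect_equal(unname(of[sf]), length(ids) / sum(b$repeats$subfamily == sf))
})
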