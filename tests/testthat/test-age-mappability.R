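test_that("Jukes-Cantor ages follow the closed form and the primate cutoff", {
  expect_equal(jukes_cantor_age(0)$jc_distance, 0)
  expect_equal(jukes_cantor_age(0)$age_myrs, 0)
  # milliDiv 150 at 2.2e-9/site/yr: d = -(3/4) ln(1 - 0.2) ~ 0.16736, ~76.1 Myr
  a <- jukes_cantor_age(150)
  expect_equal(a$jc_distance, -0.75 * log(1 - 4 * 0.15 / 3), tolerance = 1e-12)
  expect_equal(a$age_myrs, 76.07, tolerance = 1e-3)
  expect_true(a$primate_specific)
  # the 95-Myr boundary
  md94 <- 1000 * 0.75 * (1 - exp(-94e6 * 2.2e-9 / 0.75))
  md96 <- 1000 * 0.75 * (1 - exp(-96e6 * 2.2e-9 / 0.75))
  expect_true(jukes_cantor_age(md94)$primate_specific)
  expect_false(jukes_cantor_age(md96)$primate_specific)
  expect_error(jukes_cantor_age(760), "0.75")
})

test_that("JC distance is strictly increasing and dominates raw divergence", {
  md <- seq(5, 700, by = 5)
  d <- jukes_cantor_age(md)$jc_distance
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= md / 1000))
})

test_that("subfamily profiles summarise instances and classify ages", {
  b <- small_bundle()
  pr <- subfamily_profiles(b$repeats)
  expect_equal(sum(pr$n_instances), length(b$repeats))
  expect_true(all(pr$age_myrs >= 0))
  one <- pr$subfamily[1]
  expect_equal(pr$mean_milli_div[1],
               mean(b$repeats$milli_div[b$repeats$subfamily == one]))
})

test_that("lineage partition tabulates per-label repeat-class proportions", {
  cl <- gr0("chr1", c(0, 1000, 2000, 3000), c(100, 1100, 2100, 3100))
  reps <- gr0("chr1", c(50, 1050), c(80, 1080),
              subfamily = c("a", "b"), repclass = c("SINE", "SINE"))
  reps$repclass <- c("SINE", "SINE")
  out <- lineage_partition(cl, c("primate", "primate", "mammalian", "mammalian"),
                           reps)
  expect_equal(as.integer(out$counts), c(2L, 2L))
  expect_equal(out$class_proportions["primate", "SINE"], 1.0)
  expect_equal(out$class_proportions["mammalian", "SINE"], 0)
  expect_error(lineage_partition(cl, c("a", "b", NA, "c"), reps), "label")
})

test_that("mappability is 0 for duplicated subfamilies and 1 for unique ones", {
  # genome: unique random left arm, then two identical 400-bp copies
  set.seed(5)
  uniq <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE,
                       prob = c(0.35, 0.15, 0.15, 0.35)), collapse = "")
  seg <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(paste0(uniq, seg, strrep("A", 200), seg))
  names(genome) <- "chr1"
  reps <- gr("chr1", c(4001, 4601, 1001), c(4400, 5000, 1400),
             subfamily = c("dup", "dup", "uniq"))
  reps$subfamily <- c("dup", "dup", "uniq")
  mr <- mappability_ratio(genome, reps, read_length = 30, n_reads = 3000,
                          max_mismatches = 0, seed = 8)
  expect_equal(mr$ratio[mr$subfamily == "dup"], 0)
  expect_equal(mr$ratio[mr$subfamily == "uniq"], 1)
})

test_that("uniqueness agrees with a pure-string brute-force oracle", {
  set.seed(11)
  g <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(g); names(genome) <- "chr1"
  reps <- gr("chr1", 501, 1500, subfamily = "S")
  reps$subfamily <- "S"
  mr <- mappability_ratio(genome, reps, read_length = 12, n_reads = 400,
                          max_mismatches = 0, seed = 3)
  # oracle: slide a 12-mer window over the genome string and its revcomp
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(g, "")[[1]]), collapse = ""))
  kmers <- substring(g, 1:(nchar(g) - 11), 12:nchar(g))
  kmers_rc <- substring(rc, 1:(nchar(rc) - 11), 12:nchar(rc))
  counts <- table(c(kmers, kmers_rc))
  frac_unique_region <- mean(vapply(501:(1500 - 11), function(i)
    counts[[substr(g, i, i + 11)]] == 1, logical(1)))
  # the sampled estimate should sit near the exhaustive fraction
  expect_equal(mr$ratio[1], frac_unique_region, tolerance = 0.1)
})

test_that("raising the mismatch budget never raises the ratio", {
  set.seed(13)
  g <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE), collapse = "")
  # append a slightly mutated copy of an internal segment
  seg <- substr(g, 1001, 1300)
  segm <- strsplit(seg, "")[[1]]
  idx <- seq(10, 290, by = 25)
  segm[idx] <- c("A", "C", "G", "T")[(match(segm[idx], c("A", "C", "G", "T")) %% 4) + 1]
  genome <- Biostrings::DNAStringSet(paste0(g, paste(segm, collapse = "")))
  names(genome) <- "chr1"
  reps <- gr("chr1", 1001, 1300, subfamily = "S")
  reps$subfamily <- "S"
  r0 <- mappability_ratio(genome, reps, read_length = 25, n_reads = 150,
                          max_mismatches = 0, seed = 4)$ratio[1]
  r2 <- mappability_ratio(genome, reps, read_length = 25, n_reads = 150,
                          max_mismatches = 2, seed = 4)$ratio[1]
  expect_lte(r2, r0)
})
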