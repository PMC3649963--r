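test_that("resize_to_center applies the floor-midpoint rule and clips at edges", {
  # already a centered 200-bp window: unchanged
  expect_equal(as.data.frame(resize_to_center(gr0("chr1", 100, 300), 200))[, 2:3],
               data.frame(start = 101L, end = 300L))
  # odd length: midpoint floor((100+301)/2) = 200 -> [100, 300)
  expect_equal(as.data.frame(resize_to_center(gr0("chr1", 100, 301), 200))[, 2:3],
               data.frame(start = 101L, end = 300L))
  # clipping at the chromosome start shifts the window to [0, 200)
  expect_equal(as.data.frame(resize_to_center(gr0("chr1", 10, 20), 200))[, 2:3],
               data.frame(start = 1L, end = 200L))
  # clipping at the chromosome end
  out <- resize_to_center(gr0("chr1", 980, 990), 200,
                          chrom_sizes = c(chr1 = 1000))
  expect_equal(BiocGenerics::end(out), 1000L)
  expect_equal(BiocGenerics::width(out), 200L)
  expect_error(resize_to_center(gr0("chr1", 0, 10), 0), "positive")
})

test_that("cluster_regions groups by strict gap and respects the examples", {
  # gap 50 < 100: one cluster
  g <- c(gr0("chr1", 0, 100), gr0("chr1", 150, 250))
  expect_equal(length(cluster_regions(g, 100)), 1L)
  # gap 150 >= 100: two clusters
  g2 <- c(gr0("chr1", 0, 100), gr0("chr1", 250, 350))
  expect_equal(length(cluster_regions(g2, 100)), 2L)
  # gap exactly 100 is not merged (strict <)
  g3 <- c(gr0("chr1", 0, 100), gr0("chr1", 200, 300))
  expect_equal(length(cluster_regions(g3, 100)), 2L)
  # single interval maps to itself
  expect_equal(length(cluster_regions(gr0("chr1", 5, 10), 100)), 1L)
})

test_that("clustering is idempotent and monotone in max_gap", {
  x <- random_intervals(300, max_pos = 2e4, seed = 7)
  for (gap in c(0, 10, 100, 1000)) {
    cl <- cluster_regions(x, gap)
    cl2 <- cluster_regions(GenomicRanges::granges(cl), gap)
    expect_identical(as.data.frame(GenomicRanges::granges(cl)),
                     as.data.frame(GenomicRanges::granges(cl2)))
  }
  n <- vapply(c(0, 10, 50, 100, 500, 5000),
              function(gap) length(cluster_regions(x, gap)), integer(1))
  expect_true(all(diff(n) <= 0))
})

test_that("overlap bookkeeping uses half-open arithmetic and set semantics", {
  inst <- c(gr0("chr1", 250, 400, subfamily = "S1"),
            gr0("chr1", 300, 400, subfamily = "S2"))
  inst$subfamily <- c("S1", "S2")
  # region [100,300) overlaps [250,400) by 50 bp but not [300,400)
  res <- overlapping_instance_sets(gr0("chr1", 100, 300), inst)
  expect_equal(res$hit_ids, list(S1 = 1L))
  # two regions hitting one instance count it once
  res2 <- overlapping_instance_sets(c(gr0("chr1", 100, 300), gr0("chr1", 200, 320)),
                                    inst)
  expect_equal(res2$hit_ids$S1, 1L)
})

test_that("overlap relation agrees with a brute-force all-pairs scan", {
  a <- random_intervals(400, max_pos = 3e4, seed = 21)
  b <- random_intervals(400, max_pos = 3e4, seed = 22)
  b$subfamily <- rep(c("X", "Y"), 200)
  got <- overlapping_instance_sets(a, b)
  # brute force on plain integers (1-based closed)
  as_ <- BiocGenerics::start(a); ae <- BiocGenerics::end(a)
  bs <- BiocGenerics::start(b); be <- BiocGenerics::end(b)
  hit <- vapply(seq_along(b), function(j)
    any(as_ <= be[j] & bs[j] <= ae), logical(1))
  expect_identical(got$instance_hit, hit)
})

test_that("tag GC QC applies the 45-55% acceptance window", {
  expect_false(qc_tag_gc(c("ATAT", "TTAA"))$pass)      # GC 0
  expect_true(qc_tag_gc(c("ACGT", "GCTA"))$pass)       # GC exactly 0.50
  expect_false(qc_tag_gc(rep(0.56, 10))$pass)          # above the 55% bound
  expect_true(qc_tag_gc(c(0.45, 0.55))$pass)
  expect_error(qc_tag_gc(character(0)), "empty")
})

test_that("aggregate profiles count strand-oriented tag offsets", {
  inst <- gr("chr1", c(1000, 5000), c(1099, 5099), strand = c("+", "+"))
  expect_equal(aggregate_profile(gr("chr1", 1, 1), inst, flank = 0),
               numeric(100))
  # one tag at offset 10 of one of two plus-strand instances
  prof <- aggregate_profile(gr("chr1", 1010, 1010), inst, flank = 5)
  expect_equal(prof[5 + 10 + 1], 0.5)
  expect_equal(sum(prof), 0.5)
  # minus-strand instance: offset mirrors to length-1-10 = 89
  minus <- gr("chr1", 1000, 1099, strand = "-")
  prof2 <- aggregate_profile(gr("chr1", 1010, 1010), minus, flank = 0)
  expect_equal(which(prof2 > 0) - 1L, 89L)
  expect_error(aggregate_profile(gr("chr1", 1, 1), inst[0]), "instances")
})
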