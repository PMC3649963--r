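test_that("gene-proximity categories follow the distance rules and precedence", {
  genes <- toy_genes()
  cat_at <- function(pos) as.character(annotate_region(gr("chr1", pos, pos), genes))
  expect_equal(cat_at(200000 - 500), "TSS")          # 500 bp from a TSS
  expect_equal(cat_at(200000 - 3000), "promoter")    # 3 kb upstream, outside body
  expect_equal(cat_at(205000), "intragenic")         # inside gA body
  expect_equal(cat_at(218000), "proximal")           # 8 kb past gA end
  expect_equal(cat_at(260000), "distal")             # 50 kb past gA end
  expect_equal(cat_at(701000), "desert")             # >100 kb from gB and gC
  # promoter is strand-aware: gB is minus, upstream means > tss
  expect_equal(cat_at(540000 + 3000), "promoter")
  expect_equal(cat_at(540000 - 3000), "intragenic")  # inside gB body instead
  # precedence: 800 bp upstream is both TSS-near and promoter; TSS wins
  expect_equal(cat_at(200000 - 800), "TSS")
})

test_that("annotation distribution matches per-region tallies and sums to 1", {
  genes <- toy_genes()
  pos <- seq(1000, 999000, by = 997)
  regions <- gr("chr1", pos, pos)
  d <- annotation_distribution(regions, genes)
  expect_equal(sum(d), 1)
  tal <- table(annotate_region(regions, genes)) / length(regions)
  expect_equal(as.numeric(d), as.numeric(tal))
  expect_error(annotation_distribution(regions[0], genes), "non-empty")
})

test_that("matched random sampling hits the target distribution exactly", {
  genes <- toy_genes()
  target <- c(TSS = 0.2, promoter = 0.1, intragenic = 0.3, proximal = 0.15,
              distal = 0.15, desert = 0.1)
  bg <- sample_matched_random(genes, toy_chrom_sizes, target, n = 2000,
                              region_width = 200, seed = 9)
  expect_equal(length(bg), 2000L)
  expect_true(all(BiocGenerics::width(bg) == 200L))
  # every region re-annotates to its assigned category (by construction)
  expect_true(all(as.character(annotate_region(bg, genes)) == bg$category))
  # per-category counts follow largest-remainder apportionment of n x target
  expect_equal(as.integer(table(factor(bg$category,
                                       levels = names(target)))[names(target)]),
               as.integer(round(2000 * target)))
})

test_that("matched sampling is reproducible and respects degenerate targets", {
  genes <- toy_genes()
  a <- sample_matched_random(genes, toy_chrom_sizes, c(desert = 1), n = 100,
                             region_width = 200, seed = 5)
  b <- sample_matched_random(genes, toy_chrom_sizes, c(desert = 1), n = 100,
                             region_width = 200, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(bg_cat <- as.character(annotate_region(a, genes)) == "desert"))
  c2 <- sample_matched_random(genes, toy_chrom_sizes, c(desert = 1), n = 100,
                              region_width = 200, seed = 6)
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))
})

test_that("empirical deviation at n = 10000 stays under 0.5% per category", {
  genes <- toy_genes()
  target <- c(TSS = 0.05, promoter = 0.05, intragenic = 0.25, proximal = 0.2,
              distal = 0.3, desert = 0.15)
  bg <- sample_matched_random(genes, toy_chrom_sizes, target, n = 10000,
                              region_width = 200, seed = 31)
  emp <- annotation_distribution(bg, genes)
  expect_true(all(abs(emp[names(target)] - target) < 0.005))
})

test_that("an unreachable category is reported by name", {
  # single gene covering everything: no desert exists
  genes <- gr("chr1", 1, 999999, strand = "+", name = "g", tss = 1)
  expect_error(
    sample_matched_random(genes, toy_chrom_sizes, c(desert = 1), n = 10,
                          region_width = 200, seed = 1),
    "desert")
})
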