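make_expr <- function(values, cell_types) {
  list(values = values, dataset_ids = colnames(values),
       cell_types = cell_types, genes = rownames(values))
}

test_that("up-regulation calls follow the max-z rule over outside datasets", {
  set.seed(1)
  v <- matrix(rnorm(50 * 6), 50, 6,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("d%d", 1:6)))
  ct <- c("A", "A", "B", "B", "C", "C")
  # constant gene: never up-regulated
  v["g01", ] <- 3
  # plant clean 4-sd shifts into 10 genes for cell type A
  planted <- sprintf("g%02d", 11:20)
  base <- matrix(rnorm(10 * 6, sd = 0.5), 10, 6)
  v[planted, ] <- base
  v[planted, 1:2] <- base[, 1:2] + 4 * 0.5 * 2  # far above the outside spread
  up <- upregulated_genes(make_expr(v, ct), "A")
  expect_true(all(planted %in% up))
  expect_false("g01" %in% up)
  # invariance under per-gene constant shifts
  v2 <- v + 7
  expect_identical(sort(upregulated_genes(make_expr(v2, ct), "A")), sort(up))
  expect_error(upregulated_genes(make_expr(v[, 1:2], ct[1:2]), "A"), ">= 2")
})

test_that("dar_gene_set collects distinct genes inside the centered window", {
  genes <- toy_genes()
  # no gene within a 50-kb window around position 700000
  inst_far <- gr("chr1", 700000, 700100)
  expect_equal(dar_gene_set(inst_far, genes), character(0))
  # two instances flanking gA: counted once
  inst2 <- gr("chr1", c(195000, 212000), c(195200, 212200))
  expect_equal(dar_gene_set(inst2, genes), "gA")
  # window boundary: gene body must overlap the window
  inst3 <- gr("chr1", 200000 - 26000, 200000 - 26000)
  expect_equal(dar_gene_set(inst3, genes, window_bp = 50000), character(0))
})

test_that("permutation z matches hypergeometric moments and is reproducible", {
  universe <- sprintf("g%03d", 1:200)
  up <- universe[1:50]            # K/N = 0.25
  z1 <- expression_permutation_z(30, 40, up, universe, n_perm = 10000, seed = 2)
  z2 <- expression_permutation_z(30, 40, up, universe, n_perm = 10000, seed = 2)
  expect_identical(z1, z2)
  # closed-form hypergeometric moments
  N <- 200; K <- 50; n <- 40
  mu <- n * K / N
  sg <- sqrt(n * K / N * (1 - K / N) * (N - n) / (N - 1))
  se <- sg / sqrt(10000)
  expect_lt(abs(z1$perm_mean - mu), 3 * se)
  expect_equal(z1$perm_sd, sg, tolerance = 0.05)
  # observed at the permutation mean -> z near 0
  z0 <- expression_permutation_z(round(mu), n, up, universe,
                                 n_perm = 5000, seed = 3)
  expect_lt(abs(z0$z), 0.5)
  expect_error(expression_permutation_z(1, 500, up, universe, 1000, 1),
               "universe")
})

test_that("the published-form z arithmetic reproduces a 15.1-15.2 score", {
  # (85 - 19.6) / 4.3, the shape of the statistic the permutation builds
  expect_equal((85 - 19.6) / 4.3, 15.209, tolerance = 1e-3)
})

test_that("window-based z detects planted expressed neighborhoods", {
  cs <- c(chr1 = 2e6)
  set.seed(9)
  win <- 50000
  # instances in three windows; elevated tag density there for cell type A
  inst <- gr("chr1", c(125000, 625000, 1325000), c(125300, 625300, 1325300))
  mk_tags <- function(base_rate, hot_mult) {
    n_bg <- rpois(1, base_rate * 2e6)
    pos <- sample.int(2e6, n_bg, replace = TRUE)
    hot <- unlist(lapply(c(100001, 600001, 1300001), function(s)
      s + sample.int(win, round(base_rate * win * (hot_mult - 1)), replace = TRUE)))
    gr("chr1", c(pos, hot), c(pos, hot))
  }
  tags <- list(a1 = mk_tags(0.002, 6), a2 = mk_tags(0.002, 6),
               b1 = mk_tags(0.002, 1), b2 = mk_tags(0.002, 1),
               c1 = mk_tags(0.002, 1), c2 = mk_tags(0.002, 1))
  ctypes <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C", c2 = "C")
  z <- rnaseq_window_z(inst, tags, ctypes, "A", cs, window_bp = win,
                       n_perm = 2000, seed = 12)
  expect_gt(z$z, 3)
  # all-zero densities: no window is up-regulated
  empty <- lapply(tags, function(x) x[0])
  z0 <- suppressWarnings(rnaseq_window_z(inst, empty, ctypes, "A", cs,
                                         window_bp = win, n_perm = 500,
                                         seed = 12))
  expect_equal(z0$observed, 0)
})
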