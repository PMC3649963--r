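# Exhaustive hypergeometric tail by combinatorial enumeration.
enum_hyper_sf <- function(k, N, K, n) {
  kk <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

test_that("hypergeom_sf matches exhaustive enumeration for N <= 60", {
  for (N in c(5, 20, 60)) {
    for (K in unique(c(0, 2, N %/% 2, N))) {
      for (n in unique(c(1, N %/% 3, N))) {
        for (k in 0:min(K, n)) {
          expect_equal(hypergeom_sf(k, N, K, n), enum_hyper_sf(k, N, K, n),
                       tolerance = 1e-10,
                       label = sprintf("k=%d N=%d K=%d n=%d", k, N, K, n))
        }
      }
    }
  }
  expect_equal(hypergeom_sf(5, 10, 5, 5), 1 / 252)
  expect_equal(hypergeom_sf(0, 10, 5, 5), 1)
  expect_equal(hypergeom_sf(4, 20, 10, 4), 210 / 4845)
  # monotone non-increasing in k
  p <- hypergeom_sf(0:10, 30, 10, 15)
  expect_true(all(diff(p) <= 1e-15))
})

test_that("PWM p-values agree with 4^L word enumeration", {
  set.seed(3)
  for (L in c(4, 6, 8)) {
    mat <- matrix(stats::runif(4 * L, 0.02, 1), 4, L)
    mat <- sweep(mat, 2, colSums(mat), "/")
    p <- pwm(mat, "t")
    # enumerate every word's integer score under the uniform background
    grids <- rep(list(1:4), L)
    words <- as.matrix(expand.grid(grids))
    sc <- integer(nrow(words))
    for (j in 1:L) sc <- sc + p$lom_q[cbind(words[, j], j)]
    qs <- sort(sc)[ceiling(c(0.05, 0.5, 0.9, 0.99) * length(sc))]
    for (q in qs) {
      expect_equal(pwm_score_pvalue(p, q * p$bin_bits),
                   mean(sc >= q), tolerance = 1e-9)
    }
    # extremes
    expect_equal(pwm_score_pvalue(p, min(sc) * p$bin_bits), 1)
    expect_equal(pwm_score_pvalue(p, (max(sc) + 1) * p$bin_bits), 0)
  }
})

test_that("a single dominant-base position has hit probability 1/4", {
  mat <- matrix(0.05 / 3, 4, 4)
  mat[cbind(c(1, 2, 3, 4), 1:4)] <- 0.95
  p <- pwm(mat, "acgt")
  # the consensus word ACGT: p-value = P(all four positions maximal) = (1/4)^4?
  best <- sum(apply(p$lom_q, 2, max)) * p$bin_bits
  expect_equal(pwm_score_pvalue(p, best), (0.25)^4, tolerance = 1e-9)
})

test_that("pwm_scan finds planted sites on both strands with consistent p-values", {
  mat <- matrix(0.02, 4, 6)
  mat[cbind(match(c("A", "C", "G", "T", "A", "C"), c("A", "C", "G", "T")), 1:6)] <- 0.94
  p <- pwm(mat, "m6")
  bgseq <- strrep("G", 40)
  s_plus <- paste0(bgseq, "ACGTAC", bgseq)
  hits <- pwm_scan(c(s1 = s_plus), p, p_threshold = 1e-3)
  expect_true(any(hits$strand == "+" & hits$offset == 40))
  # reverse-complement input: same hit set with flipped strands/offsets
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s_plus, "")[[1]]), collapse = ""))
  hits_rc <- pwm_scan(c(s1 = rc), p, p_threshold = 1e-3)
  expect_equal(nrow(hits), nrow(hits_rc))
  expect_equal(sort(hits$p_value), sort(hits_rc$p_value), tolerance = 1e-12)
  map_off <- nchar(s_plus) - (hits$offset + p$length)
  expect_setequal(hits_rc$offset, map_off)
  # a PWM longer than the sequence yields no hits, no error
  expect_equal(nrow(pwm_scan(c(x = "ACGT"), p, 0.5)), 0L)
})

test_that("JASPAR and MEME motif files parse into equivalent models", {
  jf <- tempfile()
  writeLines(c(">M001 testmotif",
               "A [ 10 0 0 5 ]", "C [ 0 10 0 5 ]",
               "G [ 0 0 10 0 ]", "T [ 0 0 0 0 ]"), jf)
  pj <- read_jaspar(jf)
  expect_named(pj, "M001")
  expect_equal(pj$M001$length, 4L)
  expect_equal(sum(pj$M001$prob[, 1]), 1)
  mf <- tempfile()
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies", "A 0.25 C 0.25 G 0.25 T 0.25",
               "", "MOTIF M002", "letter-probability matrix: alength= 4 w= 4",
               " 1.0 0.0 0.0 0.0", " 0.0 1.0 0.0 0.0",
               " 0.0 0.0 1.0 0.0", " 0.25 0.25 0.25 0.25"), mf)
  pm <- read_meme(mf)
  expect_named(pm, "M002")
  expect_equal(pm$M002$length, 4L)
})

test_that("joint association test counts flags and flags significance", {
  # disjoint partner and DHS hits: k = 0, p = 1
  d <- c(rep(TRUE, 5), rep(FALSE, 15))
  c1 <- c(rep(FALSE, 5), rep(TRUE, 5), rep(FALSE, 10))
  j <- joint_association_test(d, c1)
  expect_equal(j$n_both, 0L)
  expect_equal(j$log10_p, 0)
  expect_false(j$significant)
  # total overlap in a small universe: p = 1/C(20,10)
  d2 <- rep(c(TRUE, FALSE), each = 10)
  j2 <- joint_association_test(d2, d2)
  expect_equal(10^j2$log10_p, 1 / choose(20, 10), tolerance = 1e-9)
  expect_true(j2$significant)
  expect_error(joint_association_test(d, c1[-1]), "universe")
})

test_that("independent random flags are significant at ~the nominal rate", {
  set.seed(77)
  n_sig <- 0; n_pairs <- 1000
  for (i in seq_len(n_pairs)) {
    d <- stats::runif(60) < 0.3
    c1 <- stats::runif(60) < 0.3
    n_sig <- n_sig + joint_association_test(d, c1)$significant
  }
  # nominal 0.001 (conservative, discrete); allow generous binomial slack
  expect_lte(n_sig, 6)
})

test_that("classifier features separate planted from null subfamilies", {
  b <- small_bundle()
  p1 <- b$pwms[[1]]
  seqs <- instance_sequences(b)
  gh <- pwm_scan(as.character(b$genome), p1, 1e-5)
  gpos <- 2 * sum(nchar(as.character(b$genome)) - p1$length + 1)
  planted <- which(b$repeats$subfamily == "SF01")
  nulls <- which(b$repeats$subfamily == "SF07")
  fp <- classifier_features(seqs[planted], p1, nrow(gh), gpos, n_sim = 3, seed = 2)
  fn <- classifier_features(seqs[nulls], p1, nrow(gh), gpos, n_sim = 3, seed = 2)
  expect_gt(fp$f1, 0.5)           # ~80% of instances carry the plant
  expect_lt(fn$f1, 0.1)
  expect_gt(fp$f2, fn$f2)
  expect_lt(fp$f4, fn$f4)         # much smaller log10 p for the planted set
  expect_gt(fp$f5, fn$f5)
  expect_error(classifier_features(character(0), p1, 1, 10), "empty")
})

test_that("weighted rank average is symmetric, bounded and flags the top decile", {
  ft <- data.frame(f1 = c(0.9, 0.1, 0.5), f2 = c(0.8, 0.05, 0.4),
                   f3 = c(2, 1, 1.5), f4 = c(-50, -1, -10), f5 = c(9, 1, 3))
  out <- weighted_rank_average(ft)
  expect_equal(out$rank_score, c(1, 0, 0.5))
  expect_true(out$top_decile[1])
  # single pair: rank score 1 regardless of weights
  expect_equal(weighted_rank_average(ft[1, ])$rank_score, 1)
  # permuting feature columns together with weights leaves scores unchanged
  w <- c(f1 = 3, f2 = 1, f3 = 2, f4 = 1, f5 = 0.5)
  a <- weighted_rank_average(ft, weights = w)
  ft2 <- ft[, c("f2", "f1", "f3", "f5", "f4")]
  names(ft2) <- c("f2", "f1", "f3", "f5", "f4")
  b2 <- weighted_rank_average(ft2, weights = w)
  expect_equal(a$rank_score, b2$rank_score)
  expect_error(weighted_rank_average(ft, weights = c(f1 = 0, f2 = 0, f3 = 0,
                                                     f4 = 0, f5 = 0)), "weights")
})

test_that("the motif support rule applies strict >25 and >20% cutoffs", {
  expect_true(motif_support_rule(26, 0.30))
  expect_false(motif_support_rule(25, 0.30))    # not > 25
  expect_false(motif_support_rule(100, 0.10))   # fraction too low
  expect_false(motif_support_rule(100, 0.20))   # not > 0.20
})
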