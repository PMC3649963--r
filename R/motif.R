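# PWM scanning with exact p-values, TF/motif-repeat joint association tests,
# the five-feature motif-repeat classifier and the tissue-specific motif
# support rule.
#
# Scores are log-odds in bits against a 0-order background, discretised to a
# fixed bin width; the null score distribution is obtained by position-wise
# convolution on the same grid, so scan scores and p-values are exactly
# consistent (and match brute-force word enumeration for short motifs).

DNA <- c("A", "C", "G", "T")

#' Construct a position weight matrix model
#'
#' @param mat 4 x L numeric matrix (rows A, C, G, T) of counts or
#'   probabilities; count matrices get `pseudocount` added per cell before
#'   column normalization.
#' @param motif_id Motif identifier.
#' @param pseudocount Per-cell pseudocount for count matrices (default
#'   0.25).
#' @param background Background base frequencies (default uniform).
#' @param bin_bits Score discretisation width in bits (default 1e-3).
#' @return Object of class `pwm` with the probability matrix, integer
#'   log-odds scores on the bin grid, and the exact null tail distribution.
#' @export
pwm <- function(mat, motif_id = "motif", pseudocount = 0.25,
                background = rep(0.25, 4), bin_bits = 1e-3) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(mat) < 4) stop("PWM length must be >= 4")
  rownames(mat) <- DNA
  background <- background / sum(background)
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-6)) {          # counts -> probabilities
    mat <- sweep(mat + pseudocount, 2, cs + 4 * pseudocount, "/")
  } else if (any(mat == 0)) {             # guard zero probabilities
    mat <- sweep(mat + 1e-6, 2, colSums(mat + 1e-6), "/")
  }
  lom <- log2(sweep(mat, 1, background, "/"))
  lom_q <- round(lom / bin_bits)
  storage.mode(lom_q) <- "integer"
  obj <- structure(list(motif_id = motif_id, prob = mat,
                        background = background, bin_bits = bin_bits,
                        lom_q = lom_q, length = ncol(mat)),
                   class = "pwm")
  obj$null <- pwm_null_dist(obj)
  obj
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': length %d, bin %g bits, max score %.2f bits\n",
              x$motif_id, x$length, x$bin_bits,
              sum(apply(x$lom_q, 2, max)) * x$bin_bits))
  invisible(x)
}

# Exact null distribution of the integer score under the background model:
# position-wise convolution over the discretised score grid.
pwm_null_dist <- function(p) {
  # DP: running distribution over partial integer sums
  run_lo <- min(p$lom_q[, 1]); run_hi <- max(p$lom_q[, 1])
  run <- numeric(run_hi - run_lo + 1L)
  for (b in 1:4) {
    i <- p$lom_q[b, 1] - run_lo + 1L
    run[i] <- run[i] + p$background[b]
  }
  if (p$length > 1) for (j in 2:p$length) {
    s <- p$lom_q[, j]
    new_lo <- run_lo + min(s); new_hi <- run_lo + length(run) - 1L + max(s)
    new <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      sh <- run_lo + s[b] - new_lo
      idx <- seq_along(run) + sh
      new[idx] <- new[idx] + run * p$background[b]
    }
    run <- new; run_lo <- new_lo
  }
  tail_p <- rev(cumsum(rev(run)))
  list(score_lo = run_lo, tail = tail_p)   # tail[i] = P(S >= score_lo + i - 1)
}

# Tail probability of an integer score on the PWM's bin grid (vectorised).
pwm_tail_int <- function(p, s_int) {
  lo <- p$null$score_lo
  n <- length(p$null$tail)
  i <- s_int - lo + 1L
  out <- numeric(length(i))
  out[i <= 1L] <- 1
  mid <- i > 1L & i <= n
  out[mid] <- p$null$tail[i[mid]]
  out[i > n] <- 0
  out
}

#' Exact p-value of a PWM log-odds score
#'
#' Probability that a background word of motif length scores at least
#' `score`, from the convolution of the discretised per-position score
#' distribution.
#'
#' @param p A [pwm()] object.
#' @param score Log-odds score in bits (vectorised).
#' @return Tail probability in (0, 1\]; scores above the achievable maximum
#'   give 0.
#' @export
pwm_score_pvalue <- function(p, score) {
  pwm_tail_int(p, as.integer(round(score / p$bin_bits)))
}

# Encode sequences as integer codes A1 C2 G3 T4, anything else 0.
encode_dna <- function(x) {
  code <- integer(256)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  code[utf8ToInt("a")] <- 1L; code[utf8ToInt("c")] <- 2L
  code[utf8ToInt("g")] <- 3L; code[utf8ToInt("t")] <- 4L
  lapply(x, function(s) code[utf8ToInt(s)])
}

# Integer scores at every offset of one encoded sequence for an integer
# log-odds matrix; N positions (code 0) contribute 0.
scan_scores_int <- function(code, lom_q) {
  L <- ncol(lom_q); n <- length(code)
  if (n < L) return(integer(0))
  S <- integer(n - L + 1L)
  for (j in seq_len(L)) {
    lut <- c(0L, lom_q[, j])
    S <- S + lut[code[j:(j + n - L)] + 1L]
  }
  S
}

revcomp_lom <- function(lom_q) {
  out <- lom_q[c(4L, 3L, 2L, 1L), rev(seq_len(ncol(lom_q))), drop = FALSE]
  rownames(out) <- DNA
  out
}

#' Scan sequences with a PWM
#'
#' Scores both strands at every offset and emits hits whose exact p-value is
#' at or below the threshold. `N` bases contribute zero log-odds.
#'
#' @param sequences Character vector or `DNAStringSet` (names become
#'   `sequence_id`).
#' @param p A [pwm()] object.
#' @param p_threshold Maximum hit p-value (default 1e-5).
#' @return data.frame of hits: `sequence_id`, `offset` (0-based, leftmost
#'   base on the forward strand), `strand`, `score` (bits), `p_value`.
#' @export
pwm_scan <- function(sequences, p, p_threshold = 1e-5) {
  stopifnot_scalar_prob(p_threshold, "p_threshold")
  if (methods::is(sequences, "XStringSet")) sequences <- as.character(sequences)
  ids <- names(sequences)
  if (is.null(ids)) ids <- as.character(seq_along(sequences))
  codes <- encode_dna(sequences)
  # smallest integer score whose tail is <= threshold
  thr_idx <- which(p$null$tail <= p_threshold)
  if (!length(thr_idx)) return(empty_hits())
  s_min <- p$null$score_lo + thr_idx[1] - 1L
  lom_f <- p$lom_q
  lom_r <- revcomp_lom(p$lom_q)
  out <- vector("list", 2L * length(codes))
  k <- 0L
  for (i in seq_along(codes)) {
    for (str in c("+", "-")) {
      S <- scan_scores_int(codes[[i]], if (str == "+") lom_f else lom_r)
      hit <- which(S >= s_min)
      if (length(hit)) {
        k <- k + 1L
        out[[k]] <- data.frame(
          sequence_id = ids[i], offset = hit - 1L, strand = str,
          score = S[hit] * p$bin_bits,
          p_value = pwm_tail_int(p, S[hit]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) return(empty_hits())
  do.call(rbind, out[seq_len(k)])
}

empty_hits <- function() {
  data.frame(sequence_id = character(0), offset = integer(0),
             strand = character(0), score = numeric(0), p_value = numeric(0),
             stringsAsFactors = FALSE)
}

#' Read JASPAR-format count matrices
#'
#' Supports the common JASPAR text layout: a `>ID name` header followed by
#' four rows `A [ ... ]` / `C` / `G` / `T` (brackets optional), possibly
#' several motifs per file.
#'
#' @param path File path.
#' @param ... Passed to [pwm()] (pseudocount, background, bin width).
#' @return Named list of [pwm()] objects.
#' @export
read_jaspar <- function(path, ...) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no '>' motif headers in ", path)
  out <- list()
  for (h in seq_along(heads)) {
    i <- heads[h]
    stop_at <- if (h < length(heads)) heads[h + 1] - 1L else length(lines)
    block <- lines[(i + 1):stop_at]
    if (length(block) < 4) stop("motif block too short after line ", i)
    id <- sub("^>\\s*", "", lines[i])
    id <- strsplit(id, "\\s+")[[1]][1]
    rows <- lapply(block[1:4], function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("\\[|\\]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1)
      stop("ragged count rows for motif ", id)
    mat <- do.call(rbind, rows)
    out[[id]] <- pwm(mat, motif_id = id, ...)
  }
  out
}

#' Read MEME minimal-format motifs
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections;
#' uses the file's background letter frequencies when present.
#'
#' @inheritParams read_jaspar
#' @return Named list of [pwm()] objects.
#' @export
read_meme <- function(path, ...) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i) && bg_i[1] < length(lines)) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(toks))
    freq <- v[!is.na(v)]
    if (length(freq) == 4) bg <- freq
  }
  starts <- grep("^MOTIF", lines)
  if (!length(starts)) stop("no MOTIF blocks in ", path)
  out <- list()
  for (s in starts) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    lp <- grep("^letter-probability matrix", lines)
    lp <- lp[lp > s][1]
    if (is.na(lp)) stop("missing letter-probability matrix for motif ", id)
    w <- sub(".*w=\\s*(\\d+).*", "\\1", lines[lp])
    w <- as.integer(w)
    rows <- lines[(lp + 1):(lp + w)]
    mat <- t(vapply(rows, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
                    numeric(4)))
    out[[id]] <- pwm(t(mat), motif_id = id, background = bg, ...)
  }
  out
}

#' Joint hypergeometric test of ChIP (or motif) and DHS co-occurrence
#'
#' Universe = the subfamily's instances (N); successes = instances with a
#' partner peak/motif (K); draw = DHS-contributing instances (n); observed =
#' instances with both (k). One-sided hypergeometric upper tail.
#'
#' @param dhs_flags Logical per instance: contributes DHS.
#' @param partner_flags Logical per instance: has the ChIP peak / motif.
#' @param subfamily,partner Labels carried into the result.
#' @param alpha Significance cutoff (default 0.001).
#' @return One-row data.frame: `subfamily`, `partner`, `n_instances`,
#'   `n_dhs`, `n_partner`, `n_both`, `log10_p`, `significant`.
#' @export
joint_association_test <- function(dhs_flags, partner_flags,
                                   subfamily = NA_character_,
                                   partner = NA_character_, alpha = 0.001) {
  if (length(dhs_flags) != length(partner_flags))
    stop("flag vectors must cover the same instance universe")
  N <- length(dhs_flags)
  K <- sum(partner_flags)
  n <- sum(dhs_flags)
  k <- sum(dhs_flags & partner_flags)
  lp <- hypergeom_sf(k, N, K, n, log10 = TRUE)
  data.frame(subfamily = subfamily, partner = partner, n_instances = N,
             n_dhs = n, n_partner = K, n_both = k, log10_p = lp,
             significant = lp < log10(alpha), stringsAsFactors = FALSE)
}

# First-order Markov resample of a DNA code vector (N-free), via the
# compiled chain simulator; returns a code vector of the same length.
markov_resample_codes <- function(code, lengths_out) {
  code <- code[code > 0L]
  if (length(code) < 2L) stop("sequence too short to fit a Markov model")
  trans <- matrix(1e-9, 4, 4)
  from <- code[-length(code)]; to <- code[-1]
  for (b in 1:4) {
    idx <- from == b
    if (any(idx)) trans[b, ] <- trans[b, ] + tabulate(to[idx], nbins = 4)
  }
  trans <- trans / rowSums(trans)
  init <- tabulate(code, nbins = 4) / length(code)
  lapply(lengths_out, function(n) .markov_chain(n, trans, init))
}

#' Five-feature motif-repeat classifier features
#'
#' For one (motif, subfamily) pair computes: `f1` fraction of instances
#' with a motif hit; `f2` fraction of the genome's hits falling inside the
#' subfamily; `f3` mean best-hit score of ChIP-bound over unbound instances
#' (NA without `bound_flags`); `f4` log10 one-sided binomial p of the
#' subfamily hit count against the genome-wide per-position hit rate; `f5`
#' regularized ratio of the observed hit count to its mean over `n_sim`
#' first-order-Markov resamples of the instance sequences (the
#' motif-generation potential of the sequence composition).
#'
#' @param sequences Instance sequences (character or `DNAStringSet`).
#' @param p A [pwm()] object.
#' @param genome_n_hits Genome-wide hit count for this motif at the same
#'   threshold.
#' @param genome_n_positions Genome-wide number of scanned positions (both
#'   strands).
#' @param bound_flags Optional logical per instance: ChIP-bound.
#' @param n_sim Number of Markov resamples for f5 (default 10).
#' @param seed Integer seed for f5.
#' @param p_threshold Hit threshold (default 1e-5).
#' @return One-row data.frame with `f1`-`f5` and the underlying counts.
#' @export
classifier_features <- function(sequences, p, genome_n_hits,
                                genome_n_positions, bound_flags = NULL,
                                n_sim = 10, seed = 1L, p_threshold = 1e-5) {
  if (methods::is(sequences, "XStringSet")) sequences <- as.character(sequences)
  if (!length(sequences)) stop("empty subfamily")
  names(sequences) <- as.character(seq_along(sequences))
  hits <- pwm_scan(sequences, p, p_threshold)
  n_inst <- length(sequences)
  per_inst <- table(factor(hits$sequence_id, levels = names(sequences)))
  f1 <- mean(per_inst > 0)
  n_hits <- nrow(hits)
  f2 <- if (genome_n_hits > 0) min(1, n_hits / genome_n_hits) else 0
  f3 <- NA_real_
  if (!is.null(bound_flags)) {
    best <- tapply(hits$score, factor(hits$sequence_id, levels = names(sequences)),
                   max)
    best <- as.numeric(best)
    b <- best[bound_flags]; u <- best[!bound_flags]
    b <- b[!is.na(b)]; u <- u[!is.na(u)]
    if (length(b) && length(u) && mean(u) != 0) f3 <- mean(b) / mean(u)
  }
  L <- p$length
  npos <- sum(pmax(0L, nchar(sequences) - L + 1L)) * 2L
  rate <- if (genome_n_positions > 0) genome_n_hits / genome_n_positions else 0
  f4 <- binomial_sf(min(n_hits, npos), npos, min(1, rate), log10 = TRUE)
  codes <- encode_dna(sequences)
  lens <- vapply(codes, length, integer(1))
  thr <- pwm_threshold_int(p, p_threshold)
  lom_r <- revcomp_lom(p$lom_q)
  sim_counts <- with_seed(seed, vapply(seq_len(n_sim), function(s) {
    sim <- markov_resample_codes(unlist(codes), lens)
    sum(vapply(sim, function(cd) {
      sum(scan_scores_int(cd, p$lom_q) >= thr) +
        sum(scan_scores_int(cd, lom_r) >= thr)
    }, numeric(1)))
  }, numeric(1)))
  f5 <- (n_hits + 0.5) / (mean(sim_counts) + 0.5)
  data.frame(motif_id = p$motif_id, n_instances = n_inst, n_hits = n_hits,
             f1 = f1, f2 = f2, f3 = f3, f4 = f4, f5 = f5,
             stringsAsFactors = FALSE)
}

# Smallest integer score with tail <= threshold (Inf sentinel when none).
pwm_threshold_int <- function(p, p_threshold) {
  i <- which(p$null$tail <= p_threshold)
  if (!length(i)) return(.Machine$integer.max)
  p$null$score_lo + i[1] - 1L
}

#' Weighted rank average of classifier features
#'
#' Ranks every feature across (motif, subfamily) pairs so that 1 is most
#' motif-favorable (larger is better for f1, f2, f3, f5; smaller is better
#' for the f4 log10 p), normalizes ranks to \[0, 1\], and combines them as a
#' weighted mean over the non-missing features of each pair. The top decile
#' by rank score is flagged.
#'
#' @param features data.frame with columns `f1`-`f5` (e.g. rows from
#'   [classifier_features()]).
#' @param weights Non-negative feature weights (default equal).
#' @param top_fraction Fraction flagged (default 0.10).
#' @return The input with `rank_score` and `top_decile` columns appended.
#' @export
weighted_rank_average <- function(features,
                                  weights = c(f1 = 1, f2 = 1, f3 = 1,
                                              f4 = 1, f5 = 1),
                                  top_fraction = 0.10) {
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be >= 0 and not all zero")
  dirs <- c(f1 = 1, f2 = 1, f3 = 1, f4 = -1, f5 = 1)
  n <- nrow(features)
  norm_ranks <- sapply(names(dirs), function(f) {
    v <- features[[f]] * dirs[[f]]
    r <- rank(v, ties.method = "average", na.last = "keep")
    if (n == 1) ifelse(is.na(v), NA_real_, 1)
    else (r - 1) / (n - 1)
  })
  norm_ranks <- matrix(norm_ranks, nrow = n,
                       dimnames = list(NULL, names(dirs)))
  w <- matrix(rep(weights[names(dirs)], each = n), nrow = n)
  w[is.na(norm_ranks)] <- 0
  score <- rowSums(norm_ranks * w, na.rm = TRUE) / rowSums(w)
  features$rank_score <- score
  n_top <- ceiling(top_fraction * n)
  cutoff <- sort(score, decreasing = TRUE)[n_top]
  features$top_decile <- score >= cutoff
  features
}

#' Motif support rule for cell-type-specific DARs
#'
#' A (DAR, motif) pair is supported when the motif is present in more than
#' `min_instances` repeat instances and in more than `min_fraction` of the
#' DHS-contributing instances (strict inequalities).
#'
#' @param n_with_motif Instances carrying the motif (vectorised).
#' @param frac_dhs_with_motif Fraction of DHS-contributing instances
#'   carrying the motif.
#' @param min_instances Default 25.
#' @param min_fraction Default 0.20.
#' @return Logical vector.
#' @export
motif_support_rule <- function(n_with_motif, frac_dhs_with_motif,
                               min_instances = 25, min_fraction = 0.20) {
  n_with_motif > min_instances & frac_dhs_with_motif > min_fraction
}
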