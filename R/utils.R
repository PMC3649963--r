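# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded operations never disturb the
#' caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Small deterministic string hash (polynomial, 31-bit) used to derive
# per-dataset seeds from a master seed; keeps values inside R's integer range.
string_hash <- function(x) {
  v <- utf8ToInt(as.character(x))
  h <- 0
  for (c in v) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

derive_seed <- function(master_seed, key) {
  as.integer((as.numeric(master_seed) %% 2147483647 + string_hash(key)) %% 2147483629 + 1)
}

# GRanges constructor from 0-based half-open coordinates (file convention).
granges_0based <- function(chrom, start0, end0, strand = "*", seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand
  )
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("%s must be a probability in [0, 1]", name))
}
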