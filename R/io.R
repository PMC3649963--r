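#' Read genomic regions from standard file formats
#'
#' Parses BED3/BED6, ENCODE narrowPeak (10-column) and UCSC RepeatMasker
#' ("rmsk") tab tables into [GenomicRanges::GRanges]. File coordinates are
#' 0-based half-open (UCSC convention); the returned `GRanges` follow the
#' usual Bioconductor 1-based closed convention.
#'
#' narrowPeak records carry metadata columns `name`, `score`, `signalValue`,
#' `pValue`, `qValue` (both as -log10) and `peak` (point-source offset from
#' the region start, or -1 when absent). rmsk records become repeat instances
#' with metadata `subfamily`, `family`, `repclass` and `milli_div`; repeat
#' classes are collapsed to `LTR/ERV`, `DNA`, `LINE`, `SINE`,
#' `Low_complexity`, `Simple_repeat` or `Other`.
#'
#' @param path Path to an existing file.
#' @param format One of `"bed"`, `"narrowPeak"`, `"rmsk"`.
#' @return A `GRanges` with format-specific metadata columns.
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines("chr2\t0\t10", tf)
#' read_regions(tf, "bed")
#' @export
read_regions <- function(path, format = c("bed", "narrowPeak", "rmsk")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    bed = read_bed_file(path),
    narrowPeak = read_narrowpeak_file(path),
    rmsk = read_rmsk_file(path)
  )
}

check_field_counts <- function(path, allowed, what) {
  n <- utils::count.fields(path, sep = "\t", comment.char = "#",
                           quote = "", blank.lines.skip = TRUE)
  bad <- which(!(n %in% allowed))
  if (length(bad))
    stop(sprintf("malformed %s line %d in %s: expected %s tab-separated fields, found %d",
                 what, bad[1], path, paste(allowed, collapse = " or "), n[bad[1]]))
  invisible(TRUE)
}

read_bed_file <- function(path) {
  check_field_counts(path, c(3L, 4L, 5L, 6L), "BED")
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::GRanges(gr)
}

narrowpeak_extra_cols <- c(signalValue = "numeric", pValue = "numeric",
                           qValue = "numeric", peak = "integer")

read_narrowpeak_file <- function(path) {
  check_field_counts(path, 10L, "narrowPeak")
  gr <- rtracklayer::import(path, format = "BED", extraCols = narrowpeak_extra_cols)
  GenomicRanges::GRanges(gr)
}

#' @importFrom utils read.delim
read_rmsk_file <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("genoName", first, fixed = TRUE)
  df <- utils::read.delim(path, header = has_header, comment.char = "#",
                          quote = "", stringsAsFactors = FALSE)
  want <- c("genoName", "genoStart", "genoEnd", "strand", "repName",
            "repClass", "repFamily", "milliDiv")
  if (has_header) {
    miss <- setdiff(want, names(df))
    if (length(miss)) stop("rmsk table missing columns: ", paste(miss, collapse = ", "))
    df <- df[want]
  } else {
    if (ncol(df) != 8L)
      stop(sprintf("malformed rmsk line %d in %s: expected 8 tab-separated fields, found %d",
                   1L, path, ncol(df)))
    names(df) <- want
  }
  if (!is.numeric(df$genoStart) || !is.numeric(df$genoEnd) || !is.numeric(df$milliDiv)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$genoStart))))[1]
    stop(sprintf("malformed rmsk line %d in %s: non-numeric coordinate",
                 ifelse(is.na(bad), 1L, bad + has_header), path))
  }
  gr <- granges_0based(df$genoName, df$genoStart, df$genoEnd,
                       strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*"))
  S4Vectors::mcols(gr)$subfamily <- df$repName
  S4Vectors::mcols(gr)$family <- df$repFamily
  S4Vectors::mcols(gr)$repclass <- collapse_repclass(df$repClass)
  S4Vectors::mcols(gr)$milli_div <- as.integer(df$milliDiv)
  if (any(gr$milli_div < 0 | gr$milli_div > 1000))
    stop("milliDiv values must lie in [0, 1000]")
  gr
}

collapse_repclass <- function(x) {
  out <- rep("Other", length(x))
  out[grepl("^LTR|^ERV", x)] <- "LTR/ERV"
  out[grepl("^DNA", x)] <- "DNA"
  out[grepl("^LINE", x)] <- "LINE"
  out[grepl("^SINE", x)] <- "SINE"
  out[x == "Low_complexity"] <- "Low_complexity"
  out[x == "Simple_repeat"] <- "Simple_repeat"
  out
}

#' Read gene models from BED6
#'
#' Column 4 is the gene name, column 6 the strand. The transcription start
#' site (TSS) is the 5' end of the interval: the start for `+` genes, the
#' last base for `-` genes.
#'
#' @param path BED6 file path.
#' @return `GRanges` with metadata columns `name` and `tss` (1-based
#'   position of the TSS).
#' @export
read_genes <- function(path) {
  gr <- read_bed_file(path)
  if (any(!(as.character(BiocGenerics::strand(gr)) %in% c("+", "-"))))
    stop("gene models require explicit +/- strand")
  S4Vectors::mcols(gr)$tss <- gene_tss(gr)
  gr
}

# 1-based TSS position from stranded gene bodies.
gene_tss <- function(genes) {
  ifelse(as.character(BiocGenerics::strand(genes)) == "+",
         BiocGenerics::start(genes), BiocGenerics::end(genes))
}

#' Write intervals as sorted BED
#'
#' Emits deterministic, coordinate-sorted BED3 (or BED6 when `name`/`score`
#' metadata are present and `six = TRUE`), converting back to 0-based
#' half-open coordinates.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param six Write BED6 columns (name, score, strand).
#' @param header Optional character vector written as leading `#` comment
#'   lines (e.g. seed and parameter provenance).
#' @return Invisibly, `path`.
#' @export
write_bed <- function(gr, path, six = FALSE, header = NULL) {
  gr <- sort_granges(gr)
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    stringsAsFactors = FALSE
  )
  if (six) {
    nm <- S4Vectors::mcols(gr)$name
    if (is.null(nm)) nm <- sprintf("region_%d", seq_along(gr))
    sc <- S4Vectors::mcols(gr)$score
    if (is.null(sc)) sc <- 0
    df$name <- nm
    df$score <- sc
    df$strand <- sub("\\*", ".", as.character(BiocGenerics::strand(gr)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write peaks in ENCODE narrowPeak format
#'
#' @param peaks `GRanges` with (optionally) `name`, `score`, `signalValue`,
#'   `pValue`, `qValue`, `peak` metadata; missing columns are filled with
#'   narrowPeak defaults (`.`/0/-1).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_narrowpeak <- function(peaks, path) {
  peaks <- sort_granges(peaks)
  m <- S4Vectors::mcols(peaks)
  pick <- function(col, default) if (!is.null(m[[col]])) m[[col]] else rep(default, length(peaks))
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(peaks)),
    start = BiocGenerics::start(peaks) - 1L,
    end = BiocGenerics::end(peaks),
    name = pick("name", "."),
    score = pick("score", 0),
    strand = sub("\\*", ".", as.character(BiocGenerics::strand(peaks))),
    signalValue = pick("signalValue", 0),
    pValue = pick("pValue", -1),
    qValue = pick("qValue", -1),
    peak = pick("peak", -1L),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a RepeatMasker-style rmsk tab table
#'
#' @param repeats Repeat instances (`GRanges` with `subfamily`, `family`,
#'   `repclass`, `milli_div`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rmsk <- function(repeats, path) {
  repeats <- sort_granges(repeats)
  df <- data.frame(
    genoName = as.character(GenomeInfoDb::seqnames(repeats)),
    genoStart = BiocGenerics::start(repeats) - 1L,
    genoEnd = BiocGenerics::end(repeats),
    strand = sub("\\*", "+", as.character(BiocGenerics::strand(repeats))),
    repName = repeats$subfamily,
    repClass = repeats$repclass,
    repFamily = repeats$family,
    milliDiv = repeats$milli_div,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

sort_granges <- function(gr) {
  o <- order(as.character(GenomeInfoDb::seqnames(gr)),
             BiocGenerics::start(gr), BiocGenerics::end(gr))
  gr[o]
}

#' Read an expression matrix with a two-row header
#'
#' Row 1: dataset identifiers; row 2: cell-type labels; first column: gene
#' names (unique). Values are log-scale expression.
#'
#' @param path TSV path.
#' @return A list with `values` (genes x datasets matrix), `dataset_ids`,
#'   `cell_types`, `genes`.
#' @export
read_expression_matrix <- function(path) {
  lines <- readLines(path, n = 2L)
  hdr1 <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  hdr2 <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  dataset_ids <- hdr1[-1]
  cell_types <- hdr2[-1]
  if (any(cell_types == "")) stop("missing cell_type labels in expression header")
  df <- utils::read.delim(path, header = FALSE, skip = 2L, stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) stop("gene names must be unique")
  values <- as.matrix(df[-1])
  dimnames(values) <- list(genes, dataset_ids)
  list(values = values, dataset_ids = dataset_ids, cell_types = cell_types,
       genes = genes)
}

#' Write an expression matrix with a two-row header
#'
#' @param expr List as returned by [read_expression_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(expr, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", expr$dataset_ids), collapse = "\t"), con)
  writeLines(paste(c("cell_type", expr$cell_types), collapse = "\t"), con)
  utils::write.table(
    data.frame(gene = rownames(expr$values), expr$values, check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
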