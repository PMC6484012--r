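#' @importFrom stats p.adjust pbinom phyper ppois dnorm rnorm rpois rbinom
#'   runif rlnorm t.test fisher.test ks.test cor pt sd setNames aggregate
#' @importFrom utils head read.delim write.table
NULL

# Internal coordinate convention: 0-based, half-open [start, end), as in BED.
# 1-based formats are converted at the I/O boundary only.

#' Construct a peak set
#'
#' A peak set is the package's container for genomic intervals: ChIP peaks,
#' open-chromatin regions, footprint calls. Coordinates are 0-based
#' half-open. Intervals are stored sorted by (chrom, start).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand one of "+", "-", "." per interval (default ".").
#' @param score optional numeric score.
#' @param summit_offset optional integer offset of the summit from `start`;
#'   must lie in `[0, end - start)`.
#' @param name optional interval names.
#' @param set_name label for the whole set.
#' @param genome_length total genome length in bp, used for
#'   fraction-of-genome computations (NA if unknown).
#' @return A `peak_set`: a data.frame with columns chrom, start, end,
#'   strand, score, summit_offset, name, plus attributes `set_name` and
#'   `genome_length`.
#' @export
peak_set <- function(chrom, start, end, strand = NULL, score = NULL,
                     summit_offset = NULL, name = NULL,
                     set_name = "peaks", genome_length = NA_real_) {
  start <- as.integer(start); end <- as.integer(end)
  n <- length(start)
  stopifnot(length(end) == n)
  chrom <- rep_len(as.character(chrom), n)
  if (n > 0L) {
    if (any(!nzchar(chrom))) stop("chrom names must be nonempty")
    bad <- which(!(start >= 0L & start < end))
    if (length(bad))
      stop("invalid interval (need 0 <= start < end) at row ", bad[1])
  }
  if (is.null(strand)) strand <- "."
  strand <- rep_len(as.character(strand), n)
  if (n > 0L && any(!strand %in% c("+", "-", ".")))
    stop("strand must be one of +, -, .")
  if (is.null(score)) score <- rep(NA_real_, n)
  if (is.null(summit_offset)) summit_offset <- rep(NA_integer_, n)
  summit_offset <- as.integer(summit_offset)
  ok <- is.na(summit_offset) | (summit_offset >= 0L & summit_offset < end - start)
  if (n > 0L && any(!ok))
    stop("summit_offset outside [0, width) at row ", which(!ok)[1])
  if (is.null(name)) name <- rep(NA_character_, n)
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   strand = strand, score = as.numeric(score),
                   summit_offset = summit_offset,
                   name = as.character(name), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("peak_set", "data.frame"),
            set_name = set_name, genome_length = as.numeric(genome_length))
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set '%s': %d intervals on %d chrom(s)%s\n",
              attr(x, "set_name"), nrow(x), length(unique(x$chrom)),
              if (is.na(attr(x, "genome_length"))) ""
              else sprintf(", genome %.0f bp", attr(x, "genome_length"))))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 6))
  invisible(x)
}

# keep attributes through subsetting
#' @export
`[.peak_set` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "set_name") <- attr(x, "set_name")
    attr(out, "genome_length") <- attr(x, "genome_length")
    class(out) <- c("peak_set", "data.frame")
    rownames(out) <- NULL
  }
  out
}

# absolute summit coordinate (midpoint when no summit recorded)
peak_summits <- function(ps) {
  s <- ps$start + ifelse(is.na(ps$summit_offset),
                         (ps$end - ps$start) %/% 2L, ps$summit_offset)
  as.integer(s)
}

# split a peak set into an IRangesList-like plain list keyed by chrom
# (1-based closed coordinates for IRanges)
ps_irl <- function(ps) {
  idx <- split(seq_len(nrow(ps)), ps$chrom)
  lapply(idx, function(i) IRanges::IRanges(ps$start[i] + 1L, ps$end[i]))
}

#' Merge overlapping intervals of a peak set
#'
#' Overlapping or bookended intervals are collapsed; scores and summits are
#' dropped (a merged region's summit is no longer well defined).
#'
#' @param ps a [peak_set()].
#' @return merged `peak_set`.
#' @export
merge_peaks <- function(ps) {
  if (nrow(ps) == 0L) return(ps)
  irl <- ps_irl(ps)
  red <- lapply(irl, IRanges::reduce)
  chrom <- rep(names(red), vapply(red, length, 1L))
  st <- unlist(lapply(red, IRanges::start), use.names = FALSE) - 1L
  en <- unlist(lapply(red, IRanges::end), use.names = FALSE)
  peak_set(chrom, st, en, set_name = attr(ps, "set_name"),
           genome_length = attr(ps, "genome_length"))
}

# logical: does each interval of a overlap (>= 1 bp) any interval of b?
overlaps_any_peak <- function(a, b) {
  out <- logical(nrow(a))
  if (nrow(a) == 0L || nrow(b) == 0L) return(out)
  bspl <- split(seq_len(nrow(b)), b$chrom)
  aspl <- split(seq_len(nrow(a)), a$chrom)
  for (ch in names(aspl)) {
    ia <- aspl[[ch]]
    ib <- bspl[[ch]]
    if (is.null(ib)) next
    ira <- IRanges::IRanges(a$start[ia] + 1L, a$end[ia])
    irb <- IRanges::IRanges(b$start[ib] + 1L, b$end[ib])
    out[ia] <- IRanges::overlapsAny(ira, irb)
  }
  out
}

# total bases covered by a (merged) peak set
covered_bp <- function(ps) sum(as.numeric(ps$end - ps$start))

#' Construct a per-base Tn5 cut track
#'
#' @param counts named list of non-negative integer vectors, one per
#'   chromosome, giving Tn5 insertion counts per base.
#' @return A `cut_track` with elements `counts` and `library_size`.
#' @export
cut_track <- function(counts) {
  stopifnot(is.list(counts), !is.null(names(counts)))
  counts <- lapply(counts, function(x) {
    x <- as.numeric(x)
    if (any(x < 0)) stop("cut counts must be >= 0")
    x
  })
  structure(list(counts = counts,
                 library_size = sum(vapply(counts, sum, 0))),
            class = "cut_track")
}

#' @export
print.cut_track <- function(x, ...) {
  cat(sprintf("cut_track: %d chrom(s), %.0f bp, library size %.0f cuts\n",
              length(x$counts),
              sum(vapply(x$counts, length, 1L)), x$library_size))
  invisible(x)
}

#' Construct a paired-end fragment set
#'
#' Fragments are classified by length: nucleosome-free (< 100 bp),
#' mono-nucleosomal (150-250 bp), other. Class boundaries are arguments so
#' the partition stays configurable.
#'
#' @param chrom,start,end fragment coordinates (0-based half-open).
#' @param nfr_max,nuc_min,nuc_max length-class boundaries in bp.
#' @return A `fragment_set` data.frame with columns chrom, start, end,
#'   length, class.
#' @export
fragment_set <- function(chrom, start, end, nfr_max = 100L,
                         nuc_min = 150L, nuc_max = 250L) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) && any(start >= end)) stop("fragment start must be < end")
  len <- end - start
  cls <- ifelse(len < nfr_max, "nfr",
                ifelse(len >= nuc_min & len <= nuc_max, "nucleosomal",
                       "other"))
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   length = len, class = cls, stringsAsFactors = FALSE)
  structure(df, class = c("fragment_set", "data.frame"))
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("fragment_set: %d fragments (%d nfr, %d nucleosomal, %d other)\n",
              nrow(x), sum(x$class == "nfr"),
              sum(x$class == "nucleosomal"), sum(x$class == "other")))
  invisible(x)
}
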