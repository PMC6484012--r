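# Readers and writers for the external formats the pipeline touches.
# Everything is converted to the internal 0-based half-open convention at
# this boundary; malformed lines are rejected with a line number, never
# silently skipped.

.read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines[nzchar(lines)]
}

#' Read genomic intervals from BED6, narrowPeak or bedGraph
#'
#' @param path file path.
#' @param dialect one of "bed6" (3-6 columns), "narrowPeak" (10 columns,
#'   column 10 is the summit offset from start, -1 for none), "bedgraph"
#'   (4 columns, value attached as `score`).
#' @param set_name,genome_length passed to [peak_set()].
#' @return a [peak_set()], sorted by (chrom, start).
#' @export
read_intervals <- function(path, dialect = c("bed6", "narrowPeak", "bedgraph"),
                           set_name = basename(path),
                           genome_length = NA_real_) {
  dialect <- match.arg(dialect)
  lines <- .read_tsv_lines(path)
  if (length(lines) == 0L)
    return(peak_set(character(), integer(), integer(),
                    set_name = set_name, genome_length = genome_length))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- switch(dialect, bed6 = 3L, narrowPeak = 10L, bedgraph = 4L)
  nf <- lengths(fields)
  bad <- which(nf < ncol_min)
  if (length(bad))
    stop(sprintf("%s line %d: expected >= %d tab-separated columns, got %d",
                 dialect, bad[1], ncol_min, nf[bad[1]]))
  get <- function(i) vapply(fields, `[`, "", i)
  chrom <- get(1L)
  start <- suppressWarnings(as.integer(get(2L)))
  end <- suppressWarnings(as.integer(get(3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("%s line %d: non-integer coordinates", dialect, bad[1]))
  bad <- which(start >= end | start < 0L)
  if (length(bad))
    stop(sprintf("%s line %d: invalid interval [%d, %d)",
                 dialect, bad[1], start[bad[1]], end[bad[1]]))
  name <- NULL; score <- NULL; strand <- NULL; summit <- NULL
  if (dialect == "bed6") {
    if (all(nf >= 4L)) name <- get(4L)
    if (all(nf >= 5L)) score <- suppressWarnings(as.numeric(get(5L)))
    if (all(nf >= 6L)) {
      strand <- get(6L)
      bad <- which(!strand %in% c("+", "-", "."))
      if (length(bad))
        stop(sprintf("bed6 line %d: bad strand '%s'", bad[1], strand[bad[1]]))
    }
  } else if (dialect == "narrowPeak") {
    name <- get(4L)
    strand <- get(6L)
    score <- suppressWarnings(as.numeric(get(7L)))  # signalValue
    summit <- suppressWarnings(as.integer(get(10L)))
    bad <- which(is.na(summit))
    if (length(bad))
      stop(sprintf("narrowPeak line %d: non-integer summit", bad[1]))
    summit[summit < 0L] <- NA_integer_
  } else {
    score <- suppressWarnings(as.numeric(get(4L)))
    bad <- which(is.na(score))
    if (length(bad))
      stop(sprintf("bedgraph line %d: non-numeric value", bad[1]))
  }
  peak_set(chrom, start, end, strand = strand, score = score,
           summit_offset = summit, name = name,
           set_name = set_name, genome_length = genome_length)
}

#' Write a peak set to BED6, narrowPeak or bedGraph
#' @param ps a [peak_set()].
#' @param path output path.
#' @param dialect output format.
#' @export
write_intervals <- function(ps, path,
                            dialect = c("bed6", "narrowPeak", "bedgraph")) {
  dialect <- match.arg(dialect)
  nm <- ifelse(is.na(ps$name), ".", ps$name)
  sc <- ifelse(is.na(ps$score), 0, ps$score)
  out <- switch(dialect,
    bed6 = data.frame(ps$chrom, ps$start, ps$end, nm, sc, ps$strand),
    narrowPeak = data.frame(ps$chrom, ps$start, ps$end, nm, 0L, ps$strand,
                            sc, -1, -1,
                            ifelse(is.na(ps$summit_offset), -1L,
                                   ps$summit_offset)),
    bedgraph = data.frame(ps$chrom, ps$start, ps$end, sc))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a cut track as bedGraph (one line per run of equal counts)
#' @param track a [cut_track()].
#' @param path output path.
#' @param drop_zero omit zero-count runs (default TRUE).
#' @export
write_cut_track <- function(track, path, drop_zero = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$counts)) {
    x <- track$counts[[ch]]
    r <- rle(x)
    en <- cumsum(r$lengths)
    st <- en - r$lengths
    keep <- if (drop_zero) r$values != 0 else rep(TRUE, length(en))
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%g", ch, st[keep], en[keep],
                         r$values[keep]), con)
  }
  invisible(path)
}

#' Read a bedGraph into a cut track
#' @param path bedGraph path.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @export
read_cut_track <- function(path, chrom_lengths) {
  bg <- read_intervals(path, "bedgraph")
  counts <- lapply(chrom_lengths, function(L) numeric(L))
  for (i in seq_len(nrow(bg))) {
    ch <- bg$chrom[i]
    if (is.null(counts[[ch]])) stop("chrom not in chrom_lengths: ", ch)
    counts[[ch]][(bg$start[i] + 1L):bg$end[i]] <- bg$score[i]
  }
  cut_track(counts)
}

#' Read fragments from a 3-column TSV (chrom, start, end)
#' @param path TSV path (no header).
#' @param ... length-class boundaries passed to [fragment_set()].
#' @export
read_fragments <- function(path, ...) {
  lines <- .read_tsv_lines(path)
  if (!length(lines)) return(fragment_set(character(), integer(), integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) stop("fragment line ", bad[1], ": need 3 columns")
  fragment_set(vapply(fields, `[`, "", 1L),
               as.integer(vapply(fields, `[`, "", 2L)),
               as.integer(vapply(fields, `[`, "", 3L)), ...)
}

#' Write fragments as TSV (chrom, start, end, length)
#' @param frags a [fragment_set()].
#' @param path output path.
#' @export
write_fragments <- function(frags, path) {
  write.table(frags[, c("chrom", "start", "end", "length")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# ---- genome FASTA -----------------------------------------------------------

#' Read a genome FASTA into a named character vector of sequences
#' @param path FASTA path.
#' @return named character vector, alphabet restricted to ACGTN.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  g <- setNames(toupper(as.character(ss)),
                sub("\\s.*$", "", names(ss)))
  if (any(nchar(g) == 0L)) stop("empty sequence in FASTA")
  if (any(grepl("[^ACGTN]", g))) stop("genome alphabet must be ACGTN")
  g
}

#' Write a genome to FASTA
#' @param genome named character vector of sequences.
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# ---- PWMs -------------------------------------------------------------------

#' Construct a position weight matrix
#'
#' @param mat 4 x width matrix of per-column base probabilities, rows in
#'   A, C, G, T order. Columns must each sum to 1 (within 1e-9) and all
#'   entries must be strictly positive.
#' @param id,name identifiers.
#' @param background length-4 background frequencies (default uniform).
#' @export
pwm <- function(mat, id = "pwm", name = id,
                background = rep(0.25, 4)) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("PWM matrix must have 4 rows (A,C,G,T)")
  if (ncol(mat) < 1L) stop("PWM width must be >= 1")
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-9)) stop("PWM columns must sum to 1")
  if (any(mat <= 0)) stop("PWM entries must be > 0 (apply a pseudocount)")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  rownames(mat) <- c("A", "C", "G", "T")
  structure(list(id = id, name = name, matrix = unname(mat),
                 background = background, width = ncol(mat)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (%s), width %d\n", x$id, x$name, x$width))
  m <- round(x$matrix, 3); rownames(m) <- c("A", "C", "G", "T")
  print(m)
  invisible(x)
}

#' Read PWMs from JASPAR count-matrix text
#'
#' Parses the JASPAR 2016 text format: a `>ID NAME` header followed by four
#' rows `A [ 4 19 0 ... ]` (C, G, T). Counts are converted to column
#' probabilities after adding one total pseudocount per column, split by
#' the background frequencies.
#'
#' @param path file path.
#' @param background length-4 background for the pseudocount split and the
#'   stored background model (default uniform).
#' @param pseudocount_total total pseudocount added per column (default 1).
#' @return list of [pwm()] objects.
#' @export
read_pwm_jaspar <- function(path, background = rep(0.25, 4),
                            pseudocount_total = 1) {
  lines <- .read_tsv_lines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no '>' headers found in ", path)
  ends <- c(hdr[-1] - 1L, length(lines))
  out <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    block <- lines[hdr[i]:ends[i]]
    h <- sub("^>\\s*", "", block[1])
    toks <- strsplit(h, "[ \t]+")[[1]]
    id <- toks[1]
    name <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else toks[1]
    body <- block[-1]
    if (length(body) != 4L)
      stop("PWM record ", id, ": expected 4 count rows, got ", length(body))
    rows <- lapply(body, function(l) {
      nums <- regmatches(l, gregexpr("-?[0-9]+\\.?[0-9]*", l))[[1]]
      # drop a leading base letter if the row starts with A/C/G/T
      as.numeric(nums)
    })
    # order rows by their base letter when present, else assume A,C,G,T
    letters_ <- toupper(sub("^\\s*([ACGTacgt]).*$", "\\1", body))
    if (all(letters_ %in% c("A", "C", "G", "T")) &&
        length(unique(letters_)) == 4L) {
      rows <- rows[match(c("A", "C", "G", "T"), letters_)]
    }
    w <- unique(lengths(rows))
    if (length(w) != 1L)
      stop("PWM record ", id, ": rows have unequal widths")
    cnt <- do.call(rbind, rows)
    if (any(cnt < 0)) stop("PWM record ", id, ": negative counts")
    pc <- matrix(background * pseudocount_total, nrow = 4, ncol = w)
    cnt <- cnt + pc
    prob <- sweep(cnt, 2, colSums(cnt), "/")
    out[[i]] <- pwm(prob, id = id, name = name, background = background)
  }
  out
}

#' Write PWMs in JASPAR-style count text (probabilities x 100)
#' @param pwms list of [pwm()].
#' @param path output path.
#' @export
write_pwm_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$id, p$name), con)
    for (b in 1:4) {
      writeLines(sprintf("%s [ %s ]", c("A", "C", "G", "T")[b],
                         paste(round(p$matrix[b, ] * 100, 2),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

# ---- typed tables -----------------------------------------------------------

.table_schemas <- list(
  tss = c("gene", "chrom", "tss", "strand"),
  deg = c("gene", "log2FC", "q"),
  geneset = c("set_name", "gene"),
  expression = c("gene", "fpkm")
)

#' Read a typed TSV table (TSS annotation, DEG, gene sets, expression)
#'
#' @param path TSV path with a header row.
#' @param schema one of "tss" (gene, chrom, tss, strand), "deg" (gene,
#'   log2FC, q), "geneset" (set_name, gene), "expression" (gene, fpkm).
#' @return typed data.frame. Duplicate (set_name, gene) pairs in gene-set
#'   tables are dropped with a warning.
#' @export
read_table_typed <- function(path, schema = c("tss", "deg", "geneset",
                                              "expression")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  req <- .table_schemas[[schema]]
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop(sprintf("table %s: schema '%s' requires column(s) %s",
                 basename(path), schema, paste(missing, collapse = ", ")))
  if (schema == "tss") {
    df$tss <- as.integer(df$tss)
    if (nrow(df) && any(!df$strand %in% c("+", "-")))
      stop("tss table: strand must be + or -")
  } else if (schema == "deg") {
    df$log2FC <- as.numeric(df$log2FC)
    df$q <- as.numeric(df$q)
  } else if (schema == "geneset") {
    dup <- duplicated(df[, c("set_name", "gene")])
    if (any(dup)) {
      warning(sum(dup), " duplicate (set_name, gene) pairs deduplicated")
      df <- df[!dup, , drop = FALSE]
    }
  } else if (schema == "expression") {
    df$fpkm <- as.numeric(df$fpkm)
  }
  rownames(df) <- NULL
  df
}
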