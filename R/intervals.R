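# Interval algebra and overlap statistics: Jaccard index, summit-confocal
# co-occurrence with a hypergeometric test, genomic-feature enrichment,
# nearest-TSS annotation, and control-vs-knockout region loss.

#' Jaccard index between two peak sets
#'
#' In `bp` mode the index is intersected bases over union bases. In `count`
#' mode the two sets are pooled and merged into union regions; the index is
#' the fraction of union regions that overlap peaks of both input sets
#' (the number of peaks that overlap between the two files, divided by the
#' union of the two files), so each union region is counted once. Both
#' modes are symmetric in A and B.
#'
#' @param A,B [peak_set()] objects; internally-overlapping intervals are
#'   merged first.
#' @param mode "bp" or "count".
#' @return numeric in `[0, 1]`; 0 with a warning when the union is empty.
#' @export
jaccard <- function(A, B, mode = c("bp", "count")) {
  mode <- match.arg(mode)
  A <- merge_peaks(A); B <- merge_peaks(B)
  if (nrow(A) + nrow(B) == 0L) {
    warning("empty union of peak sets; Jaccard undefined, returning 0")
    return(0)
  }
  U <- merge_peaks(peak_set(c(A$chrom, B$chrom), c(A$start, B$start),
                            c(A$end, B$end), set_name = "union"))
  if (mode == "bp") {
    inter <- 0
    aspl <- split(seq_len(nrow(A)), A$chrom)
    bspl <- split(seq_len(nrow(B)), B$chrom)
    for (ch in intersect(names(aspl), names(bspl))) {
      ia <- aspl[[ch]]; ib <- bspl[[ch]]
      ira <- IRanges::IRanges(A$start[ia] + 1L, A$end[ia])
      irb <- IRanges::IRanges(B$start[ib] + 1L, B$end[ib])
      inter <- inter + sum(IRanges::width(IRanges::intersect(ira, irb)))
    }
    inter / covered_bp(U)
  } else {
    both <- overlaps_any_peak(U, A) & overlaps_any_peak(U, B)
    sum(both) / nrow(U)
  }
}

#' Summit-confocal co-occurrence with a hypergeometric test
#'
#' Tests whether peaks of A co-occur with peaks of B over a universe of
#' candidate regions (by default the merged open-chromatin regions of the
#' matching timepoint). A universe region is "confocal" with a summit when
#' that summit falls inside the window of `confocal_window` bp centered on
#' the region midpoint. Counting k = regions confocal with both an A and a
#' B summit whose summits lie within `max_summit_dist` bp of each other,
#' n = regions confocal with A, K = regions confocal with B, N = all
#' regions, the natural log of the upper hypergeometric tail
#' P(X >= k) is returned.
#'
#' @param A,B [peak_set()] objects with summits.
#' @param universe [peak_set()] of candidate regions.
#' @param max_summit_dist maximum A-to-B summit distance in bp for
#'   co-localization (default 20).
#' @param confocal_window window size in bp centered on each universe
#'   region midpoint (default 3000).
#' @return list with k, n, K, N, ln_p.
#' @export
cooccurrence_test <- function(A, B, universe, max_summit_dist = 20L,
                              confocal_window = 3000L) {
  if (nrow(universe) == 0L) stop("empty universe")
  mids <- peak_summits(universe)
  half <- confocal_window / 2
  sa <- peak_summits(A); sb <- peak_summits(B)
  N <- nrow(universe)
  in_window <- function(summits, schrom) {
    # for each universe region, the summits (indices) inside its window
    lapply(seq_len(N), function(i) {
      j <- which(schrom == universe$chrom[i] &
                   abs(summits - mids[i]) <= half)
      j
    })
  }
  wa <- in_window(sa, A$chrom)
  wb <- in_window(sb, B$chrom)
  matched_a <- lengths(wa) > 0L
  matched_b <- lengths(wb) > 0L
  both <- vapply(seq_len(N), function(i) {
    if (!matched_a[i] || !matched_b[i]) return(FALSE)
    d <- outer(sa[wa[[i]]], sb[wb[[i]]], function(x, y) abs(x - y))
    any(d <= max_summit_dist)
  }, logical(1))
  K <- sum(matched_b); n <- sum(matched_a); k <- sum(both)
  ln_p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  list(k = k, n = n, K = K, N = N, ln_p = ln_p)
}

#' Build a genomic feature annotation
#'
#' Resolves overlapping category intervals by precedence
#' promoter > 5UTR > 3UTR > exon > intron > ncRNA; any base not covered is
#' intergenic. Genome fractions are computed from the resolved coverage.
#'
#' @param category_intervals named list of [peak_set()] objects keyed by
#'   category (subset of promoter, 5UTR, 3UTR, exon, intron, ncRNA).
#' @param genome_length total genome length in bp.
#' @return a `feature_annotation`: list of resolved peak sets plus genome
#'   fractions (including intergenic).
#' @export
feature_annotation <- function(category_intervals, genome_length) {
  precedence <- c("promoter", "5UTR", "3UTR", "exon", "intron", "ncRNA")
  unknown <- setdiff(names(category_intervals), precedence)
  if (length(unknown)) stop("unknown categories: ",
                            paste(unknown, collapse = ", "))
  resolved <- list()
  claimed <- NULL  # peak_set of already-claimed bases
  for (cat in precedence) {
    ps <- category_intervals[[cat]]
    if (is.null(ps) || nrow(ps) == 0L) next
    ps <- merge_peaks(ps)
    if (!is.null(claimed) && nrow(claimed) > 0L) {
      ps <- setdiff_peaks(ps, claimed)
    }
    resolved[[cat]] <- ps
    claimed <- if (is.null(claimed)) ps else
      merge_peaks(peak_set(c(claimed$chrom, ps$chrom),
                           c(claimed$start, ps$start),
                           c(claimed$end, ps$end)))
  }
  fracs <- vapply(resolved, function(p) covered_bp(p) / genome_length, 0)
  fracs <- c(fracs, intergenic = max(0, 1 - sum(fracs)))
  structure(list(categories = resolved, genome_fractions = fracs,
                 genome_length = genome_length),
            class = "feature_annotation")
}

# base-level set difference a \ b
setdiff_peaks <- function(a, b) {
  aspl <- split(seq_len(nrow(a)), a$chrom)
  bspl <- split(seq_len(nrow(b)), b$chrom)
  chroms <- names(aspl)
  res_ch <- character(); res_st <- integer(); res_en <- integer()
  for (ch in chroms) {
    ia <- aspl[[ch]]
    ira <- IRanges::IRanges(a$start[ia] + 1L, a$end[ia])
    ib <- bspl[[ch]]
    d <- if (is.null(ib)) ira else
      IRanges::setdiff(ira, IRanges::IRanges(b$start[ib] + 1L, b$end[ib]))
    if (length(d)) {
      res_ch <- c(res_ch, rep(ch, length(d)))
      res_st <- c(res_st, IRanges::start(d) - 1L)
      res_en <- c(res_en, IRanges::end(d))
    }
  }
  peak_set(res_ch, res_st, res_en, set_name = attr(a, "set_name"),
           genome_length = attr(a, "genome_length"))
}

#' Per-category log2 fold enrichment of peaks over genomic features
#'
#' Each peak is assigned to exactly one category by its summit (midpoint if
#' no summit is recorded); enrichment per category is
#' log2((peak fraction + eps) / (genome fraction + eps)).
#'
#' @param peaks a [peak_set()].
#' @param ann a [feature_annotation()].
#' @param eps numeric stabilizer (default 1e-9).
#' @return data.frame with category, n_peaks, peak_fraction,
#'   genome_fraction, log2FE (NA where the genome fraction is zero).
#' @export
feature_enrichment <- function(peaks, ann, eps = 1e-9) {
  if (nrow(peaks) == 0L) stop("empty peak set")
  s <- peak_summits(peaks)
  pts <- peak_set(peaks$chrom, s, s + 1L)
  cats <- c(names(ann$categories), "intergenic")
  assigned <- rep("intergenic", nrow(pts))
  for (cat in names(ann$categories)) {
    hit <- overlaps_any_peak(pts, ann$categories[[cat]])
    assigned[hit & assigned == "intergenic"] <- cat
  }
  n <- vapply(cats, function(cc) sum(assigned == cc), 0)
  pf <- n / nrow(peaks)
  gf <- ann$genome_fractions[cats]
  log2FE <- ifelse(gf == 0 & cats != "intergenic", NA_real_,
                   log2((pf + eps) / (gf + eps)))
  data.frame(category = cats, n_peaks = as.integer(n), peak_fraction = pf,
             genome_fraction = as.numeric(gf), log2FE = log2FE,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assign each peak to its nearest transcription start site
#'
#' Distance is measured summit-to-TSS and signed relative to the gene's
#' strand: negative when the summit lies upstream (5') of the gene. Ties
#' are broken by the lexicographically smaller gene name.
#'
#' @param peaks a [peak_set()].
#' @param tss_table data.frame with columns gene, chrom, tss, strand
#'   (see [read_table_typed()]).
#' @return data.frame: peak index, chrom, summit, gene, distance. Peaks on
#'   chromosomes absent from the TSS table get NA with a warning.
#' @export
nearest_tss <- function(peaks, tss_table) {
  if (nrow(tss_table) == 0L) stop("empty TSS table")
  s <- peak_summits(peaks)
  gene <- rep(NA_character_, nrow(peaks))
  dist <- rep(NA_real_, nrow(peaks))
  tspl <- split(seq_len(nrow(tss_table)), tss_table$chrom)
  n_missing <- 0L
  for (i in seq_len(nrow(peaks))) {
    j <- tspl[[peaks$chrom[i]]]
    if (is.null(j)) { n_missing <- n_missing + 1L; next }
    d_abs <- abs(tss_table$tss[j] - s[i])
    cand <- j[d_abs == min(d_abs)]
    if (length(cand) > 1L)
      cand <- cand[order(tss_table$gene[cand])][1L]
    gene[i] <- tss_table$gene[cand]
    raw <- s[i] - tss_table$tss[cand]
    dist[i] <- if (tss_table$strand[cand] == "+") raw else -raw
  }
  if (n_missing > 0L)
    warning(n_missing, " peak(s) on chromosomes absent from the TSS table")
  data.frame(peak = seq_len(nrow(peaks)), chrom = peaks$chrom, summit = s,
             gene = gene, distance = dist, stringsAsFactors = FALSE)
}

#' Fraction of control regions lost in a perturbed condition
#'
#' A control region is lost when it overlaps no perturbed region by at
#' least 1 bp ("overlap" mode), or when its perturbed coverage drops below
#' `coverage_ratio` times its control coverage ("coverage" mode, which
#' requires per-condition cut tracks).
#'
#' @param control,perturbed merged [peak_set()] objects.
#' @param mode "overlap" (default) or "coverage".
#' @param control_track,perturbed_track [cut_track()] objects, needed for
#'   coverage mode; both are library-size normalized before comparison.
#' @param coverage_ratio loss threshold for coverage mode (default 0.5).
#' @return list with lost_fraction, retained and lost peak sets.
#' @export
region_loss <- function(control, perturbed, mode = c("overlap", "coverage"),
                        control_track = NULL, perturbed_track = NULL,
                        coverage_ratio = 0.5) {
  mode <- match.arg(mode)
  if (nrow(control) == 0L) stop("empty control peak set")
  control <- merge_peaks(control); perturbed <- merge_peaks(perturbed)
  if (mode == "overlap") {
    kept <- overlaps_any_peak(control, perturbed)
  } else {
    if (is.null(control_track) || is.null(perturbed_track))
      stop("coverage mode requires control_track and perturbed_track")
    sc <- 1e6 / max(control_track$library_size, 1)
    sp <- 1e6 / max(perturbed_track$library_size, 1)
    kept <- vapply(seq_len(nrow(control)), function(i) {
      ch <- control$chrom[i]
      idx <- (control$start[i] + 1L):control$end[i]
      cc <- sum(control_track$counts[[ch]][idx]) * sc
      pc <- sum(perturbed_track$counts[[ch]][idx]) * sp
      pc >= coverage_ratio * cc
    }, logical(1))
  }
  list(lost_fraction = mean(!kept),
       retained = control[kept, ],
       lost = control[!kept, ])
}
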