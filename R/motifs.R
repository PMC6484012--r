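# PWM machinery: log-odds scanning with p-values from the exact score
# distribution, cor/ncor similarity, average-linkage clustering under dual
# thresholds, and known-motif binomial enrichment with randomization FDR.

.BASE_CODE <- {
  v <- rep(NA_integer_, 256)
  v[utf8ToInt("A")] <- 1L; v[utf8ToInt("C")] <- 2L
  v[utf8ToInt("G")] <- 3L; v[utf8ToInt("T")] <- 4L
  v[utf8ToInt("a")] <- 1L; v[utf8ToInt("c")] <- 2L
  v[utf8ToInt("g")] <- 3L; v[utf8ToInt("t")] <- 4L
  v
}

seq_codes <- function(s) .BASE_CODE[utf8ToInt(s)]

# log2-odds matrix of a pwm (4 x width)
pwm_logodds <- function(p) log2(p$matrix / p$background)

# reverse complement of a pwm: reverse columns, swap A<->T and C<->G
pwm_revcomp <- function(p) {
  m <- p$matrix[c(4L, 3L, 2L, 1L), rev(seq_len(p$width)), drop = FALSE]
  pwm(m, id = p$id, name = p$name, background = p$background[c(4, 3, 2, 1)])
}

#' Exact distribution of PWM log-odds scores under the background model
#'
#' Computes the full probability distribution of the log-odds score of a
#' random word drawn from the PWM's background, by dynamic programming
#' over columns. Distinct partial sums are kept exactly (merged at 1e-9
#' resolution), which is feasible for the motif widths in practice.
#'
#' @param p a [pwm()].
#' @return list with sorted unique `score` values, their probabilities
#'   `prob`, and `pvalue(s)` giving P(score >= s).
#' @export
pwm_score_distribution <- function(p) {
  lo <- pwm_logodds(p)
  bg <- p$background
  sums <- 0; probs <- 1
  for (j in seq_len(p$width)) {
    ns <- as.vector(outer(lo[, j], sums, `+`))
    np <- as.vector(outer(bg, probs, `*`))
    key <- round(ns, 9)
    agg <- rowsum(np, group = key)
    sums <- as.numeric(rownames(agg))
    probs <- as.vector(agg)
    o <- order(sums)
    sums <- sums[o]; probs <- probs[o]
  }
  tail_p <- rev(cumsum(rev(probs)))
  # the boundary guard absorbs the per-column rounding drift so a query
  # exactly at a score level includes that level's mass
  pvalue <- function(s) {
    i <- findInterval(s - 1e-6, sums) + 1L
    ifelse(i > length(sums), 0, tail_p[pmin(i, length(sums))])
  }
  list(score = sums, prob = probs, pvalue = pvalue)
}

# smallest score whose tail p-value is <= alpha (Inf if none)
pwm_score_cutoff <- function(p, alpha) {
  d <- pwm_score_distribution(p)
  tail_p <- rev(cumsum(rev(d$prob)))
  ok <- which(tail_p <= alpha + 1e-15)
  if (!length(ok)) Inf else d$score[ok[1]]
}

# raw per-position scores of a pwm over an integer-coded sequence
# (NA where the window contains N)
.scores_along <- function(codes, lo) {
  w <- ncol(lo)
  L <- length(codes)
  if (L < w) return(numeric(0))
  n <- L - w + 1L
  s <- lo[codes[seq_len(n)], 1L]
  if (w > 1L) for (j in 2:w) s <- s + lo[codes[seq_len(n) + (j - 1L)], j]
  s
}

#' Scan sequences for PWM matches
#'
#' Scores every window of each sequence on both strands with the log-odds
#' score sum(log2(p_j(base)/bg(base))) and reports windows whose score
#' passes the threshold. The threshold is either a p-value under the exact
#' background score distribution or a raw score. Windows containing N are
#' skipped.
#'
#' @param genome named character vector of sequences (or a single string).
#' @param p a [pwm()].
#' @param pvalue match threshold as p-value (default 1e-4); ignored when
#'   `score_min` is given.
#' @param score_min raw score threshold in bits (overrides `pvalue`).
#' @param regions optional [peak_set()]; only these windows are scanned
#'   and reported coordinates stay genomic.
#' @return data.frame: chrom, start, end, strand, pwm_id, score, p_value.
#' @export
scan_pwm <- function(genome, p, pvalue = 1e-4, score_min = NULL,
                     regions = NULL) {
  if (is.null(names(genome)) && length(genome) == 1L)
    names(genome) <- "seq1"
  dist <- pwm_score_distribution(p)
  thr <- if (!is.null(score_min)) score_min else {
    tail_p <- rev(cumsum(rev(dist$prob)))
    ok <- which(tail_p <= pvalue + 1e-15)
    if (!length(ok)) Inf else dist$score[ok[1]]
  }
  lo_f <- pwm_logodds(p)
  lo_r <- pwm_logodds(pwm_revcomp(p))
  w <- p$width
  res <- list()
  emit <- function(chrom, offset0, codes) {
    if (length(codes) < w) {
      warning("sequence shorter than PWM width; skipped")
      return(NULL)
    }
    for (strand in c("+", "-")) {
      lo <- if (strand == "+") lo_f else lo_r
      s <- .scores_along(codes, lo)
      hit <- which(!is.na(s) & s >= thr)
      if (length(hit))
        res[[length(res) + 1L]] <<- data.frame(
          chrom = chrom, start = offset0 + hit - 1L,
          end = offset0 + hit - 1L + w, strand = strand,
          pwm_id = p$id, score = s[hit],
          p_value = dist$pvalue(s[hit]), stringsAsFactors = FALSE)
    }
  }
  if (is.null(regions)) {
    for (ch in names(genome)) emit(ch, 0L, seq_codes(genome[[ch]]))
  } else {
    for (i in seq_len(nrow(regions))) {
      ch <- regions$chrom[i]
      if (!ch %in% names(genome)) stop("region chrom not in genome: ", ch)
      sub <- substr(genome[[ch]], regions$start[i] + 1L, regions$end[i])
      emit(ch, regions$start[i], seq_codes(sub))
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      pwm_id = character(), score = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best ungapped alignment similarity between two PWMs (cor / ncor)
#'
#' Slides p2 against p1 over all ungapped offsets (both orientations of
#' p2) with at least `min_overlap` aligned columns. At each offset the
#' Pearson correlation of the flattened 4 x aligned_width probability
#' cells is computed ("cor"; defined as 0 when either side has zero
#' variance); "ncor" scales cor by aligned_width over the union width
#' spanned by both matrices at that offset. The offset maximizing ncor is
#' returned.
#'
#' @param p1,p2 [pwm()] objects.
#' @param min_overlap minimum aligned columns (default 5).
#' @return list: cor, ncor, offset (of p2's first column relative to
#'   p1's), strand ("+" or "-"), aligned_width.
#' @export
pwm_similarity <- function(p1, p2, min_overlap = 5L) {
  if (min(p1$width, p2$width) < min_overlap)
    stop("matrices too short for min_overlap = ", min_overlap)
  best <- NULL
  for (strand in c("+", "-")) {
    m2 <- if (strand == "+") p2$matrix else pwm_revcomp(p2)$matrix
    w1 <- p1$width; w2 <- ncol(m2)
    for (o in seq(-(w2 - min_overlap), w1 - min_overlap)) {
      a1 <- max(0L, o); b1 <- min(w1, o + w2)
      aw <- b1 - a1
      if (aw < min_overlap) next
      cols1 <- (a1 + 1L):b1
      cols2 <- (a1 - o + 1L):(b1 - o)
      x <- as.vector(p1$matrix[, cols1])
      y <- as.vector(m2[, cols2])
      cc <- if (sd(x) == 0 || sd(y) == 0) 0 else cor(x, y)
      uw <- max(w1, o + w2) - min(0L, o)
      nc <- cc * aw / uw
      cand <- list(cor = cc, ncor = nc, offset = o, strand = strand,
                   aligned_width = aw)
      if (is.null(best) || nc > best$ncor + 1e-12 ||
          (abs(nc - best$ncor) <= 1e-12 && cc > best$cor + 1e-12))
        best <- cand
    }
  }
  best
}

#' Cluster PWMs by average-linkage agglomeration under dual thresholds
#'
#' Pairwise similarities come from [pwm_similarity()]. Clusters are merged
#' greedily: at each step the pair of clusters with the highest average
#' ncor is merged, provided the pair's average cor >= `cor_thr` AND
#' average ncor >= `ncor_thr`; merging stops when no pair qualifies.
#' The clustering distance is d = 1 - ncor.
#'
#' @param pwms list of [pwm()] (length >= 2).
#' @param cor_thr,ncor_thr merge gates (defaults 0.6 and 0.4).
#' @param min_overlap minimum aligned columns for similarity (default 5).
#' @return list: `membership` (integer cluster id per input PWM),
#'   `merges` data.frame (cluster a, cluster b, avg_cor, avg_ncor,
#'   height = 1 - avg_ncor), `cor`/`ncor` pairwise matrices.
#' @export
cluster_pwms <- function(pwms, cor_thr = 0.6, ncor_thr = 0.4,
                         min_overlap = 5L) {
  n <- length(pwms)
  if (n < 2L) stop("need >= 2 PWMs")
  CM <- diag(1, n); NM <- diag(1, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- pwm_similarity(pwms[[i]], pwms[[j]], min_overlap)
    CM[i, j] <- CM[j, i] <- s$cor
    NM[i, j] <- NM[j, i] <- s$ncor
  }
  clusters <- as.list(seq_len(n))
  merges <- list()
  repeat {
    k <- length(clusters)
    if (k < 2L) break
    best <- NULL
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      ia <- clusters[[a]]; ib <- clusters[[b]]
      ac <- mean(CM[ia, ib]); an <- mean(NM[ia, ib])
      if (ac >= cor_thr && an >= ncor_thr &&
          (is.null(best) || an > best$an))
        best <- list(a = a, b = b, ac = ac, an = an)
    }
    if (is.null(best)) break
    merges[[length(merges) + 1L]] <-
      data.frame(a = paste(clusters[[best$a]], collapse = ","),
                 b = paste(clusters[[best$b]], collapse = ","),
                 avg_cor = best$ac, avg_ncor = best$an,
                 height = 1 - best$an, stringsAsFactors = FALSE)
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    clusters[[best$b]] <- NULL
  }
  membership <- integer(n)
  for (ci in seq_along(clusters)) membership[clusters[[ci]]] <- ci
  list(membership = membership,
       merges = if (length(merges)) do.call(rbind, merges) else
         data.frame(a = character(), b = character(), avg_cor = numeric(),
                    avg_ncor = numeric(), height = numeric()),
       cor = CM, ncor = NM)
}

# does a sequence contain >= 1 match on either strand at the score cutoff?
.has_match <- function(codes, lo_f, lo_r, thr) {
  s <- .scores_along(codes, lo_f)
  if (any(!is.na(s) & s >= thr)) return(TRUE)
  s <- .scores_along(codes, lo_r)
  any(!is.na(s) & s >= thr)
}

#' Known-motif enrichment by the cumulative binomial distribution
#'
#' For each PWM, counts the foreground regions containing at least one
#' match and compares against the per-region match rate in a background
#' whose regions are length-matched to the foreground by resampling (a
#' random subsequence of the foreground length is drawn from a random
#' background region, preserving the background's empirical word content).
#' The enrichment p-value is the upper binomial tail
#' P(X >= k_fg), X ~ Binomial(n_fg, p0_bg).
#'
#' @param fg,bg [peak_set()] of foreground / background regions.
#' @param fg_genome,bg_genome named character vectors of sequences.
#' @param pwms list of [pwm()].
#' @param pvalue per-position match threshold (default 1e-4).
#' @param resample_bg length-match the background by resampling (default
#'   TRUE); set FALSE to use the background regions exactly as given
#'   (appropriate when they are already length-matched).
#' @return data.frame sorted by ascending p: pwm_id, name, k_fg, n_fg,
#'   p0_bg, cum_binom_p, fg_pct, bg_pct, p0_floor (TRUE when p0 was
#'   floored at 1/(n_bg+1) because no background region matched).
#' @export
binomial_enrichment <- function(fg, fg_genome, bg, bg_genome, pwms,
                                pvalue = 1e-4, resample_bg = TRUE) {
  if (nrow(fg) == 0L || nrow(bg) == 0L)
    stop("foreground and background must be nonempty")
  fg_seq <- vapply(seq_len(nrow(fg)), function(i)
    substr(fg_genome[[fg$chrom[i]]], fg$start[i] + 1L, fg$end[i]), "")
  bg_seq_full <- vapply(seq_len(nrow(bg)), function(i)
    substr(bg_genome[[bg$chrom[i]]], bg$start[i] + 1L, bg$end[i]), "")
  if (resample_bg) {
    # length-matched background resample
    pick <- sample.int(length(bg_seq_full), length(fg_seq), replace = TRUE)
    bg_seq <- vapply(seq_along(fg_seq), function(i) {
      s <- bg_seq_full[pick[i]]
      L <- nchar(s); want <- nchar(fg_seq[i])
      if (L <= want) s else {
        st <- sample.int(L - want + 1L, 1L)
        substr(s, st, st + want - 1L)
      }
    }, "")
  } else {
    bg_seq <- bg_seq_full
  }
  fg_codes <- lapply(fg_seq, seq_codes)
  bg_codes <- lapply(bg_seq, seq_codes)
  n_fg <- length(fg_codes); n_bg <- length(bg_codes)
  rows <- lapply(pwms, function(p) {
    thr <- pwm_score_cutoff(p, pvalue)
    lo_f <- pwm_logodds(p); lo_r <- pwm_logodds(pwm_revcomp(p))
    k_fg <- sum(vapply(fg_codes, .has_match, logical(1), lo_f, lo_r, thr))
    k_bg <- sum(vapply(bg_codes, .has_match, logical(1), lo_f, lo_r, thr))
    p0 <- k_bg / n_bg
    floored <- FALSE
    if (p0 == 0 && k_fg > 0) { p0 <- 1 / (n_bg + 1); floored <- TRUE }
    pp <- if (k_fg == 0) 1 else pbinom(k_fg - 1, n_fg, p0,
                                       lower.tail = FALSE)
    data.frame(pwm_id = p$id, name = p$name, k_fg = k_fg, n_fg = n_fg,
               p0_bg = p0, cum_binom_p = pp,
               fg_pct = 100 * k_fg / n_fg, bg_pct = 100 * k_bg / n_bg,
               p0_floor = floored, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cum_binom_p, out$pwm_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# shuffle a PWM's columns (randomization unit for empirical FDR)
pwm_shuffle_columns <- function(p) {
  perm <- sample.int(p$width)
  pwm(p$matrix[, perm, drop = FALSE], id = p$id, name = p$name,
      background = p$background)
}

#' Empirical FDR for motif enrichment by PWM column shuffling
#'
#' Reruns [binomial_enrichment()] with every PWM's columns shuffled,
#' `n_randomizations` times; for each reported motif the FDR estimate is
#' the mean count of randomized motifs at or below its p-value divided by
#' the count of observed motifs at or below it. Only the `top_n` observed
#' motifs are reported.
#'
#' @param fg,fg_genome,bg,bg_genome,pwms,pvalue as in
#'   [binomial_enrichment()].
#' @param n_randomizations number of shuffle rounds (default 2).
#' @param top_n motifs reported (default 20).
#' @return the observed enrichment table (top_n rows) with an `fdr`
#'   column appended.
#' @export
enrichment_fdr <- function(fg, fg_genome, bg, bg_genome, pwms,
                           pvalue = 1e-4, n_randomizations = 2L,
                           top_n = 20L) {
  if (n_randomizations < 1L) stop("n_randomizations must be >= 1")
  obs <- binomial_enrichment(fg, fg_genome, bg, bg_genome, pwms, pvalue)
  rand_counts <- matrix(0, nrow = nrow(obs), ncol = n_randomizations)
  for (r in seq_len(n_randomizations)) {
    shuf <- lapply(pwms, pwm_shuffle_columns)
    rnd <- binomial_enrichment(fg, fg_genome, bg, bg_genome, shuf, pvalue)
    rand_counts[, r] <- vapply(obs$cum_binom_p,
                               function(p) sum(rnd$cum_binom_p <= p), 0)
  }
  obs_counts <- vapply(obs$cum_binom_p,
                       function(p) sum(obs$cum_binom_p <= p), 0)
  obs$fdr <- pmin(1, rowMeans(rand_counts) / obs_counts)
  head(obs, top_n)
}
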