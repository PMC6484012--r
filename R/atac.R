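# The ATAC signal layer: fragment-to-cut conversion, simplified
# Poisson open-region calling with local lambda, footprint detection and
# scoring, control-vs-knockout footprint comparison, nucleosome occupancy,
# meta-profiles, replicate-consistent high-confidence peaks, and
# NFR-nucleosome pairing.

#' Convert paired-end fragments to a per-base Tn5 cut track
#'
#' Each fragment contributes two cuts, one at the 5' base of each end.
#' With offset correction the plus-end cut is shifted +4 bp and the
#' minus-end cut -5 bp (the Tn5 dimer insertion geometry).
#'
#' @param frags a [fragment_set()].
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param offset_correction apply the +4/-5 shift (default TRUE).
#' @return a [cut_track()]. Cuts shifted out of bounds are clipped with a
#'   warning.
#' @export
cuts_from_fragments <- function(frags, chrom_lengths,
                                offset_correction = TRUE) {
  counts <- lapply(chrom_lengths, function(L) numeric(L))
  clipped <- 0L
  for (ch in unique(frags$chrom)) {
    if (!ch %in% names(chrom_lengths))
      stop("fragment chrom not in chrom_lengths: ", ch)
    sel <- frags$chrom == ch
    plus_cut <- frags$start[sel]
    minus_cut <- frags$end[sel] - 1L
    if (offset_correction) {
      plus_cut <- plus_cut + 4L
      minus_cut <- minus_cut - 5L
    }
    pos <- c(plus_cut, minus_cut)
    L <- chrom_lengths[[ch]]
    ok <- pos >= 0L & pos < L
    clipped <- clipped + sum(!ok)
    tab <- tabulate(pos[ok] + 1L, nbins = L)
    counts[[ch]] <- counts[[ch]] + tab
  }
  if (clipped > 0L)
    warning(clipped, " cut(s) fell out of bounds after offset and were clipped")
  cut_track(counts)
}

# rolling window sums via cumsum; returns sums of x over windows of size w
# starting at 1..(length(x)-w+1)
.window_sums <- function(x, w) {
  cs <- c(0, cumsum(x))
  cs[(w + 1L):length(cs)] - cs[1L:(length(cs) - w)]
}

#' Call open-chromatin regions from a cut track (simplified Poisson caller)
#'
#' Sliding windows are tested against a Poisson null whose rate is the
#' maximum of the genome-wide rate and local rates estimated in windows
#' around each position (the test window itself is excluded from the
#' local estimate so a peak cannot mask itself), scaled to the test
#' window. Significant windows passing the fold-enrichment gate are
#' merged; the summit is the maximum-count base of the merged region.
#' The default local window is 10 kb; a 1 kb window is only useful when
#' the track is an input/control, since in a treatment track any region
#' wider than the test window leaks into it.
#'
#' @param cuts a [cut_track()].
#' @param window test window in bp (default 300).
#' @param step window step in bp (default 50).
#' @param local_lambda_windows local background window sizes (default
#'   10000).
#' @param p_threshold Poisson p-value threshold (default 1e-4).
#' @param min_fold minimum fold enrichment over the null rate (default 4).
#' @return a [peak_set()] with summit offsets; `score` holds the fold
#'   enrichment at the summit window.
#' @export
call_open_regions <- function(cuts, window = 300L, step = 50L,
                              local_lambda_windows = 10000L,
                              p_threshold = 1e-4, min_fold = 4) {
  if (cuts$library_size <= 0)
    return(peak_set(character(), integer(), integer(),
                    set_name = "open_regions"))
  genome_bp <- sum(vapply(cuts$counts, length, 1L))
  rate_global <- cuts$library_size / genome_bp
  res_ch <- character(); res_st <- integer(); res_en <- integer()
  res_sm <- integer(); res_fe <- numeric()
  for (ch in names(cuts$counts)) {
    x <- cuts$counts[[ch]]
    L <- length(x)
    if (L < window) next
    starts <- seq(1L, L - window + 1L, by = step)
    ws <- .window_sums(x, window)[starts]
    lam <- rep(rate_global * window, length(starts))
    centers <- starts + window %/% 2L
    cs <- c(0, cumsum(x))
    win_cnt <- cs[pmin(L, starts + window - 1L) + 1L] - cs[starts]
    for (lw in local_lambda_windows) {
      half <- lw %/% 2L
      lo <- pmax(1L, centers - half)
      hi <- pmin(L, centers + half)
      len <- (hi - lo + 1L) - window
      loc <- (cs[hi + 1L] - cs[lo] - win_cnt) / pmax(len, 1L) * window
      lam <- pmax(lam, loc)
    }
    pv <- ppois(ws - 1, lam, lower.tail = FALSE)
    fe <- ws / lam
    sig <- which(pv <= p_threshold & fe >= min_fold)
    if (!length(sig)) next
    # merge overlapping/adjacent significant windows
    sw_start <- starts[sig] - 1L          # back to 0-based
    sw_end <- sw_start + window
    ir <- IRanges::reduce(IRanges::IRanges(sw_start + 1L, sw_end))
    for (k in seq_along(ir)) {
      st <- IRanges::start(ir)[k] - 1L
      en <- IRanges::end(ir)[k]
      seg <- x[(st + 1L):en]
      summit <- which.max(seg) - 1L
      # fold enrichment of the best window inside the region
      in_reg <- sig[sw_start >= st & sw_end <= en]
      res_ch <- c(res_ch, ch); res_st <- c(res_st, st)
      res_en <- c(res_en, en); res_sm <- c(res_sm, summit)
      res_fe <- c(res_fe, max(fe[in_reg]))
    }
  }
  peak_set(res_ch, res_st, res_en, score = res_fe,
           summit_offset = res_sm, set_name = "open_regions",
           genome_length = genome_bp)
}

#' Detect transcription-factor footprints at candidate motif sites
#'
#' A footprint is focal depletion of Tn5 cuts over the motif span relative
#' to its flanks. For each site the score is
#' log2((mean flank cuts/bp + eps) / (mean center cuts/bp + eps)); the
#' depletion p-value is the lower binomial tail P(X <= x_center) with
#' X ~ Binomial(n_total, w_center / w_total) over the center-plus-flank
#' window, BH-adjusted across sites. A site is called a footprint when the
#' score, adjusted p and flank coverage all pass their thresholds; the
#' coverage requirement applies to each flank separately (half the
#' threshold per side), since a footprint is depletion between two
#' covered flanks - an asymmetric site at the edge of an accessible
#' region is a coverage boundary, not a footprint.
#'
#' @param cuts a [cut_track()].
#' @param sites data.frame of motif matches (chrom, start, end, pwm_id,
#'   strand), e.g. from [scan_pwm()].
#' @param flank flank width each side in bp (default 50).
#' @param min_flank_cuts minimum total flank cuts (default 10).
#' @param score_thr minimum depletion score (default 1.0).
#' @param q_thr BH-adjusted p-value threshold (default 0.05).
#' @param eps pseudo-cuts per bp in the log ratio (default 0.5).
#' @return data.frame, one row per scored site: site coordinates, pwm_id,
#'   center, score, depletion_p, q, flank_cuts, center_cuts, called.
#'   Sites too close to a chromosome edge are dropped; their count is in
#'   attribute `n_skipped`.
#' @export
detect_footprints <- function(cuts, sites, flank = 50L,
                              min_flank_cuts = 10L, score_thr = 1.0,
                              q_thr = 0.05, eps = 0.5) {
  n <- nrow(sites)
  keep <- logical(n)
  score <- numeric(n); pdep <- numeric(n)
  fl_cuts <- numeric(n); ce_cuts <- numeric(n)
  fl_min_side <- numeric(n)
  for (i in seq_len(n)) {
    ch <- sites$chrom[i]
    x <- cuts$counts[[ch]]
    if (is.null(x)) next
    st <- sites$start[i]; en <- sites$end[i]
    if (st - flank < 0L || en + flank > length(x)) next
    keep[i] <- TRUE
    ctr <- x[(st + 1L):en]
    left <- x[(st - flank + 1L):st]
    right <- x[(en + 1L):(en + flank)]
    fl <- c(left, right)
    wc <- length(ctr); wt <- wc + length(fl)
    ce_cuts[i] <- sum(ctr); fl_cuts[i] <- sum(fl)
    fl_min_side[i] <- min(sum(left), sum(right))
    score[i] <- log2((fl_cuts[i] / length(fl) + eps) /
                       (ce_cuts[i] / wc + eps))
    ntot <- ce_cuts[i] + fl_cuts[i]
    pdep[i] <- pbinom(ce_cuts[i], ntot, wc / wt)
  }
  n_skipped <- sum(!keep)
  idx <- which(keep)
  q <- p.adjust(pdep[idx], method = "BH")
  out <- data.frame(chrom = sites$chrom[idx], start = sites$start[idx],
                    end = sites$end[idx],
                    strand = if ("strand" %in% names(sites))
                      sites$strand[idx] else ".",
                    pwm_id = if ("pwm_id" %in% names(sites))
                      sites$pwm_id[idx] else NA_character_,
                    center = (sites$start[idx] + sites$end[idx]) %/% 2L,
                    score = score[idx], depletion_p = pdep[idx], q = q,
                    flank_cuts = fl_cuts[idx], center_cuts = ce_cuts[idx],
                    stringsAsFactors = FALSE)
  out$flank_cuts_min_side <- fl_min_side[idx]
  out$called <- out$score >= score_thr & out$q <= q_thr &
    out$flank_cuts >= min_flank_cuts &
    out$flank_cuts_min_side >= min_flank_cuts / 2
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Compare mean footprint scores between conditions (two-sample t test)
#'
#' @param fps_ctrl,fps_ko footprint tables from [detect_footprints()]
#'   (per-site scores computed over the center +/- flank window).
#' @return list: mean_ctrl, mean_ko, t, p (two-tailed Welch t).
#' @export
footprint_score_test <- function(fps_ctrl, fps_ko) {
  if (nrow(fps_ctrl) < 2L || nrow(fps_ko) < 2L)
    stop("need >= 2 scored sites in each condition")
  tt <- t.test(fps_ctrl$score, fps_ko$score)
  list(mean_ctrl = mean(fps_ctrl$score), mean_ko = mean(fps_ko$score),
       t = unname(tt$statistic), p = tt$p.value)
}

#' Fraction of control footprints lost in a perturbed condition
#'
#' A called control footprint is lost when no called perturbed footprint
#' for the same PWM lies within `match_dist` bp of its center.
#'
#' @param fps_ctrl,fps_ko footprint tables from [detect_footprints()];
#'   only rows with `called == TRUE` participate.
#' @param match_dist center-to-center matching distance (default 10).
#' @return lost fraction in `[0, 1]`.
#' @export
footprint_loss <- function(fps_ctrl, fps_ko, match_dist = 10L) {
  ctrl <- fps_ctrl[fps_ctrl$called, , drop = FALSE]
  ko <- fps_ko[fps_ko$called, , drop = FALSE]
  if (nrow(ctrl) == 0L) stop("no called control footprints")
  lost <- vapply(seq_len(nrow(ctrl)), function(i) {
    m <- ko$pwm_id == ctrl$pwm_id[i] & ko$chrom == ctrl$chrom[i] &
      abs(ko$center - ctrl$center[i]) <= match_dist
    !any(m)
  }, logical(1))
  mean(lost)
}

#' Nucleosome occupancy from nucleosomal-length fragment midpoints
#'
#' Gaussian-kernel density of midpoints of fragments in the nucleosomal
#' length class, evaluated per base over a region and scaled to
#' per-million-fragments units.
#'
#' @param frags a [fragment_set()].
#' @param chrom,start,end region (0-based half-open).
#' @param bandwidth Gaussian kernel sd in bp (default 20).
#' @return numeric vector of length `end - start` (zeros when there are
#'   no nucleosomal fragments).
#' @export
nucleosome_occupancy <- function(frags, chrom, start, end,
                                 bandwidth = 20) {
  stopifnot(start < end)
  width <- end - start
  nuc <- frags[frags$class == "nucleosomal" & frags$chrom == chrom, ,
               drop = FALSE]
  total <- sum(frags$class == "nucleosomal")
  if (total == 0L) return(numeric(width))
  mids <- (nuc$start + nuc$end) / 2
  # only fragments whose kernel reaches the region matter
  mids <- mids[mids > start - 5 * bandwidth & mids < end + 5 * bandwidth]
  occ <- numeric(width)
  pos <- start + seq_len(width) - 0.5
  for (m in mids) occ <- occ + dnorm(pos, mean = m, sd = bandwidth)
  occ * 1e6 / total
}

#' Average signal profile around a set of centers
#'
#' Windows of +/- `halfwidth` bp around each center are extracted from a
#' per-base signal, reversed for minus-strand centers, and averaged.
#' Optionally the pointwise difference against a second aligned signal is
#' returned as well.
#'
#' @param signal a [cut_track()] or a named list of per-base numeric
#'   vectors.
#' @param centers data.frame with chrom, pos and optionally strand.
#' @param halfwidth half window size in bp (default 1500).
#' @param signal2 optional second signal for a difference profile.
#' @return data.frame: offset (-halfwidth..halfwidth), mean, n, and
#'   `diff` when `signal2` is given.
#' @export
metaprofile <- function(signal, centers, halfwidth = 1500L,
                        signal2 = NULL) {
  sig_list <- function(s) if (inherits(s, "cut_track")) s$counts else s
  s1 <- sig_list(signal)
  s2 <- if (!is.null(signal2)) sig_list(signal2)
  if (nrow(centers) == 0L) stop("no centers")
  w <- 2L * halfwidth + 1L
  extract <- function(sl) {
    acc <- numeric(w); nn <- 0L
    for (i in seq_len(nrow(centers))) {
      ch <- centers$chrom[i]
      x <- sl[[ch]]
      if (is.null(x)) next
      p <- centers$pos[i]
      lo <- p - halfwidth; hi <- p + halfwidth
      if (lo < 0L || hi >= length(x)) next
      win <- x[(lo + 1L):(hi + 1L)]
      if ("strand" %in% names(centers) && centers$strand[i] == "-")
        win <- rev(win)
      acc <- acc + win; nn <- nn + 1L
    }
    if (nn == 0L) stop("all centers out of bounds")
    list(mean = acc / nn, n = nn)
  }
  e1 <- extract(s1)
  out <- data.frame(offset = -halfwidth:halfwidth, mean = e1$mean,
                    n = e1$n)
  if (!is.null(s2)) {
    e2 <- extract(s2)
    out$mean2 <- e2$mean
    out$diff <- e1$mean - e2$mean
  }
  out
}

#' High-confidence peaks from replicated ChIP experiments
#'
#' Retains peaks supported by at least two replicate peak sets, then
#' re-tests each retained region's (position-deduplicated) tag count
#' against a Poisson null scaled from an input/isotype control track,
#' keeping peaks with p below `p_thr`, fold enrichment at least `min_FE`
#' and BH FDR at most `fdr`.
#'
#' @param replicate_peaksets list of >= 2 [peak_set()] objects.
#' @param signal_track pooled treatment [cut_track()].
#' @param control_track input or isotype-control [cut_track()].
#' @param p_thr Poisson p threshold (default 1e-4).
#' @param min_FE minimum fold enrichment (default 4).
#' @param fdr BH FDR threshold (default 1e-3).
#' @param max_tags_per_position cap on tags at one base (default 1).
#' @return a [peak_set()] of retained regions; `score` holds fold
#'   enrichment.
#' @export
high_confidence_peaks <- function(replicate_peaksets, signal_track,
                                  control_track, p_thr = 1e-4,
                                  min_FE = 4, fdr = 1e-3,
                                  max_tags_per_position = 1) {
  if (length(replicate_peaksets) < 2L) stop("need >= 2 replicates")
  pooled <- do.call(rbind, lapply(replicate_peaksets, as.data.frame))
  pooled <- peak_set(pooled$chrom, pooled$start, pooled$end)
  U <- merge_peaks(pooled)
  support <- Reduce(`+`, lapply(replicate_peaksets, function(r)
    as.integer(overlaps_any_peak(U, r))))
  U <- U[support >= 2L, ]
  if (nrow(U) == 0L) return(U)
  cap <- function(tr) lapply(tr$counts, pmin, max_tags_per_position)
  sig <- cap(signal_track); ctl <- cap(control_track)
  sig_total <- sum(vapply(sig, sum, 0))
  ctl_total <- sum(vapply(ctl, sum, 0))
  genome_bp <- sum(vapply(sig, length, 1L))
  scale <- if (ctl_total > 0) sig_total / ctl_total else 1
  rate_global <- sig_total / genome_bp
  cnt <- numeric(nrow(U)); lam <- numeric(nrow(U))
  for (i in seq_len(nrow(U))) {
    ch <- U$chrom[i]
    idx <- (U$start[i] + 1L):U$end[i]
    cnt[i] <- sum(sig[[ch]][idx])
    lam_ctl <- sum(ctl[[ch]][idx]) * scale
    lam[i] <- max(lam_ctl, rate_global * length(idx))
  }
  pv <- ppois(cnt - 1, lam, lower.tail = FALSE)
  fe <- cnt / lam
  qv <- p.adjust(pv, method = "BH")
  keep <- pv <= p_thr & fe >= min_FE & qv <= fdr
  out <- U[keep, ]
  out$score <- fe[keep]
  # summit = max-signal base
  out$summit_offset <- vapply(seq_len(nrow(out)), function(i) {
    ch <- out$chrom[i]
    seg <- signal_track$counts[[ch]][(out$start[i] + 1L):out$end[i]]
    which.max(seg) - 1L
  }, integer(1))
  attr(out, "set_name") <- "high_confidence_peaks"
  out
}

# local maxima of a numeric vector (strict rise, plateau start), 1-based
.local_maxima <- function(x, min_height = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
          x[2:(n - 1)] > min_height) + 1L
}

#' Pair nucleosome centers with flanking nucleosome-free regions
#'
#' Within each open region, local maxima of nucleosome occupancy are
#' paired with the nearest local maximum of the cut signal at least
#' `min_distance` bp away (the transposase-accessible NFR); pairs are
#' ranked by the accessibility differential, cut rate at the NFR minus
#' cut rate at the nucleosome center. Distance ties go to the leftmost
#' candidate.
#'
#' @param open_regions a [peak_set()].
#' @param occupancy named list of per-base occupancy vectors (full
#'   chromosomes, e.g. from [nucleosome_occupancy()]).
#' @param cuts a [cut_track()].
#' @param min_distance minimum dyad-to-NFR distance in bp (default 300).
#' @param smooth_bw sd in bp of the Gaussian smoothing applied to the cut
#'   signal before peak picking (default 25).
#' @return data.frame: chrom, nucleosome_center, nfr_pos, distance,
#'   differential; sorted by descending differential. Regions shorter
#'   than `min_distance` are skipped.
#' @export
nfr_nucleosome_pairs <- function(open_regions, occupancy, cuts,
                                 min_distance = 300L, smooth_bw = 25) {
  rows <- list()
  kern <- dnorm(seq(-3 * smooth_bw, 3 * smooth_bw), sd = smooth_bw)
  kern <- kern / sum(kern)
  for (i in seq_len(nrow(open_regions))) {
    ch <- open_regions$chrom[i]
    st <- open_regions$start[i]; en <- open_regions$end[i]
    if (en - st < min_distance) next
    occ <- occupancy[[ch]][(st + 1L):en]
    cut <- cuts$counts[[ch]][(st + 1L):en]
    cut_s <- stats::filter(cut, kern, sides = 2)
    cut_s[is.na(cut_s)] <- 0
    dyads <- .local_maxima(occ)
    nfrs <- .local_maxima(as.numeric(cut_s))
    if (!length(dyads) || !length(nfrs)) next
    for (d in dyads) {
      dist <- abs(nfrs - d)
      cand <- which(dist >= min_distance)
      if (!length(cand)) next
      j <- cand[order(dist[cand], nfrs[cand])][1L]
      nf <- nfrs[j]
      diff <- cut[nf] - cut[d]
      if (diff <= 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, nucleosome_center = st + d - 1L,
        nfr_pos = st + nf - 1L, distance = abs(nf - d),
        differential = diff, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(), nucleosome_center = integer(),
                      nfr_pos = integer(), distance = integer(),
                      differential = numeric()))
  out <- do.call(rbind, rows)
  out <- out[order(-out$differential), , drop = FALSE]
  rownames(out) <- NULL
  out
}
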