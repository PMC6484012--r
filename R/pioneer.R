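# TF-level pioneer analysis: per-site open/footprinted status across two
# timepoints, the chromatin-opening index and pioneer potential, a KS test
# of pioneer potential against differential expression, and per-TF
# footprint-count comparisons across conditions.

#' Build a per-site motif status table across two timepoints
#'
#' For each candidate motif site, records whether it lies inside an open
#' region at each timepoint and whether a called footprint matches it at
#' each timepoint (same PWM, center within `match_dist` bp).
#'
#' @param sites data.frame of motif matches (chrom, start, end, pwm_id).
#' @param open_t1,open_t2 [peak_set()] of open regions per timepoint.
#' @param fps_t1,fps_t2 footprint tables from [detect_footprints()]
#'   (called rows are used); either may be NULL.
#' @param match_dist footprint matching distance in bp (default 10).
#' @param condition label stored on the table (default "control").
#' @return `motif_site_table` data.frame: chrom, start, end, pwm_id,
#'   open_t1, open_t2, footprinted_t1, footprinted_t2, condition.
#' @export
motif_site_table <- function(sites, open_t1, open_t2, fps_t1 = NULL,
                             fps_t2 = NULL, match_dist = 10L,
                             condition = "control") {
  ctr <- (sites$start + sites$end) %/% 2L
  pts <- peak_set(sites$chrom, ctr, ctr + 1L)
  # peak_set sorts; map overlap flags back to input order
  ord <- order(sites$chrom, ctr, ctr + 1L)
  flag_open <- function(open) {
    f <- overlaps_any_peak(pts, open)
    out <- logical(length(f)); out[ord] <- f
    out
  }
  flag_fp <- function(fps) {
    if (is.null(fps)) return(rep(FALSE, nrow(sites)))
    fc <- fps[fps$called, , drop = FALSE]
    vapply(seq_len(nrow(sites)), function(i)
      any(fc$pwm_id == sites$pwm_id[i] & fc$chrom == sites$chrom[i] &
            abs(fc$center - ctr[i]) <= match_dist), logical(1))
  }
  out <- data.frame(chrom = sites$chrom, start = sites$start,
                    end = sites$end, pwm_id = sites$pwm_id,
                    open_t1 = flag_open(open_t1),
                    open_t2 = flag_open(open_t2),
                    footprinted_t1 = flag_fp(fps_t1),
                    footprinted_t2 = flag_fp(fps_t2),
                    condition = condition, stringsAsFactors = FALSE)
  class(out) <- c("motif_site_table", "data.frame")
  out
}

#' Chromatin-opening index and pioneer potential for one factor
#'
#' The opening index is the fraction of a factor's sites that were closed
#' at the first timepoint and are footprinted at the second which become
#' open at the second:
#' OI = #(closed_t1 & open_t2 & footprinted_t2) / #(closed_t1 & footprinted_t2).
#' Pioneer potential scales it against the genome-wide background
#' closed-to-open rate over all candidate sites of all factors:
#' PP = log2((OI + eps) / (bg + eps)).
#'
#' @param site_table a [motif_site_table()] covering all factors.
#' @param pwm_id the factor to evaluate.
#' @param eps stabilizer (default 1e-3).
#' @param bg background rate; by default the closed_t1-to-open_t2 rate
#'   over every site in the table.
#' @return list: OI, PP, n_eligible, bg; OI and PP are NA (with a
#'   `reason`) when no site is closed at t1 and footprinted at t2.
#' @export
opening_index <- function(site_table, pwm_id, eps = 1e-3, bg = NULL) {
  if (is.null(bg)) {
    closed <- !site_table$open_t1
    bg <- if (any(closed)) mean(site_table$open_t2[closed]) else 0
  }
  s <- site_table[site_table$pwm_id == pwm_id, , drop = FALSE]
  eligible <- !s$open_t1 & s$footprinted_t2
  if (!any(eligible))
    return(list(OI = NA_real_, PP = NA_real_, n_eligible = 0L, bg = bg,
                reason = "no site closed at t1 and footprinted at t2"))
  OI <- mean(s$open_t2[eligible])
  list(OI = OI, PP = log2((OI + eps) / (bg + eps)),
       n_eligible = sum(eligible), bg = bg)
}

#' Per-factor pioneer table
#'
#' Aggregates a [motif_site_table()] into one row per factor: site counts,
#' opening index, pioneer potential, footprint counts per timepoint, and a
#' differential-expression flag from a DEG table (factor gene q < `q_thr`).
#'
#' @param site_table a [motif_site_table()].
#' @param deg optional DEG table (gene, log2FC, q) whose `gene` matches
#'   factor names via `gene_map`.
#' @param gene_map named character vector pwm_id -> gene (default:
#'   identity).
#' @param q_thr DE significance threshold (default 0.05).
#' @param eps stabilizer passed to [opening_index()].
#' @return data.frame, one row per pwm_id: n_sites, n_closed_t1,
#'   n_eligible, n_opened, opening_index, pioneer_potential,
#'   footprint_count_t1, footprint_count_t2, de_flag.
#' @export
pioneer_table <- function(site_table, deg = NULL, gene_map = NULL,
                          q_thr = 0.05, eps = 1e-3) {
  ids <- sort(unique(site_table$pwm_id))
  closed <- !site_table$open_t1
  bg <- if (any(closed)) mean(site_table$open_t2[closed]) else 0
  rows <- lapply(ids, function(id) {
    s <- site_table[site_table$pwm_id == id, , drop = FALSE]
    oi <- opening_index(site_table, id, eps = eps, bg = bg)
    eligible <- !s$open_t1 & s$footprinted_t2
    gene <- if (is.null(gene_map)) id else unname(gene_map[id])
    de <- NA
    if (!is.null(deg) && !is.na(gene) && gene %in% deg$gene)
      de <- deg$q[match(gene, deg$gene)] < q_thr
    data.frame(pwm_id = id, gene = if (is.na(gene)) id else gene,
               n_sites = nrow(s), n_closed_t1 = sum(!s$open_t1),
               n_eligible = sum(eligible),
               n_opened = sum(s$open_t2[eligible]),
               opening_index = oi$OI, pioneer_potential = oi$PP,
               footprint_count_t1 = sum(s$footprinted_t1),
               footprint_count_t2 = sum(s$footprinted_t2),
               de_flag = de, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "background_rate") <- bg
  attr(out, "footprint_timepoint") <- "t2"
  out
}

#' KS test of pioneer potential between DE and non-DE factors
#'
#' Two-sample Kolmogorov-Smirnov test on pioneer-potential values of
#' differentially expressed versus comparably expressed factors, plus a
#' one-sided check that DE factors occupy higher intervals.
#'
#' For small groups the p-values are computed exactly by enumerating all
#' group-label permutations (which also handles tied pioneer-potential
#' values correctly); larger problems fall back to [stats::ks.test()].
#'
#' @param ptable a [pioneer_table()] with non-NA `de_flag` and
#'   `pioneer_potential`.
#' @param min_group minimum factors per group (default 3).
#' @param max_splits enumerate the permutation null exactly when the
#'   number of group assignments is at most this (default 20000).
#' @return list: D, p (two-sided), p_greater (one-sided, DE stochastically
#'   larger), n_de, n_nonde, exact (logical).
#' @export
pioneer_ks <- function(ptable, min_group = 3L, max_splits = 20000) {
  ok <- !is.na(ptable$de_flag) & !is.na(ptable$pioneer_potential)
  de <- ptable$pioneer_potential[ok & ptable$de_flag]
  nde <- ptable$pioneer_potential[ok & !ptable$de_flag]
  if (length(de) < min_group || length(nde) < min_group)
    stop("need >= ", min_group, " factors in each of the DE and non-DE groups")
  m <- length(de); n <- length(nde)
  d_two <- function(x, y)
    unname(suppressWarnings(ks.test(x, y)$statistic))
  d_one <- function(x, y)   # one-sided: x stochastically larger
    unname(suppressWarnings(ks.test(x, y,
                                    alternative = "less")$statistic))
  D <- d_two(de, nde)
  Dp <- d_one(de, nde)
  if (choose(m + n, m) <= max_splits) {
    pooled <- c(de, nde)
    combs <- utils::combn(m + n, m)
    d2 <- apply(combs, 2, function(i) d_two(pooled[i], pooled[-i]))
    d1 <- apply(combs, 2, function(i) d_one(pooled[i], pooled[-i]))
    p <- mean(d2 >= D - 1e-12)
    p_greater <- mean(d1 >= Dp - 1e-12)
    exact <- TRUE
  } else {
    p <- suppressWarnings(ks.test(de, nde))$p.value
    p_greater <- suppressWarnings(ks.test(de, nde,
                                          alternative = "less"))$p.value
    exact <- FALSE
  }
  list(D = D, p = p, p_greater = p_greater, n_de = m, n_nonde = n,
       exact = exact)
}

#' Footprint counts and loss fractions per factor across conditions
#'
#' @param fps_ctrl,fps_ko footprint tables from [detect_footprints()]
#'   for control and knockout.
#' @param match_dist matching distance for [footprint_loss()] (default 10).
#' @return data.frame per pwm_id: count_ctrl, count_ko, lost_fraction
#'   (NA when the factor has no called control footprints), sorted by
#'   descending control count.
#' @export
footprint_count_compare <- function(fps_ctrl, fps_ko, match_dist = 10L) {
  ids <- sort(unique(c(fps_ctrl$pwm_id, fps_ko$pwm_id)))
  rows <- lapply(ids, function(id) {
    fc <- fps_ctrl[fps_ctrl$pwm_id == id, , drop = FALSE]
    fk <- fps_ko[fps_ko$pwm_id == id, , drop = FALSE]
    n_c <- sum(fc$called); n_k <- sum(fk$called)
    lf <- if (n_c == 0L) NA_real_ else
      footprint_loss(fc, fk, match_dist = match_dist)
    data.frame(pwm_id = id, count_ctrl = n_c, count_ko = n_k,
               lost_fraction = lf, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$count_ctrl, out$pwm_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
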