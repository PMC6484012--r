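# Synthetic-data generator with planted ground truth. The generator
# emulates the statistical structure of a two-timepoint (early/late),
# two-condition (control / conditional knockout) retinal-progenitor
# study: open chromatin regions, TF-bound footprinted sites inside them,
# "closed-bound" sites for pioneer simulation, phased nucleosomes, ChIP
# replicate peak sets for a focal factor, and expression tables in which
# stated fractions of gene sets respond to the knockout.
#
# All randomness flows through R's RNG: set.seed() before calling any
# generator makes every output reproducible byte for byte.

#' Default simulation configuration
#'
#' Parameters define the planted study conditions: two timepoints (t1 =
#' embryonic, t2 = postnatal) x two conditions (control, cKO). Notable
#' defaults: open-chromatin cut rate 2 cuts/bp vs 0.05 outside, footprint
#' depletion factor 0.1, three designated pioneer factors whose closed
#' sites open between timepoints at rate 0.8 against a background rate of
#' 0.1, knockout footprint loss of 0.96 (t1) / 0.39 (t2) for the focal
#' factor, knockout region loss of 0.50 (t1) / 0.22 (t2), and a gene set
#' of which 70% is induced in the t1 knockout.
#'
#' @param ... overrides for any default field.
#' @return a `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_chroms = 2L, chrom_length = 2e6, gc = 0.5,
    # regions and ATAC signal
    n_bg_regions = 200L, region_length_mean = 500, region_length_sd = 100,
    r_open = 2, r_closed = 0.05, r_patch = 1,
    footprint_depletion = 0.1, patch_flank = 50L,
    # nucleosomes and fragments
    nucleosome_spacing = 200L, frag_mid_sd = 10, frags_per_dyad = 20,
    nfr_frags_per_region = 10,
    # TFs and sites
    n_tfs = 10L, sites_per_tf = 60L, motif_width = 10L,
    n_pioneers = 3L, opening_rate_pioneer = 0.8, opening_rate_other = 0.1,
    open_frac_t1 = 0.5,
    # knockout effects
    region_loss = c(t1 = 0.50, t2 = 0.22),
    ko_footprint_loss_focal = c(t1 = 0.96, t2 = 0.39),
    ko_footprint_loss_other = c(t1 = 0.60, t2 = 0.30),
    # per-factor overrides, named by PWM id (e.g. a SOX2-like co-factor
    # losing 93% of its footprints in the early knockout)
    ko_footprint_loss_overrides = list(t1 = c(TF02 = 0.93, TF03 = 0.84),
                                       t2 = c()),
    # ChIP simulation
    chip_jitter_sd = 20, chip_peak_width = 200L, chip_dropout = 0.1,
    chip_false_peaks = 20L, chip_rate = 1, chip_bg = 0.02,
    # expression
    n_genes = 2000L, n_reps = 3L, de_fraction = 0.2, de_log2fc = 2,
    expr_sd = 0.25, baseline_log2_mean = 5, baseline_log2_sd = 2,
    celltype_set_size = 100L,
    celltype_sets = c("amacrine", "rgc", "photoreceptor", "muller",
                      "horizontal"),
    ko_up_fraction = list(t1 = c(amacrine = 0.70, rgc = 0.70),
                          t2 = c(photoreceptor = 0.60)),
    ko_down_fraction = list(t1 = c(muller = 0.60, photoreceptor = 0.50),
                            t2 = c(horizontal = 0.60))
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown sim_config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "sim_config")
}

#' Generate a random genome
#'
#' I.i.d. sequence at the configured GC content. Deterministic under the
#' caller's RNG seed.
#'
#' @param cfg a [sim_config()].
#' @return named character vector (chr1, chr2, ...).
#' @export
make_genome <- function(cfg) {
  if (cfg$chrom_length < 1e4) stop("chrom_length must be >= 10 kb")
  p <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2, G = cfg$gc / 2,
         T = (1 - cfg$gc) / 2)
  g <- vapply(seq_len(cfg$n_chroms), function(i)
    paste(sample(names(p), cfg$chrom_length, replace = TRUE, prob = p),
          collapse = ""), "")
  setNames(g, paste0("chr", seq_len(cfg$n_chroms)))
}

#' Generate the factor motif models
#'
#' One PWM per factor: a random consensus of the configured width with
#' probability ~0.85 on the consensus base per column. The first factor
#' is the focal (knockout) factor; factors 2..(1+n_pioneers) are the
#' designated pioneers.
#'
#' @param cfg a [sim_config()].
#' @return list of [pwm()]; each carries its consensus as attribute
#'   `consensus`.
#' @export
make_pwms <- function(cfg) {
  bases <- c("A", "C", "G", "T")
  lapply(seq_len(cfg$n_tfs), function(t) {
    cons <- sample(bases, cfg$motif_width, replace = TRUE)
    cnt <- matrix(1, 4, cfg$motif_width)
    cnt[cbind(match(cons, bases), seq_len(cfg$motif_width))] <- 17
    prob <- sweep(cnt + 0.25, 2, colSums(cnt) + 1, "/")
    p <- pwm(prob, id = sprintf("TF%02d", t), name = sprintf("TF%02d", t))
    attr(p, "consensus") <- paste(cons, collapse = "")
    p
  })
}

.revcomp_string <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Lay out the planted truth and plant motif instances into the genome
#'
#' Allocates non-overlapping region slots across chromosomes, assigns
#' each either to a factor site (one site per region) or to a background
#' open region, samples per-site open/bound status at both timepoints,
#' samples the knockout footprint losses (exact planted counts per
#' factor) and the knockout region losses (exact planted counts,
#' consistent with the footprint losses), lays phased nucleosome dyads,
#' and writes each site's consensus sequence into the genome.
#'
#' @param cfg a [sim_config()].
#' @param genome from [make_genome()].
#' @param pwms from [make_pwms()].
#' @return list (`sim_truth`): `genome` (with planted instances),
#'   `sites`, `regions`, `dyads`, `genes`, `gene_sets`, `expr_truth`,
#'   `pwms`, `cfg`.
#' @export
plant_truth <- function(cfg, genome, pwms) {
  n_sites <- cfg$n_tfs * cfg$sites_per_tf
  n_slots <- n_sites + cfg$n_bg_regions
  margin <- 2000L
  per_chrom <- ceiling(n_slots / cfg$n_chroms)
  spacing <- floor((cfg$chrom_length - 2 * margin) / per_chrom)
  if (spacing < 1500L)
    stop("genome too small for the requested number of regions ",
         "(slot spacing ", spacing, " bp < 1500 bp)")
  centers <- list()
  for (ci in seq_len(cfg$n_chroms)) {
    k <- min(per_chrom, n_slots - (ci - 1L) * per_chrom)
    if (k <= 0L) break
    centers[[ci]] <- data.frame(
      chrom = paste0("chr", ci),
      center = as.integer(margin + spacing %/% 2L +
                            spacing * (seq_len(k) - 1L)))
  }
  slots <- do.call(rbind, centers)[seq_len(n_slots), ]
  slots <- slots[sample.int(n_slots), ]       # shuffle assignment
  rownames(slots) <- NULL
  len <- pmin(pmax(round(rnorm(n_slots, cfg$region_length_mean,
                               cfg$region_length_sd)),
                   cfg$motif_width + 300L), spacing - 400L)
  regions <- data.frame(
    region_id = seq_len(n_slots), chrom = slots$chrom,
    start = as.integer(slots$center - len %/% 2L),
    end = as.integer(slots$center - len %/% 2L + len),
    center = slots$center,
    kind = c(rep("site", n_sites), rep("background", cfg$n_bg_regions)),
    stringsAsFactors = FALSE)

  # --- per-site status ------------------------------------------------------
  tf_ids <- vapply(pwms, `[[`, "", "id")
  pioneers <- tf_ids[1L + seq_len(cfg$n_pioneers)]
  focal <- tf_ids[1L]
  sites <- data.frame(
    site_id = seq_len(n_sites), region_id = seq_len(n_sites),
    tf = rep(tf_ids, each = cfg$sites_per_tf),
    chrom = regions$chrom[seq_len(n_sites)],
    center = regions$center[seq_len(n_sites)],
    stringsAsFactors = FALSE)
  w <- cfg$motif_width
  sites$start <- as.integer(sites$center - w %/% 2L)
  sites$end <- sites$start + w
  sites$strand <- sample(c("+", "-"), n_sites, replace = TRUE)
  open_rate <- ifelse(sites$tf %in% pioneers, cfg$opening_rate_pioneer,
                      cfg$opening_rate_other)
  sites$open_t1 <- runif(n_sites) < cfg$open_frac_t1
  sites$open_t2 <- sites$open_t1 | (runif(n_sites) < open_rate)
  # binding truth: open sites are bound at their open timepoints; at t2
  # every factor also engages its non-opened sites as closed-bound
  # micro-footprints (the pioneer-simulation "closed-bound" class)
  sites$bound_t1 <- sites$open_t1
  sites$bound_t2 <- TRUE
  sites$closed_bound_t2 <- !sites$open_t2

  # --- knockout footprint losses (exact planted counts) ---------------------
  loss_for <- function(tf, tp) {
    ov <- cfg$ko_footprint_loss_overrides[[tp]]
    if (!is.null(ov) && tf %in% names(ov)) ov[[tf]]
    else if (tf == focal) cfg$ko_footprint_loss_focal[[tp]]
    else cfg$ko_footprint_loss_other[[tp]]
  }
  sites$fp_lost_ko_t1 <- FALSE
  sites$fp_lost_ko_t2 <- FALSE
  for (tp in c("t1", "t2")) {
    bound_col <- paste0("bound_", tp)
    lost_col <- paste0("fp_lost_ko_", tp)
    for (tf in tf_ids) {
      b <- which(sites$tf == tf & sites[[bound_col]])
      m <- round(loss_for(tf, tp) * length(b))
      if (m > 0L) sites[[lost_col]][sample(b, m)] <- TRUE
    }
  }

  # --- knockout region losses (exact planted counts) -------------------------
  # open regions at (tp, control) = background regions + regions of sites
  # open at tp; a region is eligible for loss when it is background or
  # its site's footprint is planted lost (so retained footprints always
  # sit in retained regions)
  regions$lost_ko_t1 <- FALSE
  regions$lost_ko_t2 <- FALSE
  for (tp in c("t1", "t2")) {
    open_col <- paste0("open_", tp)
    lost_col <- paste0("fp_lost_ko_", tp)
    open_site_regions <- sites$region_id[sites[[open_col]]]
    bg_regions <- regions$region_id[regions$kind == "background"]
    n_open <- length(open_site_regions) + length(bg_regions)
    eligible <- c(bg_regions,
                  sites$region_id[sites[[open_col]] & sites[[lost_col]]])
    m <- round(cfg$region_loss[[tp]] * n_open)
    if (m > length(eligible)) {
      warning("region loss fraction for ", tp, " capped at ",
              round(length(eligible) / n_open, 3),
              " (not enough eligible regions)")
      m <- length(eligible)
    }
    regions[[paste0("lost_ko_", tp)]][sample(eligible, m)] <- TRUE
  }

  # --- phased nucleosome dyads ----------------------------------------------
  dy <- list()
  for (i in seq_len(nrow(regions))) {
    ctr <- regions$center[i]
    offs <- 150L + cfg$nucleosome_spacing * (0:2)
    pos <- c(ctr - rev(offs), ctr + offs)
    dy[[i]] <- data.frame(region_id = regions$region_id[i],
                          chrom = regions$chrom[i], pos = pos)
  }
  dyads <- do.call(rbind, dy)

  # --- plant motif instances -------------------------------------------------
  cons <- setNames(vapply(pwms, attr, "", "consensus"), tf_ids)
  for (i in seq_len(n_sites)) {
    s <- cons[[sites$tf[i]]]
    if (sites$strand[i] == "-") s <- .revcomp_string(s)
    ch <- sites$chrom[i]
    substr(genome[[ch]], sites$start[i] + 1L, sites$end[i]) <- s
  }

  # --- genes, TSS, cell-type sets -------------------------------------------
  gene_names <- sprintf("gene%04d", seq_len(cfg$n_genes))
  # the factor genes live among them (evenly spread)
  tf_gene_idx <- round(seq(1, cfg$n_genes, length.out = cfg$n_tfs + 2))
  tf_gene_idx <- tf_gene_idx[2:(cfg$n_tfs + 1)]
  gene_names[tf_gene_idx] <- tf_ids
  gpos <- round(seq(5000, cfg$n_chroms * cfg$chrom_length - 5000,
                    length.out = cfg$n_genes))
  gchrom <- paste0("chr", pmin(cfg$n_chroms,
                               1L + gpos %/% cfg$chrom_length))
  gtss <- as.integer(gpos %% cfg$chrom_length)
  genes <- data.frame(gene = gene_names, chrom = gchrom, tss = gtss,
                      strand = rep_len(c("+", "-"), cfg$n_genes),
                      stringsAsFactors = FALSE)
  pool <- setdiff(gene_names, tf_ids)
  sets <- list()
  for (sn in cfg$celltype_sets) {
    pick <- sample(pool, cfg$celltype_set_size)
    pool <- setdiff(pool, pick)
    sets[[sn]] <- pick
  }
  gene_sets <- do.call(rbind, lapply(names(sets), function(sn)
    data.frame(set_name = sn, gene = sets[[sn]],
               stringsAsFactors = FALSE)))

  # --- expression truth ------------------------------------------------------
  base <- rnorm(cfg$n_genes, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  names(base) <- gene_names
  # developmental DE (t1 vs t2): the pioneers are developmentally induced;
  # a de_fraction of the non-factor genes shift in a random direction
  dev_shift <- setNames(numeric(cfg$n_genes), gene_names)
  dev_shift[pioneers] <- cfg$de_log2fc
  others <- setdiff(gene_names, tf_ids)
  n_de <- round(cfg$de_fraction * length(others))
  de_pick <- sample(others, n_de)
  dev_shift[de_pick] <- sample(c(-1, 1), n_de, replace = TRUE) *
    cfg$de_log2fc
  # knockout effects per timepoint
  ko_shift <- list(t1 = setNames(numeric(cfg$n_genes), gene_names),
                   t2 = setNames(numeric(cfg$n_genes), gene_names))
  ko_truth <- list(t1 = character(0), t2 = character(0))
  for (tp in c("t1", "t2")) {
    for (sn in names(cfg$ko_up_fraction[[tp]])) {
      members <- sets[[sn]]
      m <- round(cfg$ko_up_fraction[[tp]][[sn]] * length(members))
      pick <- sample(members, m)
      ko_shift[[tp]][pick] <- cfg$de_log2fc
      ko_truth[[tp]] <- c(ko_truth[[tp]], pick)
    }
    for (sn in names(cfg$ko_down_fraction[[tp]])) {
      members <- sets[[sn]]
      m <- round(cfg$ko_down_fraction[[tp]][[sn]] * length(members))
      pick <- sample(setdiff(members, ko_truth[[tp]]),
                     min(m, length(setdiff(members, ko_truth[[tp]]))))
      ko_shift[[tp]][pick] <- -cfg$de_log2fc
      ko_truth[[tp]] <- c(ko_truth[[tp]], pick)
    }
    ko_shift[[tp]][focal] <- -2 * cfg$de_log2fc   # the knockout itself
  }
  expr_truth <- list(baseline_log2 = base, dev_shift = dev_shift,
                     ko_shift = ko_shift, pioneers = pioneers,
                     focal = focal, de_genes_dev = c(pioneers, de_pick))

  structure(list(genome = genome, sites = sites, regions = regions,
                 dyads = dyads, genes = genes, gene_sets = gene_sets,
                 expr_truth = expr_truth, pwms = pwms, cfg = cfg),
            class = "sim_truth")
}

# open regions for a (timepoint, condition) cell, as a peak_set
truth_open_regions <- function(truth, timepoint = c("t1", "t2"),
                               condition = c("control", "ko")) {
  timepoint <- match.arg(timepoint); condition <- match.arg(condition)
  reg <- truth$regions
  open_col <- paste0("open_", timepoint)
  site_open <- truth$sites$region_id[truth$sites[[open_col]]]
  ids <- c(reg$region_id[reg$kind == "background"], site_open)
  if (condition == "ko")
    ids <- setdiff(ids, reg$region_id[reg[[paste0("lost_ko_", timepoint)]]])
  r <- reg[reg$region_id %in% ids, ]
  peak_set(r$chrom, r$start, r$end,
           set_name = paste("open", timepoint, condition),
           genome_length = truth$cfg$n_chroms * truth$cfg$chrom_length)
}

# bound sites carrying a footprint in a given cell of the design
truth_footprinted_sites <- function(truth, timepoint, condition) {
  s <- truth$sites
  bound <- s[[paste0("bound_", timepoint)]]
  if (condition == "ko")
    bound <- bound & !s[[paste0("fp_lost_ko_", timepoint)]]
  # a footprint also needs its region open in this condition (closed-bound
  # patches at t2 carry their own local signal instead)
  open_col <- paste0("open_", timepoint)
  if (condition == "ko") {
    lost_reg <- truth$regions$region_id[
      truth$regions[[paste0("lost_ko_", timepoint)]]]
    in_lost <- s$region_id %in% lost_reg
  } else in_lost <- FALSE
  ok_open <- s[[open_col]] & !in_lost
  patch <- if (timepoint == "t2") s$closed_bound_t2 else FALSE
  s[bound & (ok_open | patch), , drop = FALSE]
}

#' Simulate an ATAC experiment for one cell of the design
#'
#' Per-base cut counts are Poisson: rate `r_closed` outside open regions,
#' `r_open` inside, multiplied by `footprint_depletion` over bound motif
#' spans. Closed-bound sites at the late timepoint carry a local
#' accessible patch at rate `r_patch` (flank `patch_flank` bp each side)
#' with the same central depletion - a footprint without a callable open
#' region. In the knockout, planted-lost regions revert to the closed
#' rate and planted-lost footprints lose their depletion (or their
#' patch). Nucleosomal and NFR fragments are drawn at the planted dyads
#' and region centers.
#'
#' @param truth a [plant_truth()] result.
#' @param timepoint "t1" or "t2".
#' @param condition "control" or "ko".
#' @return list: `cuts` ([cut_track()]), `frags` ([fragment_set()]),
#'   `open_regions` (the truth's open [peak_set()] for this cell).
#' @export
simulate_atac <- function(truth, timepoint = c("t1", "t2"),
                          condition = c("control", "ko")) {
  timepoint <- match.arg(timepoint); condition <- match.arg(condition)
  cfg <- truth$cfg
  L <- cfg$chrom_length
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  rate <- setNames(lapply(chroms, function(ch) rep(cfg$r_closed, L)),
                   chroms)
  open <- truth_open_regions(truth, timepoint, condition)
  for (i in seq_len(nrow(open))) {
    ch <- open$chrom[i]
    rate[[ch]][(open$start[i] + 1L):open$end[i]] <- cfg$r_open
  }
  fps <- truth_footprinted_sites(truth, timepoint, condition)
  if (nrow(fps)) {
    patch <- if (timepoint == "t2") fps$closed_bound_t2 else
      rep(FALSE, nrow(fps))
    for (i in seq_len(nrow(fps))) {
      ch <- fps$chrom[i]
      if (patch[i]) {
        lo <- fps$start[i] - cfg$patch_flank
        hi <- fps$end[i] + cfg$patch_flank
        rate[[ch]][(lo + 1L):hi] <- cfg$r_patch
        rate[[ch]][(fps$start[i] + 1L):fps$end[i]] <-
          cfg$r_patch * cfg$footprint_depletion
      } else {
        rate[[ch]][(fps$start[i] + 1L):fps$end[i]] <-
          cfg$r_open * cfg$footprint_depletion
      }
    }
  }
  cuts <- cut_track(lapply(rate, function(r) rpois(length(r), r)))

  # fragments: NFR at open-region centers, nucleosomal at planted dyads
  open_ids <- unique(c(
    truth$regions$region_id[truth$regions$kind == "background"],
    truth$sites$region_id[truth$sites[[paste0("open_", timepoint)]]]))
  if (condition == "ko")
    open_ids <- setdiff(open_ids, truth$regions$region_id[
      truth$regions[[paste0("lost_ko_", timepoint)]]])
  reg <- truth$regions[truth$regions$region_id %in% open_ids, ]
  fr_ch <- character(); fr_st <- integer(); fr_en <- integer()
  n_nfr <- rpois(nrow(reg), cfg$nfr_frags_per_region)
  for (i in seq_len(nrow(reg))) {
    if (n_nfr[i] == 0L) next
    mid <- round(rnorm(n_nfr[i], reg$center[i], 30))
    len <- pmax(20, pmin(99, round(rnorm(n_nfr[i], 60, 15))))
    fr_ch <- c(fr_ch, rep(reg$chrom[i], n_nfr[i]))
    fr_st <- c(fr_st, mid - len %/% 2L)
    fr_en <- c(fr_en, mid - len %/% 2L + len)
  }
  dy <- truth$dyads[truth$dyads$region_id %in% open_ids, ]
  n_nuc <- rpois(nrow(dy), cfg$frags_per_dyad)
  for (i in seq_len(nrow(dy))) {
    if (n_nuc[i] == 0L) next
    mid <- round(rnorm(n_nuc[i], dy$pos[i], cfg$frag_mid_sd))
    len <- pmax(150, pmin(250, round(rnorm(n_nuc[i], 185, 15))))
    fr_ch <- c(fr_ch, rep(dy$chrom[i], n_nuc[i]))
    fr_st <- c(fr_st, mid - len %/% 2L)
    fr_en <- c(fr_en, mid - len %/% 2L + len)
  }
  keep <- fr_st >= 0L & fr_en <= L
  frags <- fragment_set(fr_ch[keep], fr_st[keep], fr_en[keep])
  list(cuts = cuts, frags = frags, open_regions = open)
}

#' Simulate replicated ChIP peak sets and tag tracks for the focal factor
#'
#' Peaks are centered (with Gaussian jitter) on the focal factor's bound
#' sites at the given timepoint; each replicate drops peaks independently
#' at the configured dropout rate and adds background false peaks. A
#' simple tag model accompanies them: rate `chip_rate` inside true peak
#' spans, `chip_bg` elsewhere; the isotype control is background-only.
#'
#' @param truth a [plant_truth()] result.
#' @param timepoint "t1" or "t2".
#' @param n_replicates number of replicate peak sets (default 2).
#' @return list: `replicates` (list of [peak_set()]), `signal_track`,
#'   `control_track` ([cut_track()]), `true_sites` (the bound sites).
#' @export
simulate_chip <- function(truth, timepoint = c("t1", "t2"),
                          n_replicates = 2L) {
  timepoint <- match.arg(timepoint)
  cfg <- truth$cfg
  focal <- truth$expr_truth$focal
  s <- truth$sites
  bound <- s[s$tf == focal & s[[paste0("bound_", timepoint)]] &
               s[[paste0("open_", timepoint)]], , drop = FALSE]
  L <- cfg$chrom_length
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  half <- cfg$chip_peak_width %/% 2L
  reps <- lapply(seq_len(n_replicates), function(r) {
    keep <- runif(nrow(bound)) >= cfg$chip_dropout
    b <- bound[keep, , drop = FALSE]
    ctr <- pmax(half, pmin(L - half,
                           round(b$center + rnorm(nrow(b), 0,
                                                  cfg$chip_jitter_sd))))
    n_false <- rpois(1, cfg$chip_false_peaks)
    f_ch <- sample(chroms, n_false, replace = TRUE)
    f_ctr <- round(runif(n_false, half + 1, L - half - 1))
    peak_set(c(b$chrom, f_ch), c(ctr, f_ctr) - half,
             c(ctr, f_ctr) + half,
             summit_offset = rep(half, nrow(b) + n_false),
             set_name = sprintf("chip_%s_rep%d", timepoint, r))
  })
  rate <- setNames(lapply(chroms, function(ch) rep(cfg$chip_bg, L)),
                   chroms)
  for (i in seq_len(nrow(bound))) {
    ch <- bound$chrom[i]
    lo <- bound$center[i] - half; hi <- bound$center[i] + half
    rate[[ch]][(lo + 1L):hi] <- cfg$chip_rate
  }
  signal <- cut_track(lapply(rate, function(r) rpois(length(r), r)))
  control <- cut_track(lapply(chroms, function(ch)
    rpois(L, cfg$chip_bg)) |> setNames(chroms))
  list(replicates = reps, signal_track = signal,
       control_track = control, true_sites = bound)
}

# per-gene moderated t on log2 replicate matrices (B vs A); limma's
# empirical-Bayes variance shrinkage is what makes n = 3 designs usable
.deg_moderated <- function(A, B) {
  x <- cbind(A, B)
  design <- cbind(intercept = 1,
                  groupB = rep(c(0, 1), c(ncol(A), ncol(B))))
  fit <- limma::eBayes(limma::lmFit(x, design))
  list(log2FC = fit$coefficients[, "groupB"],
       p = fit$p.value[, "groupB"])
}

#' Simulate expression and differential-expression tables
#'
#' Log-normal baselines with the planted developmental and knockout
#' shifts; per-group replicates (log2 noise sd `expr_sd`, n = `n_reps`);
#' DEG q-values from limma's moderated t statistic, BH-adjusted.
#'
#' @param truth a [plant_truth()] result.
#' @return list: `expression` (per timepoint: gene, fpkm), `deg_dev`
#'   (t2 vs t1 control), `deg_ko` (per timepoint: ko vs control), each a
#'   data.frame (gene, log2FC, q).
#' @export
simulate_expression <- function(truth) {
  cfg <- truth$cfg
  et <- truth$expr_truth
  genes <- names(et$baseline_log2)
  ng <- length(genes)
  draw <- function(mu) matrix(rnorm(ng * cfg$n_reps, mu, cfg$expr_sd),
                              nrow = ng)
  mu_t1 <- et$baseline_log2
  mu_t2 <- et$baseline_log2 + et$dev_shift
  mats <- list(t1_control = draw(mu_t1), t2_control = draw(mu_t2),
               t1_ko = draw(mu_t1 + et$ko_shift$t1),
               t2_ko = draw(mu_t2 + et$ko_shift$t2))
  deg_of <- function(A, B) {
    w <- .deg_moderated(A, B)
    data.frame(gene = genes, log2FC = unname(w$log2FC),
               q = p.adjust(w$p, "BH"), stringsAsFactors = FALSE)
  }
  list(
    expression = list(
      t1 = data.frame(gene = genes,
                      fpkm = 2^rowMeans(mats$t1_control),
                      stringsAsFactors = FALSE),
      t2 = data.frame(gene = genes,
                      fpkm = 2^rowMeans(mats$t2_control),
                      stringsAsFactors = FALSE)),
    deg_dev = deg_of(mats$t1_control, mats$t2_control),
    deg_ko = list(t1 = deg_of(mats$t1_control, mats$t1_ko),
                  t2 = deg_of(mats$t2_control, mats$t2_ko)))
}

#' Generate a complete synthetic study and write it to disk
#'
#' Runs the whole generator under one seed and writes every input the
#' pipeline consumes: genome FASTA, JASPAR-format PWMs, per-cell cut
#' bedGraphs and fragment TSVs, ChIP replicate narrowPeaks and tag
#' bedGraphs, TSS/gene-set/DEG/expression TSVs, a pipeline `config.json`
#' and a `truth.json` ground-truth bundle.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory (created).
#' @param seed integer seed; every output is byte-identical given the
#'   same seed and config.
#' @return invisibly, the in-memory bundle (truth plus all simulated
#'   objects and the file manifest).
#' @export
simulate_study <- function(cfg, outdir, seed) {
  set.seed(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genome <- make_genome(cfg)
  pwms <- make_pwms(cfg)
  truth <- plant_truth(cfg, genome, pwms)
  fp <- function(...) file.path(outdir, ...)
  write_genome(truth$genome, fp("genome.fa"))
  write_pwm_jaspar(pwms, fp("pwms.jaspar"))
  atac <- list()
  for (tp in c("t1", "t2")) for (cond in c("control", "ko")) {
    cell <- paste0(tp, "_", cond)
    atac[[cell]] <- simulate_atac(truth, tp, cond)
    write_cut_track(atac[[cell]]$cuts, fp(paste0("cuts_", cell, ".bedgraph")))
    write_fragments(atac[[cell]]$frags,
                    fp(paste0("fragments_", cell, ".tsv")))
  }
  chip <- list()
  for (tp in c("t1", "t2")) {
    chip[[tp]] <- simulate_chip(truth, tp)
    for (r in seq_along(chip[[tp]]$replicates))
      write_intervals(chip[[tp]]$replicates[[r]],
                      fp(sprintf("chip_%s_rep%d.narrowPeak", tp, r)),
                      "narrowPeak")
    write_cut_track(chip[[tp]]$signal_track,
                    fp(sprintf("chip_%s_signal.bedgraph", tp)))
    write_cut_track(chip[[tp]]$control_track,
                    fp(sprintf("chip_%s_control.bedgraph", tp)))
  }
  expr <- simulate_expression(truth)
  wt <- function(df, path) write.table(df, path, sep = "\t",
                                       quote = FALSE, row.names = FALSE)
  wt(truth$genes, fp("tss.tsv"))
  wt(truth$gene_sets, fp("genesets.tsv"))
  wt(expr$expression$t1, fp("expression_t1.tsv"))
  wt(expr$expression$t2, fp("expression_t2.tsv"))
  wt(expr$deg_dev, fp("deg_dev.tsv"))
  wt(expr$deg_ko$t1, fp("deg_ko_t1.tsv"))
  wt(expr$deg_ko$t2, fp("deg_ko_t2.tsv"))
  chrom_sizes <- data.frame(chrom = names(truth$genome),
                            length = nchar(truth$genome))
  wt(chrom_sizes, fp("chrom.sizes"))
  config <- list(
    genome = "genome.fa", pwms = "pwms.jaspar", chrom_sizes = "chrom.sizes",
    tss = "tss.tsv", genesets = "genesets.tsv",
    expression = list(t1 = "expression_t1.tsv", t2 = "expression_t2.tsv"),
    deg_dev = "deg_dev.tsv",
    deg_ko = list(t1 = "deg_ko_t1.tsv", t2 = "deg_ko_t2.tsv"),
    cuts = list(t1_control = "cuts_t1_control.bedgraph",
                t1_ko = "cuts_t1_ko.bedgraph",
                t2_control = "cuts_t2_control.bedgraph",
                t2_ko = "cuts_t2_ko.bedgraph"),
    fragments = list(t1_control = "fragments_t1_control.tsv",
                     t1_ko = "fragments_t1_ko.tsv",
                     t2_control = "fragments_t2_control.tsv",
                     t2_ko = "fragments_t2_ko.tsv"),
    chip = list(
      t1 = list(replicates = c("chip_t1_rep1.narrowPeak",
                               "chip_t1_rep2.narrowPeak"),
                signal = "chip_t1_signal.bedgraph",
                control = "chip_t1_control.bedgraph"),
      t2 = list(replicates = c("chip_t2_rep1.narrowPeak",
                               "chip_t2_rep2.narrowPeak"),
                signal = "chip_t2_signal.bedgraph",
                control = "chip_t2_control.bedgraph")),
    focal_tf = truth$expr_truth$focal)
  jsonlite::write_json(config, fp("config.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  truth_json <- list(
    seed = seed,
    planted = list(
      region_loss = as.list(cfg$region_loss),
      ko_footprint_loss_focal = as.list(cfg$ko_footprint_loss_focal),
      pioneers = truth$expr_truth$pioneers,
      focal = truth$expr_truth$focal,
      opening_rate_pioneer = cfg$opening_rate_pioneer,
      opening_rate_other = cfg$opening_rate_other),
    sites = truth$sites, regions = truth$regions)
  jsonlite::write_json(truth_json, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(truth = truth, atac = atac, chip = chip, expr = expr,
                 config = config, outdir = outdir))
}
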