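# End-to-end orchestration: open regions -> motif scan -> enrichment and
# clustering -> footprints -> pioneer indexes -> integration, from a
# single config, with every stage written as TSV and a markdown summary.

.read_config <- function(config) {
  if (is.character(config)) {
    base <- dirname(config)
    cfg <- jsonlite::read_json(config, simplifyVector = TRUE)
    cfg$.base <- base
    cfg
  } else {
    if (is.null(config$.base)) config$.base <- "."
    config
  }
}

.cfg_path <- function(cfg, p) {
  if (is.null(p)) return(NULL)
  file.path(cfg$.base, p)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: open-region calling per timepoint/condition,
#' Jaccard comparison of timepoints, genome-wide motif scanning,
#' known-motif binomial enrichment with randomization FDR, PWM
#' clustering, footprint detection per cell of the design,
#' control-vs-knockout footprint and region loss, the chromatin-opening
#' index and pioneer-potential table with its KS test, and (when ChIP
#' inputs are present) high-confidence peaks, nearest-TSS target
#' assignment, cell-type gene-set enrichment, knockout-dependence
#' classification and the occupancy-accessibility correlation. Every
#' stage writes a TSV under `outdir`; `summary.md` collects the headline
#' statistics. All randomness is governed by `seed`.
#'
#' Missing knockout tracks downgrade the loss and dependence stages to
#' "skipped"; missing required inputs abort before any stage runs.
#'
#' @param config path to a config JSON (as written by [simulate_study()])
#'   or an equivalent list; paths are resolved relative to the config
#'   file's directory.
#' @param outdir output directory.
#' @param seed integer seed.
#' @param scan_pvalue motif-match p-value threshold (default 1e-4).
#' @param open_params list of overrides for [call_open_regions()].
#' @param verbose log stage progress to stderr (default TRUE).
#' @return invisibly, a list with every stage result.
#' @export
run_pipeline <- function(config, outdir, seed = 1L, scan_pvalue = 1e-4,
                         open_params = list(), verbose = TRUE) {
  cfg <- .read_config(config)
  set.seed(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  required <- c(.cfg_path(cfg, cfg$genome), .cfg_path(cfg, cfg$pwms),
                .cfg_path(cfg, cfg$chrom_sizes), .cfg_path(cfg, cfg$tss),
                unlist(lapply(cfg$cuts[c("t1_control", "t2_control")],
                              function(p) .cfg_path(cfg, p))))
  missing <- required[!file.exists(required)]
  if (length(missing))
    stop("missing input file(s):\n  ", paste(missing, collapse = "\n  "))

  say("[load] reading genome, PWMs, tables")
  genome <- read_genome(.cfg_path(cfg, cfg$genome))
  pwms <- read_pwm_jaspar(.cfg_path(cfg, cfg$pwms))
  sizes <- read.delim(.cfg_path(cfg, cfg$chrom_sizes))
  chrom_lengths <- setNames(as.integer(sizes$length), sizes$chrom)
  tss <- read_table_typed(.cfg_path(cfg, cfg$tss), "tss")
  gene_sets <- if (!is.null(cfg$genesets))
    read_table_typed(.cfg_path(cfg, cfg$genesets), "geneset")
  deg_dev <- if (!is.null(cfg$deg_dev))
    read_table_typed(.cfg_path(cfg, cfg$deg_dev), "deg")
  res <- list(parameters = list(seed = seed, scan_pvalue = scan_pvalue,
                                open_params = open_params))
  wt <- function(df, name) write.table(df, file.path(outdir, name),
                                       sep = "\t", quote = FALSE,
                                       row.names = FALSE)

  # --- open regions ---------------------------------------------------------
  cells <- names(cfg$cuts)
  cuts <- list(); open <- list()
  for (cell in cells) {
    p <- .cfg_path(cfg, cfg$cuts[[cell]])
    if (!file.exists(p)) { say("[open] %s: missing, skipped", cell); next }
    say("[open] calling open regions: %s", cell)
    cuts[[cell]] <- read_cut_track(p, chrom_lengths)
    open[[cell]] <- do.call(call_open_regions,
                            c(list(cuts[[cell]]), open_params))
    write_intervals(open[[cell]],
                    file.path(outdir, paste0("open_", cell, ".bed")),
                    "bed6")
  }
  res$open_regions <- open

  # --- Jaccard between timepoints -------------------------------------------
  if (all(c("t1_control", "t2_control") %in% names(open))) {
    jac <- data.frame(
      comparison = "t1_control.vs.t2_control",
      jaccard_bp = jaccard(open$t1_control, open$t2_control, "bp"),
      jaccard_count = jaccard(open$t1_control, open$t2_control, "count"))
    wt(jac, "jaccard.tsv")
    res$jaccard <- jac
  }

  # --- motif scan ------------------------------------------------------------
  say("[scan] scanning %d PWMs over %.1f Mb", length(pwms),
      sum(chrom_lengths) / 1e6)
  sites <- do.call(rbind, lapply(pwms, function(p)
    scan_pwm(genome, p, pvalue = scan_pvalue)))
  wt(sites, "motif_sites.tsv")
  res$sites <- sites

  # --- motif enrichment + clustering ----------------------------------------
  if (!is.null(open$t1_control) && nrow(open$t1_control) > 0) {
    say("[enrich] binomial enrichment over %d regions",
        nrow(open$t1_control))
    bg <- random_regions(chrom_lengths,
                         widths = open$t1_control$end -
                           open$t1_control$start)
    res$enrichment <- enrichment_fdr(open$t1_control, genome, bg, genome,
                                     pwms, pvalue = scan_pvalue)
    wt(res$enrichment, "motif_enrichment.tsv")
  }
  say("[cluster] clustering %d PWMs", length(pwms))
  cl <- cluster_pwms(pwms)
  res$clusters <- data.frame(pwm_id = vapply(pwms, `[[`, "", "id"),
                             cluster = cl$membership)
  wt(res$clusters, "pwm_clusters.tsv")

  # --- footprints ------------------------------------------------------------
  fps <- list()
  for (cell in names(cuts)) {
    say("[footprint] %s: %d candidate sites", cell, nrow(sites))
    fps[[cell]] <- detect_footprints(cuts[[cell]], sites)
    wt(fps[[cell]], paste0("footprints_", cell, ".tsv"))
  }
  res$footprints <- fps

  # --- knockout losses -------------------------------------------------------
  loss_rows <- list(); fp_loss_tables <- list()
  for (tp in c("t1", "t2")) {
    ctrl <- paste0(tp, "_control"); ko <- paste0(tp, "_ko")
    if (is.null(open[[ctrl]]) || is.null(open[[ko]])) {
      say("[loss] %s: knockout cell missing, stage skipped", tp)
      loss_rows[[tp]] <- data.frame(timepoint = tp, region_loss = NA,
                                    footprint_loss_focal = NA,
                                    status = "skipped")
      next
    }
    rl <- region_loss(open[[ctrl]], open[[ko]])
    fl <- footprint_count_compare(fps[[ctrl]], fps[[ko]])
    fp_loss_tables[[tp]] <- fl
    wt(fl, paste0("footprint_loss_", tp, ".tsv"))
    focal <- cfg$focal_tf
    fl_focal <- if (!is.null(focal) && focal %in% fl$pwm_id)
      fl$lost_fraction[fl$pwm_id == focal] else NA_real_
    loss_rows[[tp]] <- data.frame(timepoint = tp,
                                  region_loss = rl$lost_fraction,
                                  footprint_loss_focal = fl_focal,
                                  status = "ok")
  }
  res$losses <- do.call(rbind, loss_rows)
  wt(res$losses, "knockout_loss.tsv")
  res$footprint_loss <- fp_loss_tables

  # --- pioneer analysis ------------------------------------------------------
  if (all(c("t1_control", "t2_control") %in% names(cuts))) {
    say("[pioneer] opening indexes across timepoints")
    st <- motif_site_table(sites, open$t1_control, open$t2_control,
                           fps$t1_control, fps$t2_control)
    ptab <- pioneer_table(st, deg = deg_dev)
    wt(ptab, "pioneer_table.tsv")
    res$pioneer <- ptab
    ks <- tryCatch(pioneer_ks(ptab), error = function(e) NULL)
    if (!is.null(ks)) {
      res$pioneer_ks <- ks
      wt(data.frame(D = ks$D, p = ks$p, p_greater = ks$p_greater,
                    n_de = ks$n_de, n_nonde = ks$n_nonde),
         "pioneer_ks.tsv")
    }
  }

  # --- ChIP integration ------------------------------------------------------
  for (tp in c("t1", "t2")) {
    ch <- cfg$chip[[tp]]
    if (is.null(ch)) next
    reps <- lapply(ch$replicates, function(p)
      read_intervals(.cfg_path(cfg, p), "narrowPeak"))
    sig <- read_cut_track(.cfg_path(cfg, ch$signal), chrom_lengths)
    ctl <- read_cut_track(.cfg_path(cfg, ch$control), chrom_lengths)
    say("[chip] %s: high-confidence peaks from %d replicates",
        tp, length(reps))
    hc <- high_confidence_peaks(reps, sig, ctl)
    write_intervals(hc, file.path(outdir,
                                  paste0("chip_hc_", tp, ".narrowPeak")),
                    "narrowPeak")
    if (nrow(hc) == 0L) next
    ann <- nearest_tss(hc, tss)
    wt(ann, paste0("chip_targets_", tp, ".tsv"))
    targets <- unique(ann$gene[!is.na(ann$gene)])
    res[[paste0("chip_targets_", tp)]] <- targets
    expr_p <- cfg$expression[[tp]]
    universe <- if (!is.null(expr_p)) {
      ex <- read_table_typed(.cfg_path(cfg, expr_p), "expression")
      union(ex$gene[ex$fpkm >= 1], targets)
    } else union(tss$gene, targets)
    if (!is.null(gene_sets)) {
      enr <- celltype_enrichment(targets, gene_sets, universe)
      wt(enr, paste0("celltype_enrichment_", tp, ".tsv"))
      res[[paste0("celltype_enrichment_", tp)]] <- enr
    }
    deg_ko_p <- cfg$deg_ko[[tp]]
    if (!is.null(deg_ko_p) && file.exists(.cfg_path(cfg, deg_ko_p))) {
      dk <- read_table_typed(.cfg_path(cfg, deg_ko_p), "deg")
      dep <- classify_dependence(targets, dk)
      wt(data.frame(gene = names(dep), dependence = unname(dep)),
         paste0("dependence_", tp, ".tsv"))
      res[[paste0("dependence_", tp)]] <- dep
    }
    # occupancy vs accessibility at high-confidence peaks
    atac_cell <- paste0(tp, "_control")
    if (!is.null(cuts[[atac_cell]])) {
      cov_of <- function(tr) vapply(seq_len(nrow(hc)), function(i)
        sum(tr$counts[[hc$chrom[i]]][(hc$start[i] + 1L):hc$end[i]]) *
          1e6 / tr$library_size, 0)
      oc <- occupancy_accessibility_corr(cov_of(sig),
                                         cov_of(cuts[[atac_cell]]))
      res[[paste0("occupancy_corr_", tp)]] <- oc
      wt(data.frame(r = oc$r, t = oc$t, p = oc$p, n = oc$n),
         paste0("occupancy_corr_", tp, ".tsv"))
    }
  }

  # --- summary ---------------------------------------------------------------
  s <- c("# Pipeline summary", "",
         sprintf("- seed: %d", seed),
         sprintf("- open regions: %s",
                 paste(sprintf("%s=%d", names(open),
                               vapply(open, nrow, 1L)), collapse = ", ")))
  if (!is.null(res$jaccard))
    s <- c(s, sprintf("- Jaccard t1 vs t2 (bp): %.4f; (count): %.4f",
                      res$jaccard$jaccard_bp, res$jaccard$jaccard_count))
  if (!is.null(res$losses))
    for (i in seq_len(nrow(res$losses)))
      s <- c(s, sprintf("- %s: region loss %.3f, focal footprint loss %s",
                        res$losses$timepoint[i], res$losses$region_loss[i],
                        format(res$losses$footprint_loss_focal[i])))
  if (!is.null(res$enrichment))
    s <- c(s, sprintf("- top enriched motif: %s (p = %.3g)",
                      res$enrichment$pwm_id[1],
                      res$enrichment$cum_binom_p[1]))
  if (!is.null(res$pioneer_ks))
    s <- c(s, sprintf("- pioneer KS (DE vs non-DE): D = %.3f, p = %.3g",
                      res$pioneer_ks$D, res$pioneer_ks$p))
  s <- c(s, sprintf("- elapsed: %.1f s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  writeLines(s, file.path(outdir, "summary.md"))
  say("[done] %s", outdir)
  invisible(res)
}

#' Sample random regions of given widths from a genome
#'
#' Uniformly placed, used as a background set for motif enrichment.
#'
#' @param chrom_lengths named integer vector.
#' @param widths integer vector of region widths.
#' @return a [peak_set()].
#' @export
random_regions <- function(chrom_lengths, widths) {
  n <- length(widths)
  ch <- sample(names(chrom_lengths), n, replace = TRUE,
               prob = chrom_lengths / sum(chrom_lengths))
  st <- vapply(seq_len(n), function(i)
    as.integer(floor(runif(1, 0, chrom_lengths[[ch[i]]] - widths[i]))),
    integer(1))
  peak_set(ch, st, st + widths, set_name = "random_background")
}
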