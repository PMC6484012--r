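# Cross-assay integration: target-gene enrichment in cell-type gene sets,
# knockout-dependence classification, and occupancy-accessibility
# correlation. Pipeline orchestration lives in pipeline.R.

#' Cell-type gene-set enrichment of target genes (Fisher's exact test)
#'
#' One-sided Fisher exact test per gene set on the 2x2 table of target
#' membership versus set membership over a gene universe, with
#' multiple-testing adjustment.
#'
#' @param targets character vector of target genes.
#' @param gene_sets data.frame (set_name, gene) or named list of gene
#'   vectors.
#' @param universe character vector containing all annotated genes
#'   (must cover targets and set members; members outside it are dropped).
#' @param adjust "BH" (default) or "bonferroni".
#' @return data.frame per set: set_name, k (targets in set), n (targets),
#'   K (set genes in universe), N (universe size), odds_ratio, p, p_adj;
#'   sets disjoint from the universe yield an NA row.
#' @export
celltype_enrichment <- function(targets, gene_sets, universe,
                                adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (length(targets) == 0L) stop("empty target list")
  if (is.data.frame(gene_sets))
    gene_sets <- split(gene_sets$gene, gene_sets$set_name)
  targets <- unique(targets)
  universe <- unique(universe)
  bad <- setdiff(targets, universe)
  if (length(bad))
    stop(length(bad), " target gene(s) missing from the universe")
  n <- length(targets); N <- length(universe)
  rows <- lapply(names(gene_sets), function(sn) {
    set <- intersect(unique(gene_sets[[sn]]), universe)
    K <- length(set)
    if (K == 0L)
      return(data.frame(set_name = sn, k = NA_integer_, n = n,
                        K = 0L, N = N, odds_ratio = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    k <- length(intersect(targets, set))
    tab <- matrix(c(k, n - k, K - k, N - n - K + k), nrow = 2)
    ft <- fisher.test(tab, alternative = "greater")
    data.frame(set_name = sn, k = k, n = n, K = K, N = N,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  meth <- if (adjust == "BH") "BH" else "bonferroni"
  out$p_adj <- p.adjust(out$p, method = meth)
  out[order(out$p), , drop = FALSE]
}

#' Classify knockout dependence of target genes
#'
#' A gene is "up" when its knockout-vs-control q-value is below `q_thr`
#' with positive log2 fold change, "down" with negative, otherwise "ns";
#' genes absent from the DEG table get NA.
#'
#' @param genes character vector of genes to classify.
#' @param deg_ko DEG table (gene, log2FC, q) for knockout vs control.
#' @param q_thr significance threshold (default 0.05).
#' @return character vector ("up"/"down"/"ns"/NA) named by gene.
#' @export
classify_dependence <- function(genes, deg_ko, q_thr = 0.05) {
  i <- match(genes, deg_ko$gene)
  out <- ifelse(is.na(i), NA_character_,
                ifelse(deg_ko$q[i] < q_thr & deg_ko$log2FC[i] > 0, "up",
                       ifelse(deg_ko$q[i] < q_thr & deg_ko$log2FC[i] < 0,
                              "down", "ns")))
  setNames(out, genes)
}

#' Correlation between occupancy and accessibility at target sites
#'
#' Pearson correlation of log-transformed per-peak coverages, with the
#' classical t statistic t = r * sqrt((n-2)/(1-r^2)) and its two-tailed
#' p-value (n-2 df). Inputs are expected per-million normalized; a
#' pseudocount of 1 is added before the log.
#'
#' @param chip_cov,atac_cov paired numeric vectors (n >= 3).
#' @param log_transform apply log2(x + 1) first (default TRUE).
#' @return list: r, t, p, n (all NA with a `reason` when either vector
#'   has zero variance).
#' @export
occupancy_accessibility_corr <- function(chip_cov, atac_cov,
                                         log_transform = TRUE) {
  stopifnot(length(chip_cov) == length(atac_cov))
  n <- length(chip_cov)
  if (n < 3L) stop("need n >= 3 paired coverages")
  x <- if (log_transform) log2(chip_cov + 1) else chip_cov
  y <- if (log_transform) log2(atac_cov + 1) else atac_cov
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, t = NA_real_, p = NA_real_, n = n,
                reason = "zero variance"))
  r <- cor(x, y)
  if (abs(r) >= 1) {
    t <- Inf * sign(r); p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t), df = n - 2)
  }
  list(r = r, t = t, p = p, n = n)
}
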