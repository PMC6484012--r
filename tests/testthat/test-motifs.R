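# PWM machinery: scanning with exact p-values, similarity, clustering,
# binomial enrichment and randomization FDR.

test_that("log-odds scores and p-values match hand arithmetic", {
  # single-column PWM from the JASPAR pseudocount example
  p1 <- pwm(matrix(c(10.25, 0.25, 0.25, 0.25) / 11, 4, 1), id = "one")
  hits <- scan_pwm(c(s = "A"), p1, pvalue = 1)
  plus <- hits[hits$strand == "+", ]
  expect_equal(plus$score, log2((10.25 / 11) / 0.25), tolerance = 1e-9)
  # p-value of the maximal score = probability of the best base = 0.25
  expect_equal(plus$p_value, 0.25, tolerance = 1e-12)
  # consensus sequence scores the column-wise maximum
  p2 <- cons_pwm("ACGT", weight = 0.7)
  hits2 <- scan_pwm(c(s = "ACGT"), p2, pvalue = 1)
  expect_equal(max(hits2$score), 4 * log2(0.7 / 0.25), tolerance = 1e-9)
})

test_that("scan p-values match exhaustive word enumeration (w <= 8)", {
  set.seed(41)
  for (w in c(3L, 5L, 8L)) {
    m <- matrix(runif(4 * w, 0.05, 1), 4, w)
    m <- sweep(m, 2, colSums(m), "/")
    p <- pwm(m, id = "rnd")
    d <- pwm_score_distribution(p)
    expect_equal(sum(d$prob), 1, tolerance = 1e-9)
    # enumerate all 4^w words under the uniform background
    lo <- log2(m / 0.25)
    words <- as.matrix(expand.grid(rep(list(1:4), w)))
    scores <- rowSums(matrix(lo[cbind(as.vector(words),
                                      rep(seq_len(w), each = 4^w))],
                             ncol = w))
    # pointwise tails, queried at midpoints of well-separated levels
    # (CDF agreement there pins down the whole distribution)
    gaps <- diff(d$score)
    mid_ok <- which(gaps > 1e-4)
    probe <- d$score[mid_ok] + gaps[mid_ok] / 2
    probe <- sample(probe, min(20, length(probe)))
    for (s in probe)
      expect_equal(d$pvalue(s), mean(scores >= s), tolerance = 1e-9)
    # and exactly at a level, including that level's mass
    lev <- d$score[which.max(d$prob)]
    expect_equal(d$pvalue(lev), mean(scores >= lev - 1e-6),
                 tolerance = 1e-9)
  }
})

test_that("scan respects thresholds, strands and N handling", {
  p <- cons_pwm("ACGTAC", id = "m")
  g <- c(chr1 = "TTTTACGTACTTTTT")
  hits <- scan_pwm(g, p, pvalue = 1e-3)
  expect_true(any(hits$strand == "+" & hits$start == 4L))
  # threshold above the maximal attainable score -> empty
  expect_equal(nrow(scan_pwm(g, p, score_min = 100)), 0L)
  # palindromic PWM: every + match mirrored on - at the same locus
  pal <- cons_pwm("ACGT", id = "pal")
  hp <- scan_pwm(c(chr1 = "GGACGTGG"), pal, pvalue = 1)
  plus <- hp[hp$strand == "+", c("start", "score")]
  minus <- hp[hp$strand == "-", c("start", "score")]
  expect_equal(plus$start, minus$start)
  expect_equal(plus$score, minus$score, tolerance = 1e-9)
  # windows containing N are skipped
  hn <- scan_pwm(c(chr1 = "ACGNTAC"), cons_pwm("ACGT"), pvalue = 1)
  expect_false(any(hn$start <= 3L & hn$start + 4L > 3L &
                     hn$start < 4L))
})

test_that("pwm similarity: identity, reverse complement, degenerate", {
  p <- cons_pwm("AAACCGTG", id = "p")   # non-palindromic consensus
  s <- pwm_similarity(p, p)
  expect_equal(s$cor, 1, tolerance = 1e-12)
  expect_equal(s$ncor, 1, tolerance = 1e-12)
  expect_equal(s$offset, 0L)
  expect_equal(s$strand, "+")
  # reverse complement detected on the minus orientation
  rc <- pioneerscan:::pwm_revcomp(p)
  s2 <- pwm_similarity(p, rc)
  expect_equal(s2$cor, 1, tolerance = 1e-12)
  expect_equal(s2$strand, "-")
  # uniform matrix has zero variance -> cor defined as 0
  unif <- pwm(matrix(0.25, 4, 6), id = "u")
  s3 <- pwm_similarity(p, unif)
  expect_equal(s3$cor, 0)
  expect_equal(s3$ncor, 0)
  # too short for the overlap requirement
  expect_error(pwm_similarity(cons_pwm("ACG"), cons_pwm("ACG")),
               "too short")
})

test_that("pwm similarity is symmetric and |ncor| <= |cor|", {
  set.seed(51)
  for (i in 1:6) {
    w1 <- sample(5:10, 1); w2 <- sample(5:10, 1)
    m1 <- matrix(runif(4 * w1), 4, w1); m1 <- sweep(m1, 2, colSums(m1), "/")
    m2 <- matrix(runif(4 * w2), 4, w2); m2 <- sweep(m2, 2, colSums(m2), "/")
    a <- pwm(m1, "a"); b <- pwm(m2, "b")
    sab <- pwm_similarity(a, b); sba <- pwm_similarity(b, a)
    expect_equal(sab$ncor, sba$ncor, tolerance = 1e-9)
    expect_equal(sab$aligned_width, sba$aligned_width)
    expect_lte(abs(sab$ncor), abs(sab$cor) + 1e-12)
  }
})

test_that("clustering groups duplicates and separates unrelated motifs", {
  set.seed(61)
  base <- list(cons_pwm("ACGTACGTAA", "m1"), cons_pwm("TTGACCATGG", "m2"),
               cons_pwm("GGGTTTACAC", "m3"))
  dup <- c(base, lapply(base, function(p) pwm(p$matrix,
                                              paste0(p$id, "_dup"))))
  cl <- cluster_pwms(dup)
  for (i in 1:3)
    expect_equal(cl$membership[i], cl$membership[i + 3])
  expect_equal(length(unique(cl$membership)), 3L)
  # thresholds cor = ncor = 1 keep everything singleton except duplicates
  cl2 <- cluster_pwms(dup, cor_thr = 1, ncor_thr = 1)
  expect_equal(length(unique(cl2$membership)), 3L)
  cl3 <- cluster_pwms(base, cor_thr = 1, ncor_thr = 1)
  expect_equal(length(unique(cl3$membership)), 3L)
})

test_that("three-motif clustering equals brute-force pair thresholding", {
  # A ~ B (one column nudged), C unrelated
  A <- cons_pwm("ACGTACGTAC", "A", weight = 0.85)
  mB <- A$matrix
  mB[, 3] <- c(0.70, 0.10, 0.10, 0.10)
  B <- pwm(mB, "B")
  C <- cons_pwm("TTTGGGCCCA", "C", weight = 0.85)
  sAB <- pwm_similarity(A, B)
  expect_gt(sAB$ncor, 0.8)
  cl <- cluster_pwms(list(A, B, C))
  expect_equal(cl$membership[1], cl$membership[2])
  expect_false(cl$membership[3] == cl$membership[1])
  expect_equal(nrow(cl$merges), 1L)
})

test_that("binomial enrichment p equals the exact binomial-sum oracle", {
  set.seed(71)
  # 10 fg regions, 6 seeded with the consensus; 10 bg regions, 2 seeded
  motif <- "ACGTTGCACG"
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  mk <- function(n, n_seeded, L = 60) {
    vapply(seq_len(n), function(i) {
      s <- rand_seq(L)
      if (i <= n_seeded) substr(s, 20, 29) <- motif
      s
    }, "")
  }
  fg_seqs <- mk(10, 6); bg_seqs <- mk(10, 2)
  fg_genome <- setNames(fg_seqs, paste0("f", 1:10))
  bg_genome <- setNames(bg_seqs, paste0("b", 1:10))
  fg <- peak_set(names(fg_genome), rep(0L, 10), rep(60L, 10))
  bg <- peak_set(names(bg_genome), rep(0L, 10), rep(60L, 10))
  p <- cons_pwm(motif, "planted", weight = 0.9)
  res <- binomial_enrichment(fg, fg_genome, bg, bg_genome, list(p),
                             resample_bg = FALSE)
  expect_equal(res$k_fg, 6L)
  expect_equal(res$p0_bg, 0.2)
  # worked case: P(X >= 6), X ~ Binomial(10, 0.2) ~ 6.37e-3
  expect_equal(res$cum_binom_p, binom_tail_oracle(6, 10, 0.2),
               tolerance = 1e-12)
  expect_equal(res$cum_binom_p, 6.36938e-3, tolerance = 1e-5)
  # k = 0 -> p = 1
  never <- cons_pwm("GGGGGGGGGG", "absent", weight = 0.97)
  res0 <- binomial_enrichment(fg, fg_genome, bg, bg_genome, list(never),
                              resample_bg = FALSE)
  expect_equal(res0$cum_binom_p, 1)
})

test_that("unplanted foreground is not spuriously enriched", {
  # fg drawn from the same source as bg: p should be unremarkable
  set.seed(81)
  n_small <- 0
  for (rep in 1:20) {
    g <- make_genome(sim_config(n_chroms = 1L, chrom_length = 1e4))
    st <- seq(100L, 9000L, by = 450L)[1:20]
    regions <- peak_set("chr1", st, st + 60L)
    fg <- regions[1:10, ]; bg <- regions[11:20, ]
    p <- cons_pwm("ACGTTGCACG", "null", weight = 0.9)
    res <- binomial_enrichment(fg, g, bg, g, list(p))
    if (res$cum_binom_p < 0.05) n_small <- n_small + 1
  }
  expect_lte(n_small, 4)   # ~binomial(20, .05) upper tail
})

test_that("planted motifs rank first with near-zero randomization FDR", {
  set.seed(91)
  motif <- "ACGTTGCACG"
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  fg_seqs <- vapply(1:15, function(i) {
    s <- rand_seq(80)
    substr(s, 30, 39) <- motif    # every fg region seeded
    s
  }, "")
  bg_seqs <- vapply(1:15, function(i) rand_seq(80), "")
  fg_genome <- setNames(fg_seqs, paste0("f", 1:15))
  bg_genome <- setNames(bg_seqs, paste0("b", 1:15))
  fg <- peak_set(names(fg_genome), rep(0L, 15), rep(80L, 15))
  bg <- peak_set(names(bg_genome), rep(0L, 15), rep(80L, 15))
  pwms <- list(cons_pwm(motif, "planted"), cons_pwm("TTACGGATCC", "d1"),
               cons_pwm("GGCATTAGCC", "d2"))
  res <- enrichment_fdr(fg, fg_genome, bg, bg_genome, pwms,
                        n_randomizations = 2)
  expect_equal(res$pwm_id[1], "planted")
  expect_lt(res$fdr[1], 0.5)
  expect_error(enrichment_fdr(fg, fg_genome, bg, bg_genome, pwms,
                              n_randomizations = 0), "n_randomizations")
  # determinism under a fixed seed
  set.seed(123)
  a <- enrichment_fdr(fg, fg_genome, bg, bg_genome, pwms)
  set.seed(123)
  b <- enrichment_fdr(fg, fg_genome, bg, bg_genome, pwms)
  expect_identical(a, b)
})
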