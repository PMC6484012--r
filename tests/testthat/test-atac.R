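# ATAC signal layer: cut conversion, Poisson open-region calling,
# footprints, nucleosome occupancy, meta-profiles, replicate peaks,
# NFR-nucleosome pairing.

test_that("fragment ends convert to cuts with and without Tn5 offsets", {
  fr <- fragment_set("chr1", 100L, 200L)
  cl <- c(chr1 = 300L)
  raw <- cuts_from_fragments(fr, cl, offset_correction = FALSE)
  expect_equal(which(raw$counts$chr1 > 0) - 1L, c(100L, 199L))
  cor <- cuts_from_fragments(fr, cl, offset_correction = TRUE)
  expect_equal(which(cor$counts$chr1 > 0) - 1L, c(104L, 194L))
  # empty fragment set -> all-zero track
  z <- cuts_from_fragments(fragment_set(character(), integer(),
                                        integer()), cl)
  expect_equal(z$library_size, 0)
})

test_that("cut conversion conserves counts and clips out-of-bounds", {
  set.seed(101)
  n <- 500L
  st <- sample.int(5000L, n)
  fr <- fragment_set("chr1", st, st + sample(30:250, n, replace = TRUE))
  tr <- cuts_from_fragments(fr, c(chr1 = 6000L),
                            offset_correction = FALSE)
  expect_equal(tr$library_size, 2 * n)
  # a fragment whose minus cut shifts past the edge gets clipped
  edge <- fragment_set("chr1", 0L, 4L)
  expect_warning(tr2 <- cuts_from_fragments(edge, c(chr1 = 10L),
                                            offset_correction = TRUE),
                 "clipped")
  expect_equal(tr2$library_size, 1)  # only the +4 plus-end cut survives
})

test_that("open-region calling recovers planted regions and gates on fold", {
  set.seed(111)
  L <- 2e5
  rate <- rep(0.05, L)
  planted <- data.frame(start = c(2e4, 8e4, 15e4))
  planted$end <- planted$start + 500
  for (i in 1:3) rate[(planted$start[i] + 1):planted$end[i]] <- 1.0 # 20x
  ct <- cut_track(list(chr1 = rpois(L, rate)))
  op <- call_open_regions(ct)
  truth <- peak_set("chr1", planted$start, planted$end)
  expect_equal(sum(pioneerscan:::overlaps_any_peak(truth, op)), 3L)
  # every called region overlaps a planted one (no false positives here)
  expect_true(all(pioneerscan:::overlaps_any_peak(op, truth)))
  # fold-2 region is blocked by the min-FE gate even though p is tiny
  rate2 <- rep(1, L)
  rate2[50001:51000] <- 3.9
  ct2 <- cut_track(list(chr1 = rpois(L, rate2)))
  op_gated <- call_open_regions(ct2, min_fold = 4)
  op_open <- call_open_regions(ct2, min_fold = 3)
  reg2 <- peak_set("chr1", 50000L, 51000L)
  expect_equal(sum(pioneerscan:::overlaps_any_peak(reg2, op_gated)), 0L)
  expect_equal(sum(pioneerscan:::overlaps_any_peak(reg2, op_open)), 1L)
  # all-zero track -> empty peak set
  expect_equal(nrow(call_open_regions(cut_track(list(chr1 =
                                                       numeric(1000))))),
               0L)
})

test_that("homogeneous Poisson tracks yield false positives within 3 sigma", {
  set.seed(121)
  L <- 5e5; lambda_bg <- 0.5
  ct <- cut_track(list(chr1 = rpois(L, lambda_bg)))
  op <- call_open_regions(ct, p_threshold = 1e-4, min_fold = 1)
  n_windows <- length(seq(1L, L - 300L + 1L, by = 50L))
  # each called region arises from >= 1 significant window
  expect_lte(nrow(op), 1e-4 * n_windows + 3 * sqrt(1e-4 * n_windows) + 1)
})

test_that("footprint scores and depletion p match hand arithmetic", {
  L <- 1000L
  # flank mean 3 cuts/bp, center 0: score = log2(3.5 / 0.5)
  x <- rep(3, L); x[401:410] <- 0
  ct <- cut_track(list(chr1 = x))
  sites <- data.frame(chrom = "chr1", start = 400L, end = 410L,
                      pwm_id = "m", strand = "+")
  fp <- detect_footprints(ct, sites)
  expect_equal(fp$score, log2(3.5 / 0.5), tolerance = 1e-12)
  expect_true(fp$called)
  # flank mean == center mean -> score 0, not a footprint
  y <- rep(10, L)
  fp0 <- detect_footprints(cut_track(list(chr1 = y)), sites)
  expect_equal(fp0$score, 0)
  expect_false(fp0$called)
  # closed form: 110 cuts all in the flanks, center width 10 of 110
  z <- numeric(L); z[351:400] <- 1; z[411:460] <- 1; z[351:360] <- 2
  stopifnot(sum(z) == 110)
  fpz <- detect_footprints(cut_track(list(chr1 = z)), sites)
  expect_equal(fpz$depletion_p, (100 / 110)^110, tolerance = 1e-9)
  # site too close to the edge is skipped and counted
  edge_sites <- data.frame(chrom = "chr1", start = 10L, end = 20L,
                           pwm_id = "m", strand = "+")
  fpe <- detect_footprints(ct, edge_sites)
  expect_equal(nrow(fpe), 0L)
  expect_equal(attr(fpe, "n_skipped"), 1L)
})

test_that("null cut tracks call footprints at no more than the nominal rate", {
  set.seed(131)
  n_sites <- 50L; n_seeds <- 20L
  fp_rates <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    x <- rpois(6e4, 2)
    ct <- cut_track(list(chr1 = x))
    pos <- seq(600L, 59000L, length.out = n_sites)
    sites <- data.frame(chrom = "chr1", start = as.integer(pos),
                        end = as.integer(pos) + 10L, pwm_id = "m",
                        strand = "+")
    fp <- detect_footprints(ct, sites)
    fp_rates[s] <- mean(fp$called)
  }
  q_thr <- 0.05
  expect_lte(mean(fp_rates),
             q_thr + 3 * sqrt(q_thr * (1 - q_thr) / (n_seeds * n_sites)))
})

test_that("planted depletion at adequate depth is detected sensitively", {
  set.seed(141)
  L <- 1.2e5
  rate <- rep(2, L)   # >= 30 flank cuts over 100 flank bases
  pos <- seq(1000L, L - 1000L, by = 1200L)
  for (p in pos) rate[(p + 1):(p + 10)] <- 0.2   # depletion factor 0.1
  ct <- cut_track(list(chr1 = rpois(L, rate)))
  sites <- data.frame(chrom = "chr1", start = pos, end = pos + 10L,
                      pwm_id = "m", strand = "+")
  fp <- detect_footprints(ct, sites)
  expect_gte(mean(fp$called), 0.95)
})

test_that("footprint score comparison matches the textbook t test", {
  mk <- function(scores) data.frame(chrom = "chr1",
                                    start = seq_along(scores) * 100L,
                                    end = seq_along(scores) * 100L + 10L,
                                    pwm_id = "m", strand = "+",
                                    center = seq_along(scores) * 100L + 5L,
                                    score = scores, depletion_p = 0.01,
                                    q = 0.01, flank_cuts = 100,
                                    center_cuts = 1, called = TRUE)
  # identical vectors -> t = 0, p = 1
  same <- footprint_score_test(mk(c(1, 2, 3)), mk(c(1, 2, 3)))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # hand vectors (1,2,3) vs (2,3,4): Welch equals pooled here (equal var)
  res <- footprint_score_test(mk(c(1, 2, 3)), mk(c(2, 3, 4)))
  se <- sqrt(1 / 3 + 1 / 3)
  t_hand <- (2 - 3) / se
  df_hand <- 4   # Welch df with equal n and equal variance
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)
  # strong separation
  sep <- footprint_score_test(mk(c(2, 2.01, 1.99, 2)),
                              mk(c(0, 0.01, -0.01, 0)))
  expect_lt(sep$p, 0.01)
  expect_error(footprint_score_test(mk(1), mk(c(1, 2))), ">= 2")
})

test_that("footprint loss counts unmatched control footprints", {
  mk <- function(centers, pwm = "m", called = TRUE)
    data.frame(chrom = "chr1", start = centers - 5L, end = centers + 5L,
               pwm_id = pwm, strand = "+", center = centers, score = 2,
               depletion_p = 1e-4, q = 1e-4, flank_cuts = 100,
               center_cuts = 0, called = called)
  ctrl <- mk(c(100L, 500L, 900L, 1300L))
  expect_equal(footprint_loss(ctrl, ctrl), 0)
  expect_equal(footprint_loss(ctrl, ctrl[0, ]), 1)
  # half matched within 10 bp, half not
  ko <- mk(c(105L, 492L, 2000L, 3000L))
  expect_equal(footprint_loss(ctrl, ko), 0.5)
  # same position but different factor does not rescue
  ko2 <- mk(c(100L, 500L, 900L, 1300L), pwm = "other")
  expect_equal(footprint_loss(ctrl, ko2), 1)
  expect_error(footprint_loss(ctrl[0, ], ko), "no called")
})

test_that("nucleosome occupancy peaks at midpoints and phases at spacing", {
  # single nucleosomal fragment: maximum at its midpoint
  fr <- fragment_set("chr1", 1000L, 1180L)
  occ <- nucleosome_occupancy(fr, "chr1", 900L, 1300L)
  expect_equal(900L + which.max(occ) - 1L, 1090L, tolerance = 1)
  # no nucleosomal fragments -> zeros
  nfr_only <- fragment_set("chr1", 1000L, 1050L)
  expect_equal(sum(nucleosome_occupancy(nfr_only, "chr1", 900L, 1300L)),
               0)
  # dyads planted every 200 bp: occupancy autocorrelation peaks near 200
  set.seed(151)
  dyads <- seq(500L, 9500L, by = 200L)
  n_per <- rpois(length(dyads), 15)
  mids <- unlist(mapply(function(d, n) round(rnorm(n, d, 10)),
                        dyads, n_per))
  lens <- pmax(150, pmin(250, round(rnorm(length(mids), 185, 15))))
  fr2 <- fragment_set("chr1", as.integer(mids - lens %/% 2),
                      as.integer(mids - lens %/% 2 + lens))
  occ2 <- nucleosome_occupancy(fr2, "chr1", 0L, 10000L)
  ac <- acf(occ2, lag.max = 300, plot = FALSE)$acf[, 1, 1]
  side <- 100 + which.max(ac[101:301]) - 1
  expect_true(abs(side - 200) <= 10)
})

test_that("metaprofiles align, reverse minus strands and difference to zero", {
  x <- c(chr1 = list(seq(0, 999)))
  centers <- data.frame(chrom = "chr1", pos = 500L, strand = "+")
  prof <- metaprofile(x, centers, halfwidth = 10L)
  expect_equal(prof$mean, 490:510)
  # minus strand reverses the window
  centers_m <- data.frame(chrom = "chr1", pos = 500L, strand = "-")
  prof_m <- metaprofile(x, centers_m, halfwidth = 10L)
  expect_equal(prof_m$mean, rev(490:510))
  # constant signal -> flat profile; self-difference -> zero
  const <- list(chr1 = rep(7, 1000))
  centers2 <- data.frame(chrom = "chr1", pos = c(200L, 600L),
                         strand = c("+", "-"))
  p2 <- metaprofile(const, centers2, halfwidth = 50L, signal2 = const)
  expect_true(all(p2$mean == 7))
  expect_true(all(p2$diff == 0))
  expect_error(metaprofile(const,
                           data.frame(chrom = "chr1", pos = 5L,
                                      strand = "+"), halfwidth = 50L),
               "out of bounds")
})

test_that("high-confidence peaks require replicate support and the FE gate", {
  set.seed(161)
  L <- 5e4
  truth_pos <- c(5000L, 15000L, 30000L, 42000L)
  rate <- rep(0.02, L)
  for (p in truth_pos) rate[(p - 100):(p + 100)] <- 1
  sig <- cut_track(list(chr1 = rpois(L, rate)))
  ctl <- cut_track(list(chr1 = rpois(L, 0.02)))
  reps <- lapply(1:2, function(r)
    peak_set("chr1", truth_pos - 100L, truth_pos + 100L))
  hc <- high_confidence_peaks(reps, sig, ctl)
  expect_equal(nrow(hc), 4L)
  # a peak in only one replicate is dropped
  reps2 <- list(peak_set("chr1", c(truth_pos - 100L, 25000L),
                         c(truth_pos + 100L, 25400L)),
                peak_set("chr1", truth_pos - 100L, truth_pos + 100L))
  hc2 <- high_confidence_peaks(reps2, sig, ctl)
  lone <- peak_set("chr1", 25000L, 25400L)
  expect_equal(sum(pioneerscan:::overlaps_any_peak(lone, hc2)), 0L)
  expect_error(high_confidence_peaks(reps[1], sig, ctl), ">= 2")
  # fold enrichment below min_FE is dropped regardless of p
  rate3 <- rep(1, L); rate3[20001:21000] <- 3.9
  sig3 <- cut_track(list(chr1 = pmin(rpois(L, rate3), 1)))
  ctl3 <- cut_track(list(chr1 = pmin(rpois(L, 1), 1)))
  reps3 <- lapply(1:2, function(r) peak_set("chr1", 20000L, 21000L))
  hc3 <- high_confidence_peaks(reps3, sig3, ctl3)
  expect_equal(nrow(hc3), 0L)
})

test_that("NFR-nucleosome pairing finds planted pairs and breaks ties left", {
  # one dyad at 1000, NFR (cut maximum) at 1400 inside a 2 kb region
  L <- 3000L
  occ <- list(chr1 = dnorm(seq_len(L), 1000, 30))
  cuts <- cut_track(list(chr1 = round(dnorm(seq_len(L), 1400, 40) * 4000)))
  open <- peak_set("chr1", 200L, 2600L)
  pr <- nfr_nucleosome_pairs(open, occ, cuts, min_distance = 300L)
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$distance, 400L, tolerance = 5)
  expect_gt(pr$differential, 0)
  # uniform signal -> no pairs
  flat <- cut_track(list(chr1 = rep(1, L)))
  occ_flat <- list(chr1 = rep(1, L))
  expect_equal(nrow(nfr_nucleosome_pairs(open, occ_flat, flat)), 0L)
  # region shorter than min_distance skipped
  tiny <- peak_set("chr1", 200L, 400L)
  expect_equal(nrow(nfr_nucleosome_pairs(tiny, occ, cuts)), 0L)
})
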