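# Interval statistics: Jaccard, co-occurrence, feature enrichment,
# nearest-TSS annotation, knockout region loss.

gl <- 1e6

test_that("jaccard handles identity, disjoint sets and the worked case", {
  A <- peak_set("chr1", c(0L, 1000L), c(100L, 1200L), genome_length = gl)
  B <- peak_set("chr1", c(5000L, 9000L), c(5100L, 9050L),
                genome_length = gl)
  expect_equal(jaccard(A, A, "bp"), 1)
  expect_equal(jaccard(A, A, "count"), 1)
  expect_equal(jaccard(A, B, "bp"), 0)
  expect_equal(jaccard(A, B, "count"), 0)
  # A = chr1:[0,100), B = chr1:[50,150) -> 50 / 150
  a <- peak_set("chr1", 0L, 100L)
  b <- peak_set("chr1", 50L, 150L)
  expect_equal(jaccard(a, b, "bp"), 1 / 3)
  expect_warning(
    expect_equal(jaccard(peak_set(character(), integer(), integer()),
                         peak_set(character(), integer(), integer())), 0),
    "empty")
})

test_that("jaccard is symmetric and non-increasing as B translates away", {
  set.seed(11)
  st <- sort(sample.int(1e5, 30)) * 10L
  A <- merge_peaks(peak_set("chr1", st, st + 400L))
  prev_bp <- Inf
  for (shift in c(0L, 100L, 200L, 400L, 1000L, 5000L)) {
    B <- peak_set("chr1", A$start + shift, A$end + shift)
    jb <- jaccard(A, B, "bp")
    expect_equal(jb, jaccard(B, A, "bp"))
    expect_equal(jaccard(A, B, "count"), jaccard(B, A, "count"))
    expect_lte(jb, prev_bp + 1e-12)
    prev_bp <- jb
  }
})

# build a co-occurrence geometry with known k, n, K over N universe regions
cooccur_fixture <- function(N, K, n, k) {
  stopifnot(k <= min(n, K))
  centers <- (seq_len(N)) * 10000L
  universe <- peak_set("chr1", centers - 500L, centers + 500L,
                       summit_offset = rep(500L, N))
  # B summits at the midpoints of the first K regions
  B <- peak_set("chr1", centers[seq_len(K)] - 50L,
                centers[seq_len(K)] + 50L,
                summit_offset = rep(50L, K))
  # A matched to regions 1..k (within 20 bp of the B summit) and to
  # regions (K+1)..(K+n-k) (confocal but no B nearby)
  a_centers <- c(centers[seq_len(k)] + 10L,
                 if (n > k) centers[(K + 1):(K + n - k)] + 100L)
  A <- peak_set("chr1", a_centers - 50L, a_centers + 50L,
                summit_offset = rep(50L, n))
  list(A = A, B = B, universe = universe)
}

test_that("co-occurrence counts and ln p match exact enumeration", {
  fx <- cooccur_fixture(N = 10, K = 4, n = 5, k = 3)
  res <- cooccurrence_test(fx$A, fx$B, fx$universe)
  expect_equal(res$N, 10); expect_equal(res$K, 4)
  expect_equal(res$n, 5); expect_equal(res$k, 3)
  # P(X >= 3) = 66/252
  expect_equal(exp(res$ln_p), 66 / 252, tolerance = 1e-12)
  expect_equal(res$ln_p, log(66 / 252), tolerance = 1e-9)
})

test_that("co-occurrence ln p equals the enumeration oracle for N <= 20", {
  set.seed(21)
  for (rep in 1:12) {
    N <- sample(4:20, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    k_range <- max(0, n + K - N):min(n, K)
    k <- k_range[sample.int(length(k_range), 1)]
    fx <- cooccur_fixture(N, K, n, k)
    res <- cooccurrence_test(fx$A, fx$B, fx$universe)
    expect_equal(c(res$k, res$n, res$K, res$N), c(k, n, K, N))
    expect_equal(exp(res$ln_p), hyper_tail_oracle(k, N, K, n),
                 tolerance = 1e-10)
  }
})

test_that("co-occurrence degenerate cases behave", {
  fx <- cooccur_fixture(N = 8, K = 3, n = 4, k = 0)
  res <- cooccurrence_test(fx$A, fx$B, fx$universe)
  expect_equal(res$ln_p, 0)          # P(X >= 0) = 1
  # A = B = universe: k = n = K = N, P(X >= N) = 1
  U <- fx$universe
  res2 <- cooccurrence_test(U, U, U)
  expect_equal(res2$k, res2$N)
  expect_equal(res2$ln_p, 0)
  expect_error(cooccurrence_test(fx$A, fx$B,
                                 peak_set(character(), integer(),
                                          integer())),
               "universe")
})

test_that("feature enrichment recovers planted category structure", {
  # genome 64 kb; one category covering 1/64 of it
  ann <- feature_annotation(
    list(promoter = peak_set("chr1", 0L, 1000L),
         exon = peak_set("chr1", 2000L, 10000L)),
    genome_length = 64000)
  expect_equal(sum(ann$genome_fractions), 1, tolerance = 1e-12)
  # all peaks inside the promoter category (1/64 of the genome)
  pk <- peak_set("chr1", seq(0L, 900L, by = 100L),
                 seq(0L, 900L, by = 100L) + 50L)
  fe <- feature_enrichment(pk, ann)
  expect_equal(sum(fe$peak_fraction), 1)
  expect_equal(fe$log2FE[fe$category == "promoter"], 6, tolerance = 1e-6)
  # peaks distributed proportionally to genome fractions -> log2FE ~ 0
  ann2 <- feature_annotation(
    list(promoter = peak_set("chr1", 0L, 32000L)),
    genome_length = 64000)
  half <- peak_set("chr1", c(1000L, 40000L), c(1100L, 40100L))
  fe2 <- feature_enrichment(half, ann2)
  expect_equal(fe2$log2FE, c(0, 0), tolerance = 1e-6)
  expect_error(feature_enrichment(peak_set(character(), integer(),
                                           integer()), ann),
               "empty")
})

test_that("nearest TSS assignment signs distances by gene strand", {
  tss <- data.frame(gene = c("minusGene", "plusGene"),
                    chrom = c("chr1", "chr1"),
                    tss = c(10000L, 50000L),
                    strand = c("-", "+"), stringsAsFactors = FALSE)
  # summit exactly at a TSS
  p0 <- peak_set("chr1", 49950L, 50050L, summit_offset = 50L)
  a0 <- nearest_tss(p0, tss)
  expect_equal(a0$gene, "plusGene")
  expect_equal(a0$distance, 0)
  # summit 500 bp 5' of the minus-strand gene = genomically downstream
  p1 <- peak_set("chr1", 10450L, 10550L, summit_offset = 50L)
  a1 <- nearest_tss(p1, tss)
  expect_equal(a1$gene, "minusGene")
  expect_equal(a1$distance, -500)
  # equidistant tie broken by lexicographically smaller gene name
  tss2 <- data.frame(gene = c("b_gene", "a_gene"), chrom = "chr1",
                     tss = c(900L, 1100L), strand = c("+", "+"),
                     stringsAsFactors = FALSE)
  p2 <- peak_set("chr1", 950L, 1050L, summit_offset = 50L)
  expect_equal(nearest_tss(p2, tss2)$gene, "a_gene")
  # peak on a chromosome absent from the table
  p3 <- peak_set("chrX", 0L, 100L)
  expect_warning(a3 <- nearest_tss(p3, tss), "absent")
  expect_true(is.na(a3$gene))
})

test_that("region loss is 0 on identity, 1 on empty, exact on construction", {
  set.seed(31)
  st <- sort(sample.int(9e4, 40)) * 10L
  ctrl <- merge_peaks(peak_set("chr1", st, st + 300L))
  expect_equal(region_loss(ctrl, ctrl)$lost_fraction, 0)
  none <- peak_set(character(), integer(), integer())
  expect_equal(region_loss(ctrl, none)$lost_fraction, 1)
  expect_error(region_loss(none, ctrl), "empty control")
  # delete exactly half the regions
  keep <- seq_len(nrow(ctrl)) %% 2L == 0L
  ko <- ctrl[keep, ]
  rl <- region_loss(ctrl, ko)
  expect_equal(rl$lost_fraction, 0.5)
  expect_equal(nrow(rl$lost) + nrow(rl$retained), nrow(ctrl))
  # invariant to interval order
  shuf <- ctrl[sample.int(nrow(ctrl)), ]
  expect_equal(region_loss(shuf, ko)$lost_fraction, 0.5)
})
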