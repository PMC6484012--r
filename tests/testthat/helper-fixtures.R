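# Shared fixtures, built in code. The small study bundle is expensive
# enough to build once and reuse across test files; it is cached in a
# package-local environment for the duration of the test run.

.fixture_env <- new.env(parent = emptyenv())

# a compact study configuration: same planted rates and fractions as the
# defaults, scaled down in genome size and gene count for test speed
small_sim_config <- function(...) {
  sim_config(n_chroms = 1L, chrom_length = 4e5, n_bg_regions = 40L,
             n_tfs = 5L, sites_per_tf = 20L, n_pioneers = 2L,
             n_genes = 300L, celltype_set_size = 30L,
             ko_footprint_loss_overrides = list(t1 = c(), t2 = c()),
             ...)
}

# one simulated study on disk plus its pipeline run, shared across tests
shared_study <- function() {
  if (!is.null(.fixture_env$study)) return(.fixture_env$study)
  dir <- file.path(tempdir(), "pioneerscan-shared-sim")
  bundle <- simulate_study(small_sim_config(), dir, seed = 424242)
  .fixture_env$study <- list(dir = dir, bundle = bundle)
  .fixture_env$study
}

shared_pipeline <- function() {
  if (!is.null(.fixture_env$pipe)) return(.fixture_env$pipe)
  st <- shared_study()
  out <- file.path(tempdir(), "pioneerscan-shared-out")
  res <- run_pipeline(file.path(st$dir, "config.json"), out, seed = 99,
                      verbose = FALSE)
  .fixture_env$pipe <- list(outdir = out, res = res)
  .fixture_env$pipe
}

# independent oracle: hypergeometric upper tail P(X >= k) by enumeration
hyper_tail_oracle <- function(k, N, K, n) {
  js <- max(k, 0):min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# independent oracle: binomial upper tail P(X >= k) by direct summation
binom_tail_oracle <- function(k, n, p) {
  if (k <= 0) return(1)
  js <- k:n
  sum(choose(n, js) * p^js * (1 - p)^(n - js))
}

# independent oracle: exact two-sample KS p by full enumeration of splits
ks_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x); n <- length(y)
  ks_stat <- function(a, b) {
    grid <- sort(unique(c(a, b)))
    max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
  }
  d_obs <- ks_stat(x, y)
  combs <- utils::combn(length(pooled), m)
  ds <- apply(combs, 2, function(idx)
    ks_stat(pooled[idx], pooled[-idx]))
  mean(ds >= d_obs - 1e-12)
}

# write lines to a temp file and return the path
tmp_lines <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# a simple deterministic PWM from per-column consensus with given weight
cons_pwm <- function(consensus, id = "toy", weight = 0.85) {
  bases <- c("A", "C", "G", "T")
  cons <- strsplit(consensus, "")[[1]]
  m <- matrix((1 - weight) / 3, 4, length(cons))
  m[cbind(match(cons, bases), seq_along(cons))] <- weight
  pwm(m, id = id)
}
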