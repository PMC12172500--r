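# Shared fixtures and independent oracles for the suite. Cohorts are
# generated once per session and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, expr, envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small but complete cohort (all four stages, both regions)
small_cohort <- function() {
  cached("small_cohort", {
    cfg <- default_config(n_subjects = c(Healthy = 10, AGA3 = 6,
                                         AGA5 = 5, AGA7 = 5))
    c(simulate_cohort(cfg, seed = 301), list(config = cfg))
  })
}

# full-size default cohort used by the benchmark-style tests
default_cohort <- function() {
  cached("default_cohort", {
    cfg <- default_config()
    c(simulate_cohort(cfg, seed = 11), list(config = cfg))
  })
}

random_table <- function(n, k, seed, kingdom = "bacteria") {
  set.seed(seed)
  v <- matrix(stats::rgamma(n * k, 2), n, k,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("%s_t%02d", substr(kingdom, 1, 1),
                                      seq_len(k))))
  abundance_table(v, kingdom, "genus")
}

# independent term-by-term JSD oracle: 0.5 KL(p||m) + 0.5 KL(q||m), base 2
jsd_oracle <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

# brute-force PERMANOVA pseudo-F from within/between sums of squares
brute_pseudo_F <- function(dm, g) {
  n <- nrow(dm)
  a <- length(unique(g))
  sst <- sum(dm[upper.tri(dm)]^2) / n
  ssw <- 0
  for (lev in unique(g)) {
    idx <- which(g == lev)
    sub <- dm[idx, idx, drop = FALSE]
    ssw <- ssw + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}
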