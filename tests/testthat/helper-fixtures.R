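# Shared fixtures and memoised heavy computations for the suite. Everything
# is generated in code under fixed seeds; the cache lives for one test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .cache, inherits = FALSE)) {
    assign(key, fn(), envir = .cache)
  }
  get(key, envir = .cache, inherits = FALSE)
}

# The study-scale planted cohort: package defaults (25 blocks, drivers with
# weight 1, trait noise sd 0.5, n = 500, 2000 noise genes).
default_fixture <- function() {
  cached("default_fixture", function() generate_fixture(fixture_spec()))
}

default_runs <- function() {
  cached("default_runs", function() {
    fx <- default_fixture()
    run_lasso_bootstrap(fx$expression, fx$trait, b = 10, rng_seed = 1)
  })
}

default_modules <- function() {
  cached("default_modules", function() {
    fx <- default_fixture()
    build_enrichment(fx$expression, unname(fx$manifest$drivers), fx$terms)
  })
}

# A reduced planted cohort for repetition-heavy checks (same generative
# family, smaller gene pool).
small_fixture <- function(seed = 11) {
  cached(paste0("small_fixture_", seed), function() {
    generate_fixture(fixture_spec(
      n_samples = 200, block_sizes = rep(10, 5), n_noise_genes = 120,
      trait_noise_sd = 0.5, rng_seed = seed))
  })
}

# Two planted drivers in a sea of noise, near-noiseless trait: the classic
# planted-signal recovery setting.
planted2_fixture <- function() {
  cached("planted2_fixture", function() {
    generate_fixture(fixture_spec(
      n_samples = 200, block_sizes = c(5, 5), rho = 0.8,
      n_noise_genes = 490, trait_weights = 1, trait_noise_sd = 0.1,
      rng_seed = 42))
  })
}

# Small deterministic toy matrix with named genes for exact-value tests.
toy_matrix <- function(n = 30, genes = 6, seed = 5) {
  set.seed(seed)
  X <- matrix(rnorm(n * genes), n, genes,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              paste0("g", seq_len(genes))))
  X
}

# Construct a lasso_run by hand (for tabulation/diagnostic arithmetic tests).
fake_run <- function(index, selected) {
  structure(list(run_index = index,
                 train_sample_ids = character(0),
                 test_sample_ids = character(0),
                 selected = selected, lambda = 0.1,
                 rmse_train = 0, rmse_test = 0),
            class = "lasso_run")
}

# Independent BH oracle: direct step-up formula.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Independent one-sided overlap p oracle: hypergeometric tail P[K >= k].
hyper_oracle <- function(k, size_a, size_b, N) {
  sum(dhyper(k:min(size_a, size_b), size_b, N - size_b, size_a))
}
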