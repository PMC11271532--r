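test_that("co-expression ranking matches a brute-force correlation sort", {
  X <- toy_matrix(n = 25, genes = 5)
  ranked <- rank_by_coexpression(X, "g2")
  # oracle: per-gene cor() loop, sorted by absolute value then gene id
  genes <- setdiff(colnames(X), "g2")
  r <- vapply(genes, function(g) cor(X[, "g2"], X[, g]), numeric(1))
  ord <- order(-abs(r), genes)
  expect_identical(ranked$gene, genes[ord])
  expect_equal(ranked$r, unname(r[ord]))
})

test_that("ranking is sign-invariant and sends flat genes last", {
  X <- toy_matrix(n = 20, genes = 3)
  X <- cbind(X,
             twin = X[, "g1"],         # identical to the seed
             anti = -X[, "g1"],        # perfectly anti-correlated
             flat = rep(2, 20))        # zero variance
  rownames(X) <- sprintf("s%02d", 1:20)
  ranked <- rank_by_coexpression(X, "g1")
  expect_setequal(ranked$gene[1:2], c("anti", "twin"))
  expect_equal(abs(ranked$r[1:2]), c(1, 1))
  expect_identical(ranked$gene[nrow(ranked)], "flat")
  expect_equal(ranked$r[nrow(ranked)], 0)
  expect_error(rank_by_coexpression(X, "flat"), "zero variance")
  expect_error(rank_by_coexpression(X, "nope"), "not in expression")
})

test_that("fixed-size modules are seed plus a ranking prefix", {
  X <- toy_matrix(n = 30, genes = 8)
  ms <- build_fixed(X, c("g1", "g5"), size = 4)
  expect_length(ms$modules, 2)
  for (m in ms$modules) {
    expect_length(m$members, 5)  # seed not counted against the budget
    expect_identical(m$members[1], m$seed)
    ranked <- rank_by_coexpression(X, m$seed)
    expect_identical(m$members[-1], ranked$gene[1:4])  # prefix property
  }
  # size = |genes| - 1 covers the whole universe
  all_m <- build_fixed(X, "g1", size = 7)
  expect_setequal(all_m$modules$g1$members, colnames(X))
  expect_error(build_fixed(X, "g1", size = 8), "size must")
})

test_that("build_fixed is invariant to sample and gene order", {
  X <- toy_matrix(n = 30, genes = 8)
  ms <- build_fixed(X, "g2", size = 3)
  Xs <- X[sample(nrow(X)), sample(ncol(X))]
  ms2 <- build_fixed(Xs, "g2", size = 3)
  expect_identical(ms$modules$g2$members, ms2$modules$g2$members)
})

test_that("proportional sizes follow S_n = S_1 * |beta_n|/|beta_1| with clamping", {
  X <- toy_matrix(n = 60, genes = 12)
  model <- structure(list(
    seeds = c("g1", "g2", "g3"),
    coefficients = c(`(Intercept)` = 0, g1 = 0.5, g2 = -0.25, g3 = 0.01),
    r2_cv = c(mean = 0.9, sd = 0.01), rmse_cv = c(mean = 1, sd = 0.1)),
    class = "trait_model")
  ms <- build_proportional(X, model, max_size = 10, min_size = 3)
  sizes <- lengths(module_members(ms)) - 1L  # exclude the seed
  expect_equal(unname(sizes[c("g1", "g2", "g3")]), c(10, 5, 3))
  # oracle: the documented formula with round-half-even and [min, max] clamp
  beta <- abs(model$coefficients[model$seeds])
  oracle <- pmin(pmax(round(10 * beta / max(beta)), 3), 10)
  expect_equal(unname(sizes[names(beta)]), unname(oracle))
  # |beta_n| = |beta_1| gets the maximum size
  expect_equal(unname(sizes["g1"]), 10)
  # all-zero coefficients are an error
  model0 <- model
  model0$coefficients[] <- 0
  expect_error(build_proportional(X, model0), "zero")
})

test_that("enrichment growth recovers a planted block and stops on noise", {
  # one 30-gene block sharing a term; everything else unstructured
  fx <- cached("block30_fixture", function() {
    generate_fixture(fixture_spec(
      n_samples = 300, block_sizes = 30, n_noise_genes = 170,
      trait_noise_sd = 0.5, marker_blocks = 1, rng_seed = 21))
  })
  seed <- unname(fx$manifest$drivers[1])
  block <- fx$manifest$blocks$BLOCK01
  ms <- build_enrichment(fx$expression, seed, fx$terms, step = 10,
                         alpha = 0.05, max_size = 100)
  m <- ms$modules[[seed]]
  expect_lte(abs(length(m$members) - 30), 10)  # final size 30 +/- step
  expect_gte(length(intersect(m$members, block)) / length(m$members), 0.8)
  expect_false(m$no_growth)
  expect_gt(m$abundance, 0)
})

test_that("a disjoint gene-set collection blocks growth with a flag", {
  X <- toy_matrix(n = 40, genes = 30)
  colnames(X) <- paste0("gene", 1:30)
  db <- gene_set_db(list(T1 = c("unrelatedA", "unrelatedB")))
  ms <- build_enrichment(X, "gene1", db, step = 5, max_size = 20)
  m <- ms$modules$gene1
  expect_true(m$no_growth)
  expect_length(m$members, 6)  # seed + first step only
  expect_equal(m$abundance, 0)
})

test_that("with alpha = 1 and an all-genes term, growth is governed by abundance", {
  fx <- cached("block30_fixture", function() {
    generate_fixture(fixture_spec(
      n_samples = 300, block_sizes = 30, n_noise_genes = 170,
      trait_noise_sd = 0.5, marker_blocks = 1, rng_seed = 21))
  })
  X <- fx$expression
  seed <- unname(fx$manifest$drivers[1])
  db <- gene_set_db(list(ALL = colnames(X)))
  ms <- build_enrichment(X, seed, db, step = 10, alpha = 1, max_size = 50)
  m <- ms$modules[[seed]]
  # oracle: walk the abundance trajectory directly and find the last
  # strictly-improving prefix
  ranked <- rank_by_coexpression(X, seed)
  ab <- function(sz) functional_abundance(c(seed, ranked$gene[seq_len(sz)]),
                                          db, colnames(X), alpha = 1)
  sz <- 10
  while (sz < 50 && ab(sz + 10) > ab(sz)) sz <- sz + 10
  expect_length(m$members, sz + 1)
})

test_that("module membership is always a prefix of the co-expression ranking", {
  fx <- small_fixture()
  X <- fx$expression
  seeds <- unname(fx$manifest$drivers)[1:3]
  model <- fit_seed_model(X, fx$trait, seeds, rng_seed = 1)
  sets <- list(build_fixed(X, seeds, size = 15),
               build_proportional(X, model, max_size = 15, min_size = 5),
               build_enrichment(X, seeds, fx$terms, step = 5, max_size = 20))
  for (ms in sets) {
    for (m in ms$modules) {
      ranked <- rank_by_coexpression(X, m$seed)
      k <- length(m$members) - 1L
      expect_identical(m$members[-1], ranked$gene[seq_len(k)])
      # ordering matches descending |correlation|
      expect_true(all(diff(abs(m$correlations)) <= 1e-12))
    }
  }
})
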