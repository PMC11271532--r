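test_that("eigengene matches an independent PCA oracle", {
  X <- toy_matrix(n = 40, genes = 10)
  members <- paste0("g", 1:6)
  eg <- compute_eigengene(X, members)
  # oracle: eigendecomposition of the member covariance matrix
  Mc <- scale(X[, members], center = TRUE, scale = FALSE)
  ev <- eigen(cov(Mc), symmetric = TRUE)
  scores <- as.vector(Mc %*% ev$vectors[, 1])
  cosine <- abs(sum(eg$values * scores) /
                  sqrt(sum(eg$values^2) * sum(scores^2)))
  expect_gt(cosine, 0.999)
  expect_equal(eg$variance_explained,
               ev$values[1] / sum(ev$values), tolerance = 1e-9)
  # unit-norm loadings, sign oriented to positive mean member correlation
  expect_equal(sum(eg$loadings^2), 1, tolerance = 1e-9)
  expect_gt(mean(cor(eg$values, X[, members])), 0)
})

test_that("degenerate and random modules give the expected eigengene structure", {
  X <- toy_matrix(n = 50, genes = 4)
  X <- cbind(X, g1copy = X[, "g1"])
  eg <- compute_eigengene(X, c("g1", "g1copy"))
  expect_equal(eg$variance_explained, 1, tolerance = 1e-9)
  expect_equal(abs(cor(eg$values, X[, "g1"])), 1, tolerance = 1e-9)

  # orthogonal noise genes: PC1 carries about 1/|module| of the variance
  set.seed(77)
  reps <- vapply(1:30, function(i) {
    Z <- matrix(rnorm(400 * 8), 400, 8,
                dimnames = list(NULL, paste0("z", 1:8)))
    rownames(Z) <- sprintf("s%03d", 1:400)
    compute_eigengene(Z, paste0("z", 1:8))$variance_explained
  }, numeric(1))
  expect_lt(abs(mean(reps) - 1 / 8), 3 * sd(reps) / sqrt(30) + 0.03)

  Zero <- matrix(0, 10, 2, dimnames = list(paste0("s", 1:10), c("a", "b")))
  expect_error(compute_eigengene(Zero, c("a", "b")), "rank 0")
  expect_error(compute_eigengene(X, "g1"), "at least 2")
})

test_that("trait association recovers perfect and strong group signals", {
  set.seed(3)
  e <- rnorm(100)
  res <- trait_association(e, e)
  expect_equal(res$statistic, 1, tolerance = 1e-12)
  expect_lt(res$p_value, 1e-100)

  # binary trait, group means two sd apart, n = 100
  grp <- rep(c(0, 1), each = 50)
  eb <- rnorm(100, mean = 2 * grp)
  res_b <- trait_association(eb, trait("status", grp, kind = "binary"))
  expect_identical(res_b$method, "point-biserial")
  expect_lt(res_b$p_value, 1e-6)
  # point-biserial equals the two-sample t-test p-value
  tt <- t.test(eb[grp == 1], eb[grp == 0], var.equal = TRUE)
  expect_equal(res_b$p_value, tt$p.value, tolerance = 1e-9)

  expect_warning(res0 <- trait_association(rep(1, 100), e), "constant")
  expect_true(is.na(res0$p_value))
})

test_that("trait association p-values are uniform under the null", {
  set.seed(11)
  p <- vapply(1:2000, function(i) {
    trait_association(rnorm(60), rnorm(60))$p_value
  }, numeric(1))
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("Fisher enrichment equals the hypergeometric tail oracle", {
  universe <- sprintf("u%04d", 1:1000)
  marker <- universe[1:20]
  module <- c(universe[1:5], universe[900:904])  # 5 of 10 in the marker set
  db <- gene_set_db(list(M = marker), source_label = "celltype")
  res <- celltype_enrichment(module, db, universe)
  expect_equal(res$rows$p_raw, hyper_oracle(5, 10, 20, 1000),
               tolerance = 1e-9)
  expect_equal(res$rows$overlap, 5)

  # disjoint marker set: one-sided p >= 0.5
  db2 <- gene_set_db(list(M = universe[500:519]))
  res2 <- celltype_enrichment(universe[1:10], db2, universe)
  expect_gte(res2$rows$p_raw, 0.5)

  # module contained in the markers of a tiny universe: enrichment detected
  tiny <- sprintf("t%02d", 1:30)
  db3 <- gene_set_db(list(M = tiny[1:8]))
  res3 <- celltype_enrichment(tiny[1:6], db3, tiny)
  expect_lt(res3$rows$p_raw, 0.05)
  expect_equal(res3$rows$p_raw, hyper_oracle(6, 6, 8, 30), tolerance = 1e-9)

  # marker set outside the universe is skipped with a warning
  db4 <- gene_set_db(list(gone = c("x1", "x2"), M = tiny[1:8]))
  expect_warning(res4 <- celltype_enrichment(tiny[1:6], db4, tiny), "skipped")
  expect_identical(res4$rows$term_id, "M")
})

test_that("functional abundance equals the hand-computed formula", {
  # enumerable setting: universe of 40, two planted terms, 4-gene set
  universe <- sprintf("u%02d", 1:40)
  db <- gene_set_db(list(A = universe[1:6], B = universe[c(1:3, 20:24)],
                         C = universe[30:39]))
  G <- universe[1:4]
  # oracle: hypergeometric p per term, direct BH, formula on significant terms
  p_raw <- c(A = hyper_oracle(4, 4, 6, 40),
             B = hyper_oracle(3, 4, 8, 40),
             C = hyper_oracle(0, 4, 10, 40))
  p_adj <- bh_oracle(p_raw)
  keep <- p_adj < 0.05
  expected <- sum(-log10(p_raw[keep])) / 4
  expect_gt(sum(keep), 0)
  expect_equal(functional_abundance(G, db, universe), expected,
               tolerance = 1e-9)
  # adjusted-p variant
  expected_adj <- sum(-log10(p_adj[keep])) / 4
  expect_equal(functional_abundance(G, db, universe, p_use = "adjusted"),
               expected_adj, tolerance = 1e-9)
  # no significant term => 0
  expect_equal(functional_abundance(universe[35:38],
                                    gene_set_db(list(A = universe[1:6])),
                                    universe), 0)
})

test_that("functional abundance is invariant to gene and term listing order", {
  universe <- sprintf("u%02d", 1:40)
  db1 <- gene_set_db(list(A = universe[1:6], B = universe[c(1:3, 20:24)]))
  db2 <- gene_set_db(list(B = rev(universe[c(1:3, 20:24)]), A = sample(universe[1:6])))
  G <- universe[1:4]
  expect_equal(functional_abundance(G, db1, universe),
               functional_abundance(rev(G), db2, universe), tolerance = 1e-12)
})

test_that("a planted block outscores size-matched random gene sets", {
  fx <- small_fixture()
  universe <- colnames(fx$expression)
  block <- fx$manifest$blocks$BLOCK01
  fa_block <- functional_abundance(block, fx$terms, universe)
  set.seed(8)
  wins <- vapply(1:100, function(i) {
    fa_block > functional_abundance(sample(universe, length(block)),
                                    fx$terms, universe)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("BH adjustment matches the direct step-up formula", {
  set.seed(2)
  p <- runif(25)^2
  expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  res <- functional_enrichment(sprintf("u%02d", 1:4),
                               gene_set_db(list(A = sprintf("u%02d", 1:6),
                                                B = sprintf("u%02d", 7:12))),
                               sprintf("u%02d", 1:40))
  expect_equal(res$rows$p_adj, bh_oracle(res$rows$p_raw), tolerance = 1e-12)
  expect_true(all(res$rows$p_adj >= res$rows$p_raw))
})

test_that("annotate_modules produces one coherent row per module", {
  fx <- small_fixture()
  X <- fx$expression
  ms <- build_fixed(X, unname(fx$manifest$drivers)[1:3], size = 9)
  ann <- annotate_modules(ms, X, fx$trait, db = fx$terms, markers = fx$markers)
  expect_equal(nrow(ann), 3)
  expect_equal(ann$size, rep(10, 3))
  expect_true(all(ann$trait_p_adj >= 0 & ann$trait_p_adj <= 1))
  # each driver module is annotated with its own planted block term
  expect_identical(ann$top_terms, names(fx$manifest$blocks)[1:3])
})
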