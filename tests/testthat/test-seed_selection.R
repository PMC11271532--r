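test_that("bootstrapped LASSO recovers planted drivers and is seed-deterministic", {
  fx <- planted2_fixture()
  drivers <- unname(fx$manifest$drivers)
  runs <- run_lasso_bootstrap(fx$expression, fx$trait, b = 10, rng_seed = 7)
  tab <- tabulate_eligibility(runs)
  elig <- setNames(tab$eligibility, tab$gene)
  expect_equal(unname(elig[drivers]), c(10, 10))

  # identical master seed => bit-identical seed table
  runs2 <- run_lasso_bootstrap(fx$expression, fx$trait, b = 10, rng_seed = 7)
  expect_identical(tabulate_eligibility(runs2), tab)

  # train/test splits are disjoint and cover the samples
  for (r in runs) {
    expect_length(intersect(r$train_sample_ids, r$test_sample_ids), 0)
    expect_setequal(c(r$train_sample_ids, r$test_sample_ids),
                    rownames(fx$expression))
    expect_true(all(r$selected != 0))
  }
})

test_that("no transcript is a recurrent stable seed across null traits", {
  # under an X-independent trait, which transcripts look stable is an
  # artefact of that particular trait draw, so no transcript should reach
  # the seed threshold in most seeded repetitions
  fx <- small_fixture()
  set.seed(99)
  stable_sets <- lapply(1:6, function(i) {
    ynull <- trait("null", rnorm(nrow(fx$expression)))
    runs <- run_lasso_bootstrap(fx$expression, ynull, b = 10,
                                rng_seed = 100 + i)
    tab <- tabulate_eligibility(runs)
    tab$gene[tab$eligibility >= 8]
  })
  freq <- table(unlist(stable_sets)) / length(stable_sets)
  expect_lt(max(c(0, freq)), 0.95)
})

test_that("b = 1 yields a single run with unit eligibility", {
  fx <- planted2_fixture()
  runs <- run_lasso_bootstrap(fx$expression, fx$trait, b = 1, rng_seed = 3)
  expect_length(runs, 1)
  tab <- tabulate_eligibility(runs)
  expect_true(all(tab$eligibility == 1))
})

test_that("eligibility tabulation arithmetic matches hand counts", {
  runs <- list(fake_run(1, c(g = 0.2, h = 1.0)),
               fake_run(2, c(h = -0.5)),
               fake_run(3, c(g = -0.4)),
               fake_run(4, c(x = 0.1)),
               fake_run(5, c(g = 0.6)))
  tab <- tabulate_eligibility(runs)
  row_g <- tab[tab$gene == "g", ]
  expect_equal(row_g$eligibility, 3)
  expect_equal(row_g$mean_abs_coef, mean(c(0.2, 0.4, 0.6)))
  expect_false("absent" %in% tab$gene)
  expect_equal(max(tab$eligibility), 3)
  expect_equal(attr(tab, "b"), 5)

  expect_setequal(select_seeds(tab, 2), c("g", "h"))
  expect_warning(s <- select_seeds(tab, 6), "exceeds")
  expect_length(s, 0)
})

test_that("the seed model is predictive on planted drivers and not on noise", {
  fx <- planted2_fixture()
  drivers <- unname(fx$manifest$drivers)
  m <- fit_seed_model(fx$expression, fx$trait, drivers, rng_seed = 1)
  expect_gte(unname(m$r2_cv["mean"]), 0.95)

  set.seed(4)
  nondrivers <- sample(grep("^N", colnames(fx$expression), value = TRUE), 5)
  ynull <- trait("null", rnorm(nrow(fx$expression)))
  m0 <- fit_seed_model(fx$expression, ynull, nondrivers, rng_seed = 1)
  expect_lte(unname(m0$r2_cv["mean"]), 0.1)
})

test_that("a trait equal to one seed column is fit perfectly", {
  X <- toy_matrix(n = 40, genes = 6)
  y <- X[, "g3"]
  m <- fit_seed_model(X, y, c("g3", "g1"), rng_seed = 2)
  expect_equal(unname(m$r2_cv["mean"]), 1, tolerance = 1e-9)
  expect_equal(unname(m$coefficients["g3"]), 1, tolerance = 1e-9)
})

test_that("collinear seed columns trigger the pseudoinverse path with a warning", {
  X <- toy_matrix(n = 30, genes = 4)
  X <- cbind(X, g4b = X[, "g4"])
  set.seed(1)
  y <- X[, "g1"] + rnorm(30, 0, 0.1)
  expect_warning(m <- fit_seed_model(X, y, c("g1", "g4", "g4b"), rng_seed = 1),
                 "collinear")
  expect_gte(unname(m$r2_cv["mean"]), 0.9)
})

test_that("eligibility curves are monotone in b and r", {
  fx <- planted2_fixture()
  runs <- cached("p2_runs10", function()
    run_lasso_bootstrap(fx$expression, fx$trait, b = 10, rng_seed = 7))
  cur <- eligibility_curve(b_grid = c(2, 5, 10), r_grid = c(1, 2, 5, 10, 12),
                           runs = runs)
  # r = 1 curve non-decreasing in b (union of selections grows)
  r1 <- cur$n_transcripts[cur$r == 1]
  expect_true(all(diff(r1) >= 0))
  # at fixed b, counts non-increasing in r
  for (b in unique(cur$b)) {
    nb <- cur$n_transcripts[cur$b == b]
    expect_true(all(diff(nb) <= 0))
  }
  # r > b reported as 0
  expect_equal(cur$n_transcripts[cur$b == 10 & cur$r == 12], 0)
  # planted drivers survive the strictest threshold
  expect_gte(cur$n_transcripts[cur$b == 10 & cur$r == 10], 2)
})

test_that("eligibility correlates with coefficient size on planted signal", {
  fx <- planted2_fixture()
  runs <- cached("p2_runs10", function()
    run_lasso_bootstrap(fx$expression, fx$trait, b = 10, rng_seed = 7))
  tab <- tabulate_eligibility(runs)
  skip_if(nrow(tab) < 5)
  ct <- suppressWarnings(
    cor.test(tab$eligibility, tab$mean_abs_coef, method = "spearman"))
  expect_gt(ct$estimate, 0)
})

test_that("selection stability grows with training-set size", {
  fx <- small_fixture()
  X <- fx$expression
  n <- nrow(X)
  jac <- vapply(c(0.25, 1), function(f) {
    mean(vapply(1:3, function(rep) {
      set.seed(500 + rep)
      idx <- sort(sample(n, round(f * n)))
      runs <- run_lasso_bootstrap(X[idx, , drop = FALSE],
                                  fx$trait$values[idx], b = 6,
                                  rng_seed = 600 + rep)
      stability_jaccard(runs)
    }, numeric(1)))
  }, numeric(1))
  expect_gte(jac[2], jac[1] - 0.02)  # Monte-Carlo slack at 3 repetitions
})

test_that("run_lasso_bootstrap validates its preconditions", {
  fx <- small_fixture()
  expect_error(run_lasso_bootstrap(fx$expression, fx$trait, b = 0), "b must")
  expect_error(run_lasso_bootstrap(fx$expression, fx$trait, test_fraction = 0.6),
               "test_fraction")
  X <- fx$expression[1:8, ]
  expect_error(run_lasso_bootstrap(X, fx$trait$values[1:8], cv_folds = 5),
               "2 samples per")
})
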