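#' Bootstrapped LASSO runs for seed-transcript discovery
#'
#' Generates `b` LASSO solutions from `b` independent train/test resamples of
#' the samples. Within each run the penalty weight lambda is chosen by
#' `cv_folds`-fold cross-validation on the training split and all transcripts
#' with a non-zero coefficient are recorded, together with train and test
#' RMSE. Repeating the selection across resamples and counting how often each
#' transcript appears (its eligibility, or ratio of appearance) is what makes
#' seed selection stable in the face of the heavy collinearity of expression
#' data.
#'
#' The default resampling is the classic bootstrap: each run trains on a bag
#' of `n` samples drawn with replacement and tests on the out-of-bag samples
#' (about 37% of the cohort). This keeps the training sets of different runs
#' genuinely variable, so transcripts that are only spuriously associated
#' with the trait rarely stay selected across runs; replacement-free
#' subsampling at `1 - test_fraction` is available via
#' `resample = "subsample"` but overlaps so heavily across runs that
#' spurious selections look more stable than they are.
#'
#' Reproducibility contract: the run `i` uses RNG seed `rng_seed + i - 1`, so
#' the full set of runs (and everything downstream of it) is bit-reproducible
#' given `rng_seed`, and a set of runs computed at a larger `b` contains the
#' runs of any smaller `b` as a prefix.
#'
#' @param X samples x genes numeric matrix (usually z-scored).
#' @param y A [trait()] or numeric vector aligned to the rows of `X`.
#' @param b Number of bootstrap runs (default 10).
#' @param resample `"bootstrap"` (default: train on a with-replacement bag,
#'   test out-of-bag) or `"subsample"` (replacement-free split at
#'   `test_fraction`).
#' @param test_fraction Fraction of samples held out per run under
#'   `resample = "subsample"` (default 0.2; must be in (0, 0.5)).
#' @param cv_folds Folds for the within-run lambda cross-validation.
#' @param lambda_rule `"min"` for the CV-minimum lambda (default) or `"1se"`
#'   for the one-standard-error rule.
#' @param family `"gaussian"` (squared-error LASSO, used for both continuous
#'   and 0/1 traits, the default) or `"binomial"` for a logistic variant.
#' @param rng_seed Master seed for the resampling and CV fold assignment.
#' @return A list of class `lasso_runs`; each element has `run_index`,
#'   `train_sample_ids`, `test_sample_ids`, `selected` (named non-zero
#'   coefficients), `lambda`, `rmse_train`, `rmse_test`.
#' @export
run_lasso_bootstrap <- function(X, y, b = 10,
                                resample = c("bootstrap", "subsample"),
                                test_fraction = 0.2,
                                cv_folds = 5,
                                lambda_rule = c("min", "1se"),
                                family = c("gaussian", "binomial"),
                                rng_seed = 1) {
  check_expression(X)
  resample <- match.arg(resample)
  lambda_rule <- match.arg(lambda_rule)
  family <- match.arg(family)
  yv <- trait_values(y, X)
  n <- nrow(X)
  if (b < 1) stop("b must be >= 1")
  if (test_fraction <= 0 || test_fraction >= 0.5) {
    stop("test_fraction must lie in (0, 0.5)")
  }
  if (n < 2 * cv_folds) {
    stop("need at least 2 samples per cross-validation fold (n = ", n,
         ", cv_folds = ", cv_folds, ")")
  }
  runs <- vector("list", b)
  for (i in seq_len(b)) {
    set.seed(rng_seed + i - 1L)
    if (resample == "bootstrap") {
      train_idx <- sort(sample.int(n, n, replace = TRUE))
      test_idx <- setdiff(seq_len(n), unique(train_idx))
      if (!length(test_idx)) {
        stop("out-of-bag test set of run ", i, " is empty; use ",
             "resample = 'subsample' for very small cohorts")
      }
    } else {
      n_test <- max(1L, round(n * test_fraction))
      test_idx <- sort(sample.int(n, n_test))
      train_idx <- setdiff(seq_len(n), test_idx)
    }
    ytr <- yv[train_idx]
    if (stats::var(ytr) == 0) {
      stop("trait is constant on the training split of run ", i)
    }
    fit <- glmnet::cv.glmnet(X[train_idx, , drop = FALSE], ytr,
                             nfolds = cv_folds, family = family,
                             standardize = TRUE)
    lam <- if (lambda_rule == "min") fit$lambda.min else fit$lambda.1se
    cf <- as.matrix(stats::coef(fit, s = lam))[, 1L]
    cf <- cf[setdiff(names(cf), "(Intercept)")]
    selected <- cf[cf != 0]
    ptr <- as.vector(stats::predict(fit, X[train_idx, , drop = FALSE], s = lam,
                                    type = "response"))
    pte <- as.vector(stats::predict(fit, X[test_idx, , drop = FALSE], s = lam,
                                    type = "response"))
    runs[[i]] <- structure(
      list(run_index = i,
           train_sample_ids = rownames(X)[unique(train_idx)],
           test_sample_ids = rownames(X)[test_idx],
           selected = selected,
           lambda = lam,
           rmse_train = sqrt(mean((ytr - ptr)^2)),
           rmse_test = sqrt(mean((yv[test_idx] - pte)^2))),
      class = "lasso_run")
  }
  structure(runs, class = "lasso_runs", b = b, genes = colnames(X))
}

#' Tabulate transcript eligibility across LASSO runs
#'
#' For every transcript selected in at least one run, counts the number of
#' selecting runs (the eligibility, or ratio of appearance `r`) and the mean
#' absolute coefficient over those runs.
#'
#' @param runs A `lasso_runs` list from [run_lasso_bootstrap()].
#' @return A data.frame of class `seed_table` with columns `gene`,
#'   `eligibility`, `mean_abs_coef`, sorted by decreasing eligibility, then
#'   decreasing mean coefficient, then gene id. The number of runs is kept in
#'   `attr(, "b")`.
#' @export
tabulate_eligibility <- function(runs) {
  if (!length(runs)) stop("runs must be non-empty")
  sel <- lapply(runs, function(r) r$selected)
  genes <- sort(unique(unlist(lapply(sel, names))))
  if (!length(genes)) {
    out <- data.frame(gene = character(0), eligibility = integer(0),
                      mean_abs_coef = numeric(0))
  } else {
    elig <- integer(length(genes))
    mac <- numeric(length(genes))
    names(elig) <- names(mac) <- genes
    for (s in sel) {
      elig[names(s)] <- elig[names(s)] + 1L
      mac[names(s)] <- mac[names(s)] + abs(s)
    }
    mac <- mac / elig
    out <- data.frame(gene = genes, eligibility = unname(elig),
                      mean_abs_coef = unname(mac),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$eligibility, -out$mean_abs_coef, out$gene), ]
    rownames(out) <- NULL
  }
  structure(out, class = c("seed_table", "data.frame"), b = length(runs))
}

#' Select seed transcripts at an eligibility threshold
#'
#' @param seed_table A [tabulate_eligibility()] table.
#' @param r Minimum eligibility: transcripts selected in at least `r` of the
#'   `b` runs become seeds (default 8, the usual choice for `b = 10`).
#' @return Character vector of seed gene ids.
#' @export
select_seeds <- function(seed_table, r = 8) {
  stopifnot(inherits(seed_table, "seed_table"))
  if (r < 1) stop("r must be >= 1")
  b <- attr(seed_table, "b")
  if (!is.null(b) && r > b) {
    warning("r (", r, ") exceeds the number of runs (", b, "); no seeds")
  }
  seed_table$gene[seed_table$eligibility >= r]
}

# OLS coefficients with a pseudoinverse fallback for rank-deficient designs.
ols_coef <- function(D, y, warn = TRUE) {
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    if (warn) {
      warning("collinear predictors detected; coefficients computed with a ",
              "pseudoinverse")
    }
    beta <- MASS::ginv(D) %*% y
  } else {
    beta <- qr.coef(qrD, y)
  }
  stats::setNames(as.vector(beta), colnames(D))
}

#' Fit the seed linear model with repeated cross-validation
#'
#' Ordinary least squares of the trait on the seed transcripts. Predictive
#' performance (R-squared and RMSE) is estimated over `cv_repeats` repetitions
#' of `cv_folds`-fold cross-validation; the held-out R-squared of each fold is
#' `1 - RSS/TSS` around the held-out mean, so an uninformative model scores at
#' or below zero. Full-data coefficients are also reported, as they drive the
#' proportional module-sizing strategy.
#'
#' @param X samples x genes numeric matrix.
#' @param y A [trait()] or numeric vector.
#' @param seeds Character vector of predictor gene ids (may be empty, giving
#'   an intercept-only model).
#' @param cv_folds,cv_repeats Cross-validation geometry (defaults 5 x 10).
#' @param rng_seed Seed for the fold assignments.
#' @return An object of class `trait_model`: `seeds`, `coefficients` (named,
#'   including `(Intercept)`), `r2_cv` and `rmse_cv` (each `c(mean, sd)` over
#'   the held-out folds), plus the CV geometry.
#' @export
fit_seed_model <- function(X, y, seeds, cv_folds = 5, cv_repeats = 10,
                           rng_seed = 1) {
  check_expression(X)
  yv <- trait_values(y, X)
  seeds <- as.character(seeds)
  missing <- setdiff(seeds, colnames(X))
  if (length(missing)) {
    stop("seeds not present in the expression matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  n <- nrow(X)
  if (length(seeds) >= n) stop("need fewer seeds than samples")
  D <- cbind(`(Intercept)` = 1, X[, seeds, drop = FALSE])
  coefs <- ols_coef(D, yv)
  set.seed(rng_seed)
  r2s <- rmses <- numeric(0)
  for (rep_i in seq_len(cv_repeats)) {
    fold <- sample(rep(seq_len(cv_folds), length.out = n))
    for (k in seq_len(cv_folds)) {
      te <- fold == k
      beta <- ols_coef(D[!te, , drop = FALSE], yv[!te], warn = FALSE)
      pred <- as.vector(D[te, , drop = FALSE] %*% beta)
      res <- yv[te] - pred
      tss <- sum((yv[te] - mean(yv[te]))^2)
      r2s <- c(r2s, 1 - sum(res^2) / tss)
      rmses <- c(rmses, sqrt(mean(res^2)))
    }
  }
  structure(list(seeds = seeds,
                 coefficients = coefs,
                 r2_cv = c(mean = mean(r2s), sd = stats::sd(r2s)),
                 rmse_cv = c(mean = mean(rmses), sd = stats::sd(rmses)),
                 cv_folds = cv_folds, cv_repeats = cv_repeats),
            class = "trait_model")
}

#' Seed counts across eligibility thresholds and numbers of runs
#'
#' Computes, for every pair `(b, r)` on the supplied grids, the number of
#' transcripts selected at least `r` times within the first `b` runs. The
#' maximum of `b_grid` runs is computed once and the curves derived by
#' truncation, so the curves share their randomness (as in a single growing
#' bootstrap).
#'
#' @param X,y Expression matrix and trait (ignored when `runs` is supplied).
#' @param b_grid Integer vector of run counts.
#' @param r_grid Integer vector of eligibility thresholds.
#' @param rng_seed Seed forwarded to [run_lasso_bootstrap()].
#' @param runs Optional precomputed `lasso_runs` (with at least
#'   `max(b_grid)` runs) to reuse.
#' @param ... Further arguments to [run_lasso_bootstrap()].
#' @return A data.frame with columns `b`, `r`, `n_transcripts`.
#' @export
eligibility_curve <- function(X = NULL, y = NULL, b_grid, r_grid,
                              rng_seed = 1, runs = NULL, ...) {
  b_grid <- sort(unique(as.integer(b_grid)))
  r_grid <- sort(unique(as.integer(r_grid)))
  if (is.null(runs)) {
    runs <- run_lasso_bootstrap(X, y, b = max(b_grid), rng_seed = rng_seed, ...)
  }
  if (length(runs) < max(b_grid)) stop("runs has fewer runs than max(b_grid)")
  out <- expand.grid(r = r_grid, b = b_grid)[, c("b", "r")]
  out$n_transcripts <- mapply(function(b, r) {
    tab <- tabulate_eligibility(runs[seq_len(b)])
    sum(tab$eligibility >= r)
  }, out$b, out$r)
  rownames(out) <- NULL
  out
}

#' @export
print.seed_table <- function(x, ...) {
  cat(sprintf("<seed_table> %d transcripts selected across %d runs\n",
              nrow(x), attr(x, "b")))
  print.data.frame(utils::head(x, 10L), ...)
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf("<trait_model> %d seeds; CV R2 = %.3f +/- %.3f; CV RMSE = %.3f +/- %.3f\n",
              length(x$seeds), x$r2_cv["mean"], x$r2_cv["sd"],
              x$rmse_cv["mean"], x$rmse_cv["sd"]))
  invisible(x)
}
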