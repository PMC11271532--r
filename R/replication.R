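# In-sample R-squared of an OLS fit of y on the given gene columns (plus
# intercept). Rank-deficient designs are handled by the pivoting QR of
# .lm.fit. This is the fast scoring routine shared by the permutation and
# dropout null models.
r2_insample <- function(X, y, genes) {
  D <- cbind(1, X[, genes, drop = FALSE])
  fit <- stats::.lm.fit(D, y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Transfer the discovery seed model to a replication cohort
#'
#' Refits the seed linear model (OLS, repeated cross-validation as in
#' [fit_seed_model()]) on an independent cohort using the discovery seeds.
#' Seeds absent from the replication matrix are dropped with a warning; when
#' fewer than half are present the function stops and points at
#' [seed_dropout_analysis()].
#'
#' @param X_rep Replication samples x genes matrix.
#' @param y_rep Replication trait.
#' @param seeds Discovery seed gene ids.
#' @param ... Passed to [fit_seed_model()] (`cv_folds`, `cv_repeats`,
#'   `rng_seed`).
#' @return A list with `r2`, `rmse` (cross-validated means), `model` (the
#'   full `trait_model`), and `seeds_used`.
#' @export
seed_model_transfer <- function(X_rep, y_rep, seeds, ...) {
  check_expression(X_rep)
  present <- intersect(seeds, colnames(X_rep))
  if (length(present) < 0.5 * length(seeds)) {
    stop("fewer than 50% of the discovery seeds are present in the ",
         "replication cohort; run seed_dropout_analysis() to gauge the impact")
  }
  if (length(present) < length(seeds)) {
    warning("seeds missing from the replication cohort: ",
            paste(setdiff(seeds, present), collapse = ", "))
  }
  m <- fit_seed_model(X_rep, y_rep, present, ...)
  list(r2 = unname(m$r2_cv["mean"]), rmse = unname(m$rmse_cv["mean"]),
       model = m, seeds_used = present)
}

#' Permutation p-value for the predictivity of a seed set
#'
#' Compares the in-sample R-squared of the model built on the real seeds with
#' `n_perm` models built on random size-matched gene sets drawn from the
#' cohort's gene universe excluding the real seeds. The empirical p-value
#' uses the plus-one convention `p = (1 + #{R2_null >= R2_real}) / (1 +
#' n_perm)`, so it is never exactly zero.
#'
#' @param X_rep samples x genes matrix of the cohort under test.
#' @param y_rep Trait of that cohort.
#' @param seeds Real seed gene ids (all must be present).
#' @param n_perm Number of random seed sets (default 10000; at least 100).
#' @param rng_seed Seed for the random draws. Two seed sets scored against
#'   the same `rng_seed` share their null draws, so a strictly better model
#'   never receives a larger p-value.
#' @return A list with `p_value`, `r2_real`, `r2_null` (length `n_perm`),
#'   and `n_perm`.
#' @export
seed_permutation_pvalue <- function(X_rep, y_rep, seeds, n_perm = 10000,
                                    rng_seed = 1) {
  check_expression(X_rep)
  if (n_perm < 100) stop("n_perm must be at least 100")
  yv <- trait_values(y_rep, X_rep)
  missing <- setdiff(seeds, colnames(X_rep))
  if (length(missing)) stop("seeds missing from cohort: ",
                            paste(missing, collapse = ", "))
  pool <- setdiff(colnames(X_rep), seeds)
  if (length(pool) < length(seeds)) stop("gene universe too small for size-matched draws")
  r2_real <- r2_insample(X_rep, yv, seeds)
  set.seed(rng_seed)
  r2_null <- vapply(seq_len(n_perm), function(i) {
    r2_insample(X_rep, yv, sample(pool, length(seeds)))
  }, numeric(1L))
  p <- (1 + sum(r2_null >= r2_real)) / (1 + n_perm)
  list(p_value = p, r2_real = r2_real, r2_null = r2_null, n_perm = n_perm)
}

#' Sensitivity of the seed model to missing seeds
#'
#' Quantifies how much predictive power is lost when seeds are absent from a
#' replication cohort. For `drop_size = 1` all single removals are enumerated
#' exactly; for larger sizes `n_sim` random subsets are removed. The change
#' in in-sample R-squared relative to the full seed model is reported per
#' simulated model and summarised per drop size. Because the seed model is
#' additive, dropping a few of many seeds typically barely moves R-squared.
#'
#' @param X_rep samples x genes matrix.
#' @param y_rep Trait.
#' @param seeds Seed gene ids.
#' @param drop_sizes Integer vector of removal sizes (default `c(1, 5, 10)`;
#'   every size must be smaller than `length(seeds)`).
#' @param n_sim Monte-Carlo draws per drop size > 1 (default 10000).
#' @param rng_seed Seed for the subset draws.
#' @return A list with `baseline_r2`, `detail` (one row per evaluated model:
#'   `drop_size`, `r2`, `delta_r2`, and the dropped seed for size 1), and
#'   `summary` (per drop size: mean, median, 2.5% and 97.5% quantiles, and
#'   maximum of `delta_r2`).
#' @export
seed_dropout_analysis <- function(X_rep, y_rep, seeds,
                                  drop_sizes = c(1, 5, 10), n_sim = 10000,
                                  rng_seed = 1) {
  check_expression(X_rep)
  yv <- trait_values(y_rep, X_rep)
  if (any(drop_sizes >= length(seeds))) {
    stop("every drop size must be smaller than the number of seeds")
  }
  if (any(drop_sizes < 1)) stop("drop sizes must be positive")
  base <- r2_insample(X_rep, yv, seeds)
  detail <- list()
  for (d in sort(unique(as.integer(drop_sizes)))) {
    if (d == 1L) {
      r2 <- vapply(seeds, function(s)
        r2_insample(X_rep, yv, setdiff(seeds, s)), numeric(1L))
      detail[[length(detail) + 1L]] <- data.frame(
        drop_size = 1L, dropped = seeds, r2 = unname(r2),
        delta_r2 = base - unname(r2), stringsAsFactors = FALSE)
    } else {
      set.seed(rng_seed + d)
      r2 <- vapply(seq_len(n_sim), function(i)
        r2_insample(X_rep, yv, setdiff(seeds, sample(seeds, d))), numeric(1L))
      detail[[length(detail) + 1L]] <- data.frame(
        drop_size = d, dropped = NA_character_, r2 = r2,
        delta_r2 = base - r2, stringsAsFactors = FALSE)
    }
  }
  detail <- do.call(rbind, detail)
  rownames(detail) <- NULL
  summ <- do.call(rbind, lapply(split(detail, detail$drop_size), function(g) {
    q <- stats::quantile(g$delta_r2, c(0.025, 0.5, 0.975))
    data.frame(drop_size = g$drop_size[1L], n_models = nrow(g),
               mean_delta_r2 = mean(g$delta_r2),
               q025 = q[[1L]], median = q[[2L]], q975 = q[[3L]],
               max_delta_r2 = max(g$delta_r2))
  }))
  rownames(summ) <- NULL
  list(baseline_r2 = base, detail = detail, summary = summ)
}

#' Module replication between two networks
#'
#' A discovery module replicates when it has at least one BH-significant
#' Fisher overlap (adjusted p below `alpha`) with any module of the
#' replication network, both taken over the shared gene universe (typically
#' the intersection of the two cohorts' gene lists).
#'
#' @param modules_disc,modules_rep `tgcn_module_set`s.
#' @param universe Shared background gene ids.
#' @param alpha BH significance level (default 0.05).
#' @return A data.frame with one row per discovery module: `module`,
#'   `n_significant`, `best_p_adj`, `replicates`; the full
#'   [module_overlap_matrix()] is attached as `attr(, "overlap")`.
#' @export
module_replication <- function(modules_disc, modules_rep, universe,
                               alpha = 0.05) {
  ov <- module_overlap_matrix(modules_disc, modules_rep, universe, alpha)
  sig <- ov$p_adj < alpha
  out <- data.frame(
    module = rownames(ov$p_adj),
    n_significant = rowSums(sig, na.rm = TRUE),
    best_p_adj = apply(ov$p_adj, 1L, min, na.rm = TRUE),
    stringsAsFactors = FALSE)
  out$replicates <- out$n_significant >= 1L
  rownames(out) <- NULL
  attr(out, "overlap") <- ov
  out
}
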