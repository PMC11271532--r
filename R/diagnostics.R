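# Maximum absolute off-diagonal Spearman correlation among the columns of M.
max_abs_spearman <- function(M) {
  C <- suppressWarnings(stats::cor(M, method = "spearman"))
  diag(C) <- 0
  C[is.na(C)] <- 0
  max(abs(C))
}

#' Test the mutual independence of LASSO-selected transcripts
#'
#' Seeds are meant to represent distinct pathways, so they should be less
#' inter-correlated than random transcripts (which tend to fall inside
#' correlated co-expression blocks). Per run, the maximum absolute Spearman
#' correlation over all pairs of selected transcripts is compared with the
#' same maximum over a size-matched random gene set drawn from the universe
#' excluding that run's selections; the two per-run series are compared by a
#' two-sample t-test.
#'
#' The seed series is fully determined by the runs; `rng_seed` only controls
#' the random comparison sets.
#'
#' @param X samples x genes numeric matrix.
#' @param runs A `lasso_runs` list; runs with fewer than 2 selected
#'   transcripts are skipped with a warning.
#' @param rng_seed Seed for the random gene draws.
#' @return A list with `mean_max_r_seeds`, `mean_max_r_random`,
#'   `t_statistic`, `p_value`, and the `per_run` data.frame.
#' @export
seed_independence_test <- function(X, runs, rng_seed = 1) {
  check_expression(X)
  universe <- colnames(X)
  set.seed(rng_seed)
  rows <- list()
  for (run in runs) {
    s <- names(run$selected)
    if (length(s) < 2L) {
      warning("run ", run$run_index, " selected fewer than 2 transcripts; skipped")
      next
    }
    seed_max <- max_abs_spearman(X[, s, drop = FALSE])
    rnd <- sample(setdiff(universe, s), length(s))
    rand_max <- max_abs_spearman(X[, rnd, drop = FALSE])
    rows[[length(rows) + 1L]] <- data.frame(
      run = run$run_index, n_selected = length(s),
      max_r_seeds = seed_max, max_r_random = rand_max)
  }
  if (length(rows) < 2L) {
    stop("need at least 2 usable runs for the independence test")
  }
  per_run <- do.call(rbind, rows)
  tt <- stats::t.test(per_run$max_r_seeds, per_run$max_r_random)
  list(mean_max_r_seeds = mean(per_run$max_r_seeds),
       mean_max_r_random = mean(per_run$max_r_random),
       t_statistic = unname(tt$statistic),
       p_value = tt$p.value,
       per_run = per_run)
}

# Jaccard index of two sets; two empty sets count as identical (1).
jaccard <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Selection stability across LASSO runs
#'
#' Mean pairwise Jaccard index of the selected transcript sets over all
#' unordered pairs of runs; 1 means every run selects the same transcripts.
#' A pair of empty selections contributes 1 by convention.
#'
#' @param runs A `lasso_runs` list (length >= 2).
#' @return The mean pairwise Jaccard in `[0, 1]`.
#' @export
stability_jaccard <- function(runs) {
  if (length(runs) < 2L) stop("need at least 2 runs")
  sets <- lapply(runs, function(r) names(r$selected))
  pairs <- utils::combn(length(sets), 2L)
  mean(apply(pairs, 2L, function(ij) jaccard(sets[[ij[1L]]], sets[[ij[2L]]])))
}

#' Pairwise overlap statistics between two module sets
#'
#' For every pair of modules (one from each set) computes the intersection
#' count, the Jaccard index, and a one-sided Fisher exact p-value of the
#' overlap against the shared gene universe, BH-adjusted jointly over all
#' cells of the matrix. When the two sets are the same object (within-network
#' overlap) the diagonal is excluded from the BH family and its adjusted p is
#' `NA`.
#'
#' @param A,B `tgcn_module_set`s (or anything [module_members()] accepts)
#'   over the same universe; `B` defaults to `A`.
#' @param universe Character vector of background gene ids.
#' @param alpha Stored significance level (default 0.05).
#' @param within Logical: treat the comparison as within-network (exclude the
#'   diagonal)? Defaults to `TRUE` exactly when `B` is missing; pass `FALSE`
#'   when comparing two networks that happen to share content.
#' @return An object of class `module_overlap` with matrices `count`,
#'   `jaccard`, `p`, `p_adj` (rows = modules of `A`, columns = modules of
#'   `B`) and the `alpha` used.
#' @export
module_overlap_matrix <- function(A, B = A, universe, alpha = 0.05,
                                  within = NULL) {
  if (is.null(within)) within <- missing(B)
  mA <- module_members(A)
  mB <- module_members(B)
  mA <- lapply(mA, intersect, y = universe)
  mB <- lapply(mB, intersect, y = universe)
  same <- isTRUE(within)
  N <- length(universe)
  dims <- list(names(mA), names(mB))
  count <- jac <- p <- matrix(NA_real_, length(mA), length(mB), dimnames = dims)
  for (i in seq_along(mA)) {
    for (j in seq_along(mB)) {
      a <- mA[[i]]; b <- mB[[j]]
      k <- length(intersect(a, b))
      count[i, j] <- k
      jac[i, j] <- jaccard(a, b)
      tab <- matrix(c(k, length(b) - k,
                      length(a) - k, N - length(a) - length(b) + k), nrow = 2L)
      p[i, j] <- stats::fisher.test(tab, alternative = "greater")$p.value
    }
  }
  family <- if (same) which(row(p) != col(p)) else seq_along(p)
  p_adj <- matrix(NA_real_, nrow(p), ncol(p), dimnames = dims)
  p_adj[family] <- stats::p.adjust(p[family], method = "BH")
  structure(list(count = count, jaccard = jac, p = p, p_adj = p_adj,
                 alpha = alpha, within = same),
            class = "module_overlap")
}

#' @export
print.module_overlap <- function(x, ...) {
  sig <- sum(x$p_adj < x$alpha, na.rm = TRUE)
  cat(sprintf("<module_overlap> %d x %d module pairs; %d significant at BH %.2f%s\n",
              nrow(x$count), ncol(x$count), sig, x$alpha,
              if (x$within) " (within-network, diagonal excluded)" else ""))
  invisible(x)
}
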