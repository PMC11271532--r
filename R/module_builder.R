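#' Rank all transcripts by co-expression with a seed
#'
#' Co-expression of two transcripts is the absolute value of their Pearson
#' correlation. Returns every gene except the seed, sorted by decreasing
#' absolute correlation with the seed; ties are broken lexicographically by
#' gene id so the ranking is deterministic. Zero-variance genes get a
#' correlation of 0 and sort last.
#'
#' @param X samples x genes numeric matrix.
#' @param seed Seed gene id (must be a column of `X` with non-zero variance).
#' @return A data.frame with columns `gene` and `r` (signed Pearson
#'   correlation with the seed), ordered by decreasing `|r|`.
#' @export
rank_by_coexpression <- function(X, seed) {
  check_expression(X)
  if (!seed %in% colnames(X)) stop("seed '", seed, "' not in expression matrix")
  s <- X[, seed]
  if (stats::sd(s) == 0) stop("seed '", seed, "' has zero variance")
  others <- setdiff(colnames(X), seed)
  r <- suppressWarnings(
    as.vector(stats::cor(s, X[, others, drop = FALSE]))
  )
  r[is.na(r)] <- 0
  ord <- order(-abs(r), others)
  data.frame(gene = others[ord], r = r[ord], stringsAsFactors = FALSE)
}

# Assemble one module from a seed and a prefix of its co-expression ranking.
new_module <- function(seed, ranked, size, strategy,
                       no_growth = FALSE, abundance = NA_real_) {
  size <- min(size, nrow(ranked))
  top <- ranked[seq_len(size), , drop = FALSE]
  structure(list(seed = seed,
                 members = c(seed, top$gene),
                 correlations = stats::setNames(c(1, top$r),
                                                c(seed, top$gene)),
                 strategy = strategy,
                 no_growth = no_growth,
                 abundance = abundance),
            class = "tgcn_module")
}

new_module_set <- function(modules, universe) {
  names(modules) <- vapply(modules, `[[`, character(1L), "seed")
  structure(list(modules = modules, gene_universe = universe),
            class = "tgcn_module_set")
}

#' Extract member gene lists from a module set
#'
#' @param x A `tgcn_module_set`, a single `tgcn_module`, a named list of
#'   character vectors, or a partition (named character vector gene ->
#'   label).
#' @return A named list of character vectors (module -> members).
#' @export
module_members <- function(x) {
  if (inherits(x, "tgcn_module_set")) {
    lapply(x$modules, `[[`, "members")
  } else if (inherits(x, "tgcn_module")) {
    stats::setNames(list(x$members), x$seed)
  } else if (is.list(x)) {
    x
  } else if (is.character(x) && !is.null(names(x))) {
    split(names(x), unname(x))
  } else {
    stop("cannot interpret module container")
  }
}

#' Build fixed-size modules around each seed
#'
#' Every seed is treated as equally relevant: each module is the seed plus the
#' `size` transcripts most co-expressed with it. The seed is a member but is
#' not counted against the size budget, so `size = 100` yields modules of 101
#' transcripts.
#'
#' @param X samples x genes numeric matrix.
#' @param seeds Character vector of seed gene ids.
#' @param size Number of co-expressed transcripts per module (default 100).
#' @return A `tgcn_module_set`.
#' @export
build_fixed <- function(X, seeds, size = 100) {
  check_expression(X)
  if (size < 1 || size > ncol(X) - 1L) {
    stop("size must be in [1, n_genes - 1]")
  }
  modules <- lapply(seeds, function(s) {
    new_module(s, rank_by_coexpression(X, s), size, "fixed")
  })
  new_module_set(modules, colnames(X))
}

#' Build modules with sizes proportional to seed coefficients
#'
#' Seeds differ in relevance, as measured by the absolute value of their
#' coefficient in the seed linear model. The seed with the largest
#' |coefficient| gets the largest module (`max_size` transcripts) and module
#' `n` gets `S_n = S_1 * |beta_n| / |beta_1|` transcripts, rounded
#' half-to-even and clamped to `[min_size, max_size]`. Membership is by
#' co-expression rank, as in [build_fixed()]; the seed itself does not count
#' against the budget.
#'
#' @param X samples x genes numeric matrix.
#' @param model A [fit_seed_model()] `trait_model` supplying the seeds and
#'   coefficients.
#' @param max_size Size of the largest module (default 100).
#' @param min_size Lower clamp on module sizes (default 10).
#' @return A `tgcn_module_set`.
#' @export
build_proportional <- function(X, model, max_size = 100, min_size = 10) {
  check_expression(X)
  stopifnot(inherits(model, "trait_model"))
  beta <- abs(model$coefficients[model$seeds])
  if (anyNA(beta)) stop("model lacks coefficients for some seeds")
  b1 <- max(beta)
  if (b1 == 0) stop("all seed coefficients are zero; no informative seeds")
  sizes <- pmin(pmax(round(max_size * beta / b1), min_size), max_size)
  sizes <- pmin(sizes, ncol(X) - 1L)
  ord <- order(-beta, names(beta))
  modules <- lapply(names(beta)[ord], function(s) {
    new_module(s, rank_by_coexpression(X, s), sizes[[s]], "proportional")
  })
  new_module_set(modules, colnames(X))
}

# Two-sided p-value of a Pearson correlation via the t distribution with
# n - 2 degrees of freedom.
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  p <- numeric(length(r))
  exact <- abs(r) >= 1
  p[exact] <- 0
  t_stat <- abs(r[!exact]) * sqrt((n - 2) / (1 - r[!exact]^2))
  p[!exact] <- 2 * stats::pt(t_stat, df = n - 2, lower.tail = FALSE)
  p
}

#' Build modules by iterative enrichment-driven growth
#'
#' For each seed, start from the `step` transcripts most co-expressed with it
#' and repeatedly try to add the next `step` transcripts from the
#' co-expression ranking. A batch is accepted only if (a) every added
#' transcript's correlation with the seed is significant after
#' Benjamini-Hochberg correction at `alpha` within the batch, and (b) the
#' functional abundance of the grown module strictly improves on the current
#' one. Growth stops at the first rejected batch or at `max_size`. Modules
#' whose very first growth attempt fails keep their initial `step`
#' transcripts and carry a `no_growth` flag.
#'
#' @param X samples x genes numeric matrix.
#' @param seeds Character vector of seed gene ids.
#' @param db A [gene_set_db()] used for the functional-abundance gate.
#' @param step Batch size for growth (default 10).
#' @param alpha BH significance level for both gates (default 0.05).
#' @param max_size Maximum number of co-expressed transcripts per module
#'   (default 100; the seed is not counted).
#' @return A `tgcn_module_set`; each module records its final functional
#'   abundance and `no_growth` flag.
#' @export
build_enrichment <- function(X, seeds, db, step = 10, alpha = 0.05,
                             max_size = 100) {
  check_expression(X)
  stopifnot(inherits(db, "gene_set_db"))
  if (!length(db$terms)) stop("gene-set collection is empty")
  universe <- colnames(X)
  n <- nrow(X)
  modules <- lapply(seeds, function(s) {
    ranked <- rank_by_coexpression(X, s)
    cap <- min(max_size, nrow(ranked))
    size <- min(step, cap)
    ab_old <- functional_abundance(c(s, ranked$gene[seq_len(size)]),
                                   db, universe, alpha)
    grew <- FALSE
    while (size < cap) {
      batch_n <- min(step, cap - size)
      batch <- ranked[(size + 1L):(size + batch_n), , drop = FALSE]
      p_adj <- stats::p.adjust(cor_pvalue(batch$r, n), method = "BH")
      if (any(p_adj >= alpha)) break
      ab_new <- functional_abundance(
        c(s, ranked$gene[seq_len(size + batch_n)]), db, universe, alpha)
      if (!(ab_new > ab_old)) break
      size <- size + batch_n
      ab_old <- ab_new
      grew <- TRUE
    }
    new_module(s, ranked, size, "enrichment",
               no_growth = !grew, abundance = ab_old)
  })
  new_module_set(modules, colnames(X))
}

#' @export
print.tgcn_module <- function(x, ...) {
  cat(sprintf("<module '%s'> %d members (%s)%s\n", x$seed, length(x$members),
              x$strategy, if (isTRUE(x$no_growth)) " [no-enrichment-growth]" else ""))
  invisible(x)
}

#' @export
print.tgcn_module_set <- function(x, ...) {
  sizes <- lengths(module_members(x))
  cat(sprintf("<module_set> %d modules over %d genes; sizes %d-%d (median %d)\n",
              length(x$modules), length(x$gene_universe),
              min(sizes), max(sizes), as.integer(stats::median(sizes))))
  invisible(x)
}

#' Write a module set as a long-format table
#'
#' Columns: `module` (seed id), `gene`, `r` (signed Pearson correlation with
#' the seed), `rank` (1 = the seed itself).
#'
#' @param ms A `tgcn_module_set`.
#' @param path Output TSV path; when `NULL` the data.frame is returned only.
#' @return The long-format data.frame, invisibly when written.
#' @export
write_modules <- function(ms, path = NULL) {
  stopifnot(inherits(ms, "tgcn_module_set"))
  rows <- do.call(rbind, lapply(ms$modules, function(m) {
    data.frame(module = m$seed, gene = m$members,
               r = unname(m$correlations[m$members]),
               rank = seq_along(m$members), stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  if (!is.null(path)) {
    utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(rows))
  }
  rows
}
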