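#' Module eigengene
#'
#' The eigengene of a module is the first principal component of the samples
#' x members expression submatrix (genes centered), the module's summary
#' profile. Its sign is oriented so that the mean correlation of the members
#' with the eigengene is positive, making downstream trait correlations
#' reproducible.
#'
#' @param X samples x genes numeric matrix (z-scored upstream in the standard
#'   pipeline).
#' @param module A `tgcn_module` or a character vector of member gene ids
#'   (length >= 2).
#' @return An object of class `eigengene` with `module_label`, `values`
#'   (named by sample), `variance_explained` (fraction of the submatrix
#'   variance carried by PC1), and the unit-norm `loadings`.
#' @export
compute_eigengene <- function(X, module) {
  check_expression(X)
  members <- if (inherits(module, "tgcn_module")) module$members else as.character(module)
  label <- if (inherits(module, "tgcn_module")) module$seed else members[1L]
  missing <- setdiff(members, colnames(X))
  if (length(missing)) {
    stop("module members absent from expression matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  if (length(members) < 2L) stop("eigengene needs at least 2 member genes")
  M <- X[, members, drop = FALSE]
  Mc <- scale(M, center = TRUE, scale = FALSE)
  sv <- svd(Mc)
  if (sv$d[1L] < .Machine$double.eps * max(dim(Mc))) {
    stop("module submatrix has rank 0; eigengene undefined")
  }
  e <- sv$u[, 1L] * sv$d[1L]
  loadings <- sv$v[, 1L]
  cors <- suppressWarnings(as.vector(stats::cor(e, M)))
  if (mean(cors, na.rm = TRUE) < 0) {
    e <- -e
    loadings <- -loadings
  }
  structure(list(module_label = label,
                 values = stats::setNames(e, rownames(X)),
                 variance_explained = sv$d[1L]^2 / sum(sv$d^2),
                 loadings = stats::setNames(loadings, members)),
            class = "eigengene")
}

#' Associate a module eigengene with a trait
#'
#' Continuous traits are tested by Pearson correlation with a t-test p-value;
#' binary (0/1) traits by the point-biserial correlation, numerically the
#' same Pearson statistic and equivalent to a two-sample t-test. BH
#' adjustment across the modules of a network is the caller's job.
#'
#' @param E An [compute_eigengene()] object or numeric vector of per-sample
#'   scores.
#' @param t A [trait()] or numeric vector aligned to the samples.
#' @return A list with `statistic` (the correlation), `p_value`, and
#'   `method`.
#' @export
trait_association <- function(E, t) {
  e <- if (inherits(E, "eigengene")) E$values else E
  tv <- if (inherits(t, "tgcn_trait")) t$values else t
  if (!is.null(names(e)) && !is.null(names(tv))) tv <- tv[names(e)]
  if (length(e) != length(tv)) stop("eigengene and trait are not aligned")
  kind <- if (inherits(t, "tgcn_trait")) t$kind else "continuous"
  method <- if (kind == "binary") "point-biserial" else "pearson"
  if (stats::sd(e) == 0) {
    warning("constant eigengene; trait association undefined")
    return(list(statistic = NA_real_, p_value = NA_real_, method = method))
  }
  ct <- stats::cor.test(as.numeric(e), as.numeric(tv), method = "pearson")
  list(statistic = unname(ct$estimate), p_value = ct$p.value, method = method)
}

# One-sided Fisher over-representation of `genes` in each term of `db`,
# against `universe`. Terms with no gene in the universe are dropped (with a
# warning when warn_empty). Returns term_id, term_name, overlap, term_size,
# p_raw.
enrich_fisher <- function(genes, db, universe, warn_empty = FALSE) {
  stopifnot(inherits(db, "gene_set_db"))
  genes <- unique(intersect(genes, universe))
  N <- length(universe)
  ng <- length(genes)
  rows <- lapply(names(db$terms), function(id) {
    tg <- intersect(db$terms[[id]], universe)
    if (!length(tg)) {
      if (warn_empty) {
        warning("term '", id, "' shares no genes with the universe; skipped")
      }
      return(NULL)
    }
    k <- length(intersect(genes, tg))
    tab <- matrix(c(k, length(tg) - k,
                    ng - k, N - length(tg) - ng + k), nrow = 2L)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(term_id = id, term_name = unname(db$term_names[[id]]),
               overlap = k, term_size = length(tg), p_raw = p,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    rows <- data.frame(term_id = character(0), term_name = character(0),
                       overlap = integer(0), term_size = integer(0),
                       p_raw = numeric(0))
  }
  rownames(rows) <- NULL
  rows
}

#' Functional enrichment of a gene set
#'
#' Per-term one-sided Fisher exact over-representation tests of the gene set
#' against a local gene-set collection, BH-adjusted across terms. The
#' enrichment universe is the full expression gene list (not the union of the
#' collection), which must be supplied explicitly because the choice changes
#' the p-values.
#'
#' @param genes A `tgcn_module` or character vector of gene ids.
#' @param db A [gene_set_db()].
#' @param universe Character vector of background gene ids.
#' @param alpha Significance level on the BH-adjusted p-values (default
#'   0.05); significant rows feed the functional-abundance score.
#' @param warn_empty Warn about terms with no gene in the universe (used by
#'   [celltype_enrichment()]).
#' @return An object of class `enrichment_result`: `geneset_label`, `rows`
#'   (term_id, term_name, overlap, term_size, p_raw, p_adj, significant),
#'   `source_label` and `functional_abundance`.
#' @export
functional_enrichment <- function(genes, db, universe, alpha = 0.05,
                                  warn_empty = FALSE) {
  label <- if (inherits(genes, "tgcn_module")) genes$seed else "geneset"
  gvec <- if (inherits(genes, "tgcn_module")) genes$members else as.character(genes)
  rows <- enrich_fisher(gvec, db, universe, warn_empty = warn_empty)
  rows$p_adj <- stats::p.adjust(rows$p_raw, method = "BH")
  rows$significant <- rows$p_adj < alpha
  rows <- rows[order(rows$p_raw, rows$term_id), , drop = FALSE]
  rownames(rows) <- NULL
  fa <- if (any(rows$significant)) {
    sum(-log10(rows$p_raw[rows$significant])) / length(unique(gvec))
  } else 0
  structure(list(geneset_label = label, rows = rows,
                 source_label = db$source_label,
                 functional_abundance = fa),
            class = "enrichment_result")
}

#' Cell-type marker enrichment of a module
#'
#' One-sided Fisher exact test of the module members against each cell-type
#' marker set, BH-adjusted across marker sets. Marker sets sharing no gene
#' with the universe are skipped with a warning.
#'
#' @param module A `tgcn_module` or character vector of member gene ids.
#' @param markers A [gene_set_db()] of cell-type marker sets.
#' @param universe Background gene ids (must contain the module members).
#' @param alpha BH significance level (default 0.05).
#' @return An `enrichment_result` (see [functional_enrichment()]).
#' @export
celltype_enrichment <- function(module, markers, universe, alpha = 0.05) {
  gvec <- if (inherits(module, "tgcn_module")) module$members else as.character(module)
  outside <- setdiff(gvec, universe)
  if (length(outside)) {
    stop("module members outside the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  }
  functional_enrichment(module, markers, universe, alpha, warn_empty = TRUE)
}

#' Functional abundance of a gene set
#'
#' A scalar summarising how densely annotated a gene set is: run the Fisher
#' enrichment of the set against the collection, BH-adjust, keep the
#' significant terms, and return
#' \deqn{\frac{1}{|G|} \sum_i -\log_{10} p(t_i)}
#' over the kept terms, where |G| is the gene-set size. The p entering the sum
#' is the raw enrichment p-value of each BH-significant term by default
#' (`p_use = "adjusted"` switches to the adjusted one). Zero when no term is
#' significant.
#'
#' @param G A `tgcn_module` or character vector of gene ids.
#' @param db A [gene_set_db()].
#' @param universe Background gene ids.
#' @param alpha BH significance level deciding which terms count (default
#'   0.05).
#' @param p_use `"raw"` (default) or `"adjusted"`: which p-value enters the
#'   sum.
#' @return A non-negative scalar.
#' @export
functional_abundance <- function(G, db, universe, alpha = 0.05,
                                 p_use = c("raw", "adjusted")) {
  p_use <- match.arg(p_use)
  gvec <- if (inherits(G, "tgcn_module")) G$members else as.character(G)
  if (!length(gvec)) stop("gene set is empty")
  res <- functional_enrichment(gvec, db, universe, alpha)
  rows <- res$rows
  if (!any(rows$significant)) return(0)
  p <- if (p_use == "raw") rows$p_raw else rows$p_adj
  sum(-log10(p[rows$significant])) / length(unique(gvec))
}

#' Annotate every module of a network
#'
#' Builds the per-module summary that the pipeline report is based on:
#' eigengene variance explained, trait association (BH-adjusted across
#' modules), best cell-type marker enrichment, top functional terms and
#' functional abundance.
#'
#' @param ms A `tgcn_module_set`.
#' @param X samples x genes numeric matrix.
#' @param traits A [trait()] or list of traits.
#' @param db Optional [gene_set_db()] for functional enrichment.
#' @param markers Optional [gene_set_db()] of cell-type markers.
#' @param alpha Significance level (default 0.05).
#' @return A data.frame with one row per module.
#' @export
annotate_modules <- function(ms, X, traits, db = NULL, markers = NULL,
                             alpha = 0.05) {
  stopifnot(inherits(ms, "tgcn_module_set"))
  if (inherits(traits, "tgcn_trait")) traits <- list(traits)
  universe <- colnames(X)
  eig <- lapply(ms$modules, function(m) compute_eigengene(X, m))
  out <- data.frame(module = names(ms$modules),
                    size = unname(lengths(module_members(ms))),
                    variance_explained = vapply(eig, `[[`, numeric(1L),
                                                "variance_explained"),
                    stringsAsFactors = FALSE)
  for (tr in traits) {
    assoc <- lapply(eig, trait_association, t = tr)
    r <- vapply(assoc, `[[`, numeric(1L), "statistic")
    p <- vapply(assoc, `[[`, numeric(1L), "p_value")
    out[[paste0(tr$name, "_cor")]] <- unname(r)
    out[[paste0(tr$name, "_p_adj")]] <- stats::p.adjust(p, method = "BH")
  }
  if (!is.null(markers)) {
    ct <- lapply(ms$modules, function(m)
      celltype_enrichment(m, markers, universe, alpha))
    out$celltype <- vapply(ct, function(e) {
      sig <- e$rows[e$rows$significant, , drop = FALSE]
      if (!nrow(sig)) return(NA_character_)
      sig$term_id[which.min(sig$p_raw)]
    }, character(1L))
    out$celltype_p_adj <- vapply(ct, function(e) {
      if (!nrow(e$rows)) return(NA_real_)
      min(e$rows$p_adj)
    }, numeric(1L))
  }
  if (!is.null(db)) {
    fe <- lapply(ms$modules, function(m)
      functional_enrichment(m, db, universe, alpha))
    out$top_terms <- vapply(fe, function(e) {
      sig <- e$rows[e$rows$significant, , drop = FALSE]
      if (!nrow(sig)) return(NA_character_)
      paste(utils::head(sig$term_id, 3L), collapse = ";")
    }, character(1L))
    out$functional_abundance <- vapply(fe, `[[`, numeric(1L),
                                       "functional_abundance")
  }
  rownames(out) <- NULL
  out
}

#' @export
print.eigengene <- function(x, ...) {
  cat(sprintf("<eigengene '%s'> n = %d samples, %.1f%% variance explained\n",
              x$module_label, length(x$values), 100 * x$variance_explained))
  invisible(x)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment '%s' vs %s> %d terms, %d significant; abundance %.3f\n",
              x$geneset_label, x$source_label, nrow(x$rows),
              sum(x$rows$significant), x$functional_abundance))
  invisible(x)
}
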