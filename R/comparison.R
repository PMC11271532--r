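#' Module membership within a genome-wide partition
#'
#' Module membership (MM) of a gene is the Pearson correlation between its
#' expression profile and the eigengene of the module it is assigned to, the
#' standard proxy for intramodular connectivity ("hubness") in WGCNA-style
#' networks. The percentile of MM is computed within each module. Singleton
#' modules get MM = 1 by convention and are flagged.
#'
#' @param X samples x genes numeric matrix.
#' @param partition Named character vector mapping gene id -> module label
#'   (see [read_partition()]); genes must be columns of `X`.
#' @return A data.frame with columns `gene`, `module`, `MM`,
#'   `MM_percentile`, `singleton`.
#' @export
module_membership <- function(X, partition) {
  check_expression(X)
  missing <- setdiff(names(partition), colnames(X))
  if (length(missing)) {
    stop("partition genes absent from expression matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  groups <- split(names(partition), unname(partition))
  rows <- lapply(names(groups), function(lab) {
    g <- groups[[lab]]
    if (length(g) == 1L) {
      return(data.frame(gene = g, module = lab, MM = 1, MM_percentile = 100,
                        singleton = TRUE, stringsAsFactors = FALSE))
    }
    eg <- compute_eigengene(X, g)
    mm <- as.vector(suppressWarnings(
      stats::cor(eg$values, X[, g, drop = FALSE])))
    mm[is.na(mm)] <- 0
    data.frame(gene = g, module = lab, MM = mm,
               MM_percentile = 100 * rank(mm) / length(mm),
               singleton = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overlap of partition hub transcripts with TGCN modules
#'
#' For each module of a genome-wide partition, the `top_k` transcripts with
#' the highest |MM| (the hub transcripts; |MM| stands in for the intramodular
#' adjacency computed by full WGCNA) are tested by one-sided Fisher exact
#' test against every TGCN module, with BH adjustment over all hub-set x
#' module tests. Reported is the fraction of hub sets with at least one
#' significant overlap. Modules smaller than `top_k` contribute all their
#' genes.
#'
#' @param X samples x genes numeric matrix.
#' @param partition Named character vector gene -> module label.
#' @param tgcn A `tgcn_module_set`.
#' @param top_k Hub set size per partition module (default 10).
#' @param alpha BH significance level (default 0.05).
#' @return A list with `fraction` (hub sets with >= 1 significant TGCN
#'   overlap), `hubs` (named list of hub gene sets), and the full `overlap`
#'   matrix object.
#' @export
hub_overlap <- function(X, partition, tgcn, top_k = 10, alpha = 0.05) {
  mm <- module_membership(X, partition)
  hubs <- lapply(split(mm, mm$module), function(g) {
    g$gene[order(-abs(g$MM), g$gene)][seq_len(min(top_k, nrow(g)))]
  })
  ov <- module_overlap_matrix(hubs, module_members(tgcn), colnames(X), alpha)
  hit <- rowSums(ov$p_adj < alpha, na.rm = TRUE) >= 1L
  list(fraction = mean(hit), hubs = hubs, overlap = ov)
}

#' Cross-tabulate a TGCN against a genome-wide partition
#'
#' Counts, for every partition module (rows) and TGCN module (columns), the
#' genes they share; transcripts of a partition module used by no TGCN module
#' fall in the rightmost `none` column, so when TGCN modules are disjoint
#' each row sums exactly to the partition module size. Per-cell significance
#' is a one-sided Fisher exact test BH-adjusted over all cells (the `none`
#' column is not tested). The summary reports the fraction of TGCN modules
#' whose significant overlaps involve exactly one partition module
#' ("included within a single partition module") and the fraction of
#' partition modules contributing significantly to more than one TGCN
#' module.
#'
#' @param tgcn A `tgcn_module_set`.
#' @param partition Named character vector gene -> module label.
#' @param universe Background gene ids (default: the TGCN gene universe).
#' @param alpha BH significance level (default 0.05).
#' @return A list with `counts`, `p_adj`, and `summary` (a list with
#'   `frac_tgcn_in_single_partition` and `frac_partition_to_multiple`).
#' @export
crosstab <- function(tgcn, partition, universe = NULL, alpha = 0.05) {
  stopifnot(inherits(tgcn, "tgcn_module_set"))
  if (is.null(universe)) universe <- tgcn$gene_universe
  pmods <- lapply(split(names(partition), unname(partition)),
                  intersect, y = universe)
  tmods <- lapply(module_members(tgcn), intersect, y = universe)
  tgcn_genes <- unique(unlist(tmods))
  counts <- matrix(0L, length(pmods), length(tmods) + 1L,
                   dimnames = list(names(pmods), c(names(tmods), "none")))
  p <- matrix(NA_real_, length(pmods), length(tmods),
              dimnames = list(names(pmods), names(tmods)))
  N <- length(universe)
  for (i in seq_along(pmods)) {
    a <- pmods[[i]]
    for (j in seq_along(tmods)) {
      b <- tmods[[j]]
      k <- length(intersect(a, b))
      counts[i, j] <- k
      tab <- matrix(c(k, length(b) - k,
                      length(a) - k, N - length(a) - length(b) + k), nrow = 2L)
      p[i, j] <- stats::fisher.test(tab, alternative = "greater")$p.value
    }
    counts[i, length(tmods) + 1L] <- length(setdiff(a, tgcn_genes))
  }
  p_adj <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p),
                  dimnames = dimnames(p))
  sig <- p_adj < alpha
  per_tgcn <- colSums(sig)  # partition partners per TGCN module
  per_part <- rowSums(sig)  # TGCN partners per partition module
  summary <- list(
    frac_tgcn_in_single_partition = mean(per_tgcn == 1L),
    frac_partition_to_multiple = mean(per_part > 1L))
  list(counts = counts, p_adj = p_adj, summary = summary)
}
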