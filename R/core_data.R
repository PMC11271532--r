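#' Read an expression matrix from delimited text
#'
#' Reads a TSV/CSV file with one header row and one ID column and returns a
#' numeric matrix in samples x genes orientation, whatever the orientation of
#' the file. Duplicated gene symbols are resolved by keeping the copy with the
#' highest mean expression (with a warning); duplicated sample IDs are an
#' error, as are missing or non-numeric cells.
#'
#' @param path Path to a delimited text file. The separator is inferred from
#'   the extension (`.csv` gives comma, anything else tab) unless `sep` is
#'   given.
#' @param orientation Either `"samples_by_genes"` (rows are samples) or
#'   `"genes_by_samples"` (rows are genes; the matrix is transposed on read).
#' @param sep Optional field separator overriding the extension heuristic.
#' @return A numeric matrix with sample IDs as rownames and gene symbols as
#'   colnames.
#' @export
read_expression <- function(path,
                            orientation = c("samples_by_genes", "genes_by_samples"),
                            sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, quote = "",
                      check.names = FALSE, stringsAsFactors = FALSE,
                      comment.char = ""),
    error = function(e) stop("cannot parse expression file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("expression file '", path, "' has no data rows/columns")
  }
  ids <- as.character(raw[[1L]])
  cn <- colnames(raw)[-1L]  # data.frame subsetting would mangle duplicates
  vals <- raw[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & trimws(col) != "NA")
      if (length(bad)) {
        stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                     col[bad[1L]], ids[bad[1L]], cn[j]))
      }
      vals[[j]] <- num
    }
  }
  M <- as.matrix(vals)
  dimnames(M) <- list(ids, cn)
  if (orientation == "genes_by_samples") M <- t(M)
  if (anyDuplicated(rownames(M))) {
    stop("duplicated sample IDs: ",
         paste(unique(rownames(M)[duplicated(rownames(M))]), collapse = ", "))
  }
  M <- resolve_duplicate_genes(M)
  check_expression(M)
  M
}

# Keep, for each duplicated gene symbol, the column with the highest mean
# expression; warn with the affected symbols.
resolve_duplicate_genes <- function(M) {
  dup <- unique(colnames(M)[duplicated(colnames(M))])
  if (!length(dup)) return(M)
  warning("duplicated gene symbols resolved by keeping the highest-mean copy: ",
          paste(dup, collapse = ", "))
  keep <- rep(TRUE, ncol(M))
  mu <- colMeans(M)
  for (g in dup) {
    idx <- which(colnames(M) == g)
    keep[idx] <- FALSE
    keep[idx[which.max(mu[idx])]] <- TRUE
  }
  M[, keep, drop = FALSE]
}

# Validate the samples x genes matrix contract used across the package.
check_expression <- function(X) {
  if (!is.matrix(X) || !is.numeric(X)) stop("expression must be a numeric matrix")
  if (is.null(rownames(X)) || is.null(colnames(X))) {
    stop("expression matrix must carry sample rownames and gene colnames")
  }
  if (anyDuplicated(rownames(X))) stop("duplicated sample IDs")
  if (anyDuplicated(colnames(X))) stop("duplicated gene IDs")
  if (anyNA(X)) {
    stop("expression matrix contains missing values; remove or refuse the ",
         "affected rows/columns upstream (imputation is not performed)")
  }
  invisible(X)
}

#' Write an expression matrix to tab-delimited text
#'
#' Values are written with 17 significant digits so that
#' `read_expression(write_expression(X))` round-trips to full double
#' precision.
#'
#' @param X samples x genes numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(X, path) {
  check_expression(X)
  chr <- formatC(X, digits = 17, format = "g")
  out <- cbind(sample_id = rownames(X), chr)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Preprocess an expression matrix
#'
#' Applies an ordered subset of the standard transforms: `log2p1`
#' (\eqn{x \to \log_2(x+1)}), `quantile` (quantile normalization so that every
#' sample shares the same value distribution, per-rank mean reference with tie
#' averaging), and `zscore` (each gene standardized to mean 0, sd 1 across
#' samples). Genes with zero variance are dropped with a warning under
#' `zscore`.
#'
#' @param X samples x genes numeric matrix.
#' @param steps Character vector, ordered subset of
#'   `c("log2p1", "quantile", "zscore")`.
#' @return The transformed matrix.
#' @export
preprocess <- function(X, steps = c("log2p1", "quantile", "zscore")) {
  check_expression(X)
  steps <- match.arg(steps, c("log2p1", "quantile", "zscore"),
                     several.ok = TRUE)
  for (s in steps) {
    X <- switch(s,
      log2p1 = {
        if (min(X) < 0) stop("log2p1 requires non-negative values")
        log2(X + 1)
      },
      quantile = {
        # limma normalizes columns-as-arrays; our samples are rows
        t(limma::normalizeQuantiles(t(X), ties = TRUE))
      },
      zscore = {
        sds <- apply(X, 2L, stats::sd)
        if (any(sds == 0)) {
          warning("dropping ", sum(sds == 0),
                  " zero-variance gene(s) before z-scoring: ",
                  paste(utils::head(colnames(X)[sds == 0], 5L), collapse = ", "))
          X <- X[, sds > 0, drop = FALSE]
        }
        scale(X)[, , drop = FALSE]
      })
  }
  # scale() attaches attributes; return a clean matrix
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  X
}

#' Filter genes on minimum expression
#'
#' Keeps genes whose median expression exceeds `min_median`. Intended to run
#' before z-scoring, mirroring the usual minimum-expression retention step of
#' bulk RNA-seq pipelines; the default keeps genes with median > 0.
#'
#' @param X samples x genes numeric matrix.
#' @param min_median Threshold on the per-gene median (default 0).
#' @return The filtered matrix.
#' @export
filter_genes <- function(X, min_median = 0) {
  check_expression(X)
  med <- apply(X, 2L, stats::median)
  X[, med > min_median, drop = FALSE]
}

#' Construct a trait
#'
#' A trait is a named numeric vector aligned to the samples of an expression
#' matrix: continuous (e.g. age, or the expression of one target gene) or
#' binary case/control coded \{0,1\}.
#'
#' @param name Trait name.
#' @param values Numeric vector; names, when present, are sample IDs.
#' @param kind `"continuous"` or `"binary"`.
#' @return An object of class `tgcn_trait`.
#' @export
trait <- function(name, values, kind = c("continuous", "binary")) {
  kind <- match.arg(kind)
  if (!is.numeric(values) || !length(values)) stop("trait values must be a non-empty numeric vector")
  if (anyNA(values)) stop("trait contains missing values")
  if (stats::var(values) == 0) stop("trait has zero variance")
  if (kind == "binary" && !all(values %in% c(0, 1))) {
    stop("binary traits must be coded {0,1}")
  }
  structure(list(name = name, kind = kind, values = values),
            class = "tgcn_trait")
}

# Resolve a trait (or plain numeric vector) against the rows of X, returning
# the numeric vector in X's sample order.
trait_values <- function(y, X) {
  v <- if (inherits(y, "tgcn_trait")) y$values else y
  if (!is.numeric(v)) stop("trait must be numeric or a tgcn_trait")
  if (!is.null(names(v))) {
    missing <- setdiff(rownames(X), names(v))
    if (length(missing)) {
      stop("trait is missing values for samples: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
    v <- v[rownames(X)]
  } else if (length(v) != nrow(X)) {
    stop("trait length (", length(v), ") does not match sample count (",
         nrow(X), ")")
  }
  unname(v)
}

#' Read a trait/covariate table
#'
#' Tab-delimited table with a `sample_id` column; remaining columns are traits
#' or covariates.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with rownames set to `sample_id`.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df)) stop("trait table must have a 'sample_id' column")
  if (anyDuplicated(df$sample_id)) stop("duplicated sample IDs in trait table")
  rownames(df) <- df$sample_id
  df
}

#' Construct a gene-set collection
#'
#' @param terms Named list of character vectors (term id -> genes).
#' @param term_names Optional named character vector of human-readable term
#'   descriptions.
#' @param source_label Label for the collection (e.g. `"GO"`, `"celltype"`).
#' @return An object of class `gene_set_db`.
#' @export
gene_set_db <- function(terms, term_names = NULL, source_label = "geneset") {
  if (!length(terms) || is.null(names(terms))) stop("terms must be a non-empty named list")
  if (anyDuplicated(names(terms))) stop("duplicated term ids")
  terms <- lapply(terms, function(g) unique(as.character(g)))
  if (any(!lengths(terms))) stop("every gene set must be non-empty")
  if (is.null(term_names)) {
    term_names <- stats::setNames(names(terms), names(terms))
  }
  structure(list(terms = terms,
                 term_names = term_names[names(terms)],
                 source_label = source_label),
            class = "gene_set_db")
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one term per line, `term_id TAB description TAB gene1 TAB
#' gene2 ...`. Genes are deduplicated within a term; duplicated term ids and
#' lines with fewer than three fields are errors.
#'
#' @param path Path to the GMT file.
#' @param source_label Label recorded on the collection.
#' @return A [gene_set_db()] object.
#' @export
read_gmt <- function(path, source_label = "geneset") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("GMT file '", path, "' is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop("GMT line ", short[1L], " has fewer than 3 tab-separated fields")
  }
  ids <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicated term ids in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  descs <- stats::setNames(vapply(fields, `[[`, character(1L), 2L), ids)
  terms <- stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])), ids)
  gene_set_db(terms, descs, source_label)
}

#' Write gene sets in GMT format
#'
#' @param db A [gene_set_db()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "gene_set_db"))
  lines <- vapply(names(db$terms), function(id) {
    paste(c(id, db$term_names[[id]], db$terms[[id]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-to-module partition
#'
#' Two-column tab-delimited file `gene_id TAB module_label`, as produced by
#' genome-wide clustering tools (WGCNA-style partitions). Each gene belongs to
#' exactly one module.
#'
#' @param path Path to the TSV file (no header expected; a `gene`/`module`
#'   header row is tolerated).
#' @return A named character vector mapping gene id to module label.
#' @export
read_partition <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("partition file must have two columns")
  if (identical(tolower(df[1L, 1L]), "gene")) df <- df[-1L, , drop = FALSE]
  part <- stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
  if (anyDuplicated(names(part))) stop("a gene appears twice in the partition")
  if (any(!nzchar(part))) stop("empty module labels in partition")
  if (!length(part)) stop("partition is empty")
  part
}

#' @export
print.gene_set_db <- function(x, ...) {
  cat(sprintf("<gene_set_db '%s'> %d terms, %d distinct genes\n",
              x$source_label, length(x$terms),
              length(unique(unlist(x$terms)))))
  invisible(x)
}

#' @export
print.tgcn_trait <- function(x, ...) {
  cat(sprintf("<trait '%s'> %s, n = %d\n", x$name, x$kind, length(x$values)))
  invisible(x)
}
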