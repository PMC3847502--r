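#' Construct an expression matrix with sample metadata
#'
#' The central container of the package: a genes x samples matrix of log2
#' expression values together with the condition and replicate of every
#' sample column. All downstream stages (differential expression,
#' transcript-group classification, clustering, panel reports) consume this
#' object.
#'
#' @param values Numeric matrix, genes in rows (rownames are gene ids),
#'   one column per array/sample. All values must be finite.
#' @param condition Character vector, one condition label per column.
#' @param replicate Integer vector, one replicate index per column. If
#'   `NULL`, replicates are numbered 1..k within each condition in column
#'   order.
#' @return An object of class `expr_matrix`: a list with elements
#'   `values` (the matrix, columns relabelled `condition.replicate`) and
#'   `samples` (a data.frame with columns `label`, `condition`,
#'   `replicate`).
#' @export
expr_matrix <- function(values, condition, replicate = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("gene ids (rownames) must be present and unique")
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("expression values must be finite numerics")
  if (length(condition) != ncol(values))
    stop("one condition label is required per column")
  condition <- as.character(condition)
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(condition), condition, FUN = seq_along)
  }
  replicate <- as.integer(replicate)
  key <- paste(condition, replicate, sep = ".")
  if (anyDuplicated(key))
    stop("every (condition, replicate) pair must be unique")
  colnames(values) <- key
  structure(
    list(values = values,
         samples = data.frame(label = key, condition = condition,
                              replicate = replicate,
                              stringsAsFactors = FALSE)),
    class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cond <- table(x$samples$condition)
  cat(sprintf("expr_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s n=%d", names(cond), cond), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene identifiers of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of gene ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' Condition labels of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of distinct condition labels, in column order.
#' @export
conditions <- function(x) unique(x$samples$condition)

replicate_count <- function(x, cond) sum(x$samples$condition == cond)

#' Read a gene x sample expression table from TSV
#'
#' The expected layout is one header row, a `gene_id` first column, and one
#' column per sample named `condition.replicate` (e.g. `glucose.1`). The
#' replicate index is everything after the final dot.
#'
#' @param path Path to a tab-separated file.
#' @param raw If `TRUE`, values are raw intensities and are transformed to
#'   `log2(x + 1)`; by default values are taken as already on the log2
#'   scale.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, raw = FALSE) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs gene_id plus >=1 sample column")
  ids <- as.character(tab[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate gene_id rows: ", paste(unique(dup), collapse = ", "))
  vals <- tab[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop(sprintf("non-numeric value in column '%s', row %d",
                   names(vals)[j], bad))
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (raw) {
    if (any(m < 0)) stop("raw intensities must be non-negative")
    m <- log2(m + 1)
  }
  labels <- colnames(m)
  pos <- regexpr("\\.[^.]*$", labels)
  if (any(pos < 0L))
    stop("sample columns must be named condition.replicate")
  cond <- substr(labels, 1L, pos - 1L)
  rep_ <- suppressWarnings(as.integer(substring(labels, pos + 1L)))
  if (any(is.na(rep_)))
    stop("sample columns must end in a numeric replicate index")
  expr_matrix(m, cond, rep_)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]: `gene_id` first column, then one column
#' per sample labelled `condition.replicate`.
#'
#' @param x An `expr_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  out <- data.frame(gene_id = gene_ids(x), x$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
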