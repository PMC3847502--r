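#' Per-condition mean log2 expression
#'
#' Arithmetic mean of the log2 replicate values within each condition; the
#' gene x condition matrix that clustering and the heat maps operate on.
#'
#' @param x An [expr_matrix()].
#' @return Numeric matrix, genes x conditions (condition column order as in
#'   the input).
#' @export
condition_means <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  conds <- conditions(x)
  out <- vapply(conds, function(cond)
    rowMeans(x$values[, x$samples$condition == cond, drop = FALSE]),
    numeric(nrow(x$values)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(gene_ids(x), conds))
  out
}

#' Hierarchical clustering of gene expression profiles
#'
#' Agglomerative clustering on pairwise Euclidean distances between
#' per-gene condition-mean vectors. Genes are sorted lexicographically by
#' id before clustering, which makes the result invariant to input row
#' order and gives a deterministic tie-break. Duplicate profiles (distance
#' zero) are legal and merge first.
#'
#' @param means Numeric matrix of per-gene condition means (rownames are
#'   gene ids), e.g. from [condition_means()].
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return An object of class `gene_dendrogram`: list with the underlying
#'   `hclust` object, `leaf_order` (gene ids in display order),
#'   `merge_heights`, and `newick` (the tree serialized with branch
#'   lengths derived from merge heights).
#' @export
hierarchical_cluster <- function(means,
                                 linkage = c("average", "complete",
                                             "single")) {
  linkage <- match.arg(linkage)
  means <- as.matrix(means)
  if (nrow(means) < 2L) stop("need >=2 genes to cluster")
  if (is.null(rownames(means))) stop("means must carry gene ids as rownames")
  means <- means[order(rownames(means)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(means, method = "euclidean"),
                      method = linkage)
  structure(
    list(hclust = hc,
         leaf_order = hc$labels[hc$order],
         merge_heights = hc$height,
         newick = ape::write.tree(ape::as.phylo(hc))),
    class = "gene_dendrogram")
}

#' @export
print.gene_dendrogram <- function(x, ...) {
  cat(sprintf("gene_dendrogram: %d leaves, root height %.4g\n",
              length(x$leaf_order), max(x$merge_heights)))
  invisible(x)
}

#' Cut a gene dendrogram into k clusters
#'
#' @param dendro A `gene_dendrogram`.
#' @param k Number of clusters.
#' @return Named integer vector of cluster memberships.
#' @export
cut_gene_tree <- function(dendro, k) {
  stopifnot(inherits(dendro, "gene_dendrogram"))
  stats::cutree(dendro$hclust, k = k)
}

#' Render an expression heat map with the 0-16 log2 color scale
#'
#' Writes an image (dark blue at 0 to dark red at 16, values clipped to
#' [0, 16] for display only) and a companion TSV of
#' `(row_rank, gene_id, <condition values>)` so figure content is testable
#' without pixel comparison. Row order comes from the dendrogram when one
#' is supplied, otherwise from the input; columns keep their input order.
#'
#' @param means Gene x condition matrix of log2 means.
#' @param image_file Output image path (`.png` or `.pdf` by extension).
#' @param tsv_file Output TSV path.
#' @param dendro Optional `gene_dendrogram` fixing the row order.
#' @param scale_limits Display clipping limits, default `c(0, 16)`.
#' @return Invisible list with `image_file`, `tsv_file`, `row_order`.
#' @export
render_heatmap <- function(means, image_file, tsv_file, dendro = NULL,
                           scale_limits = c(0, 16)) {
  means <- as.matrix(means)
  if (nrow(means) == 0L) stop("empty matrix")
  row_order <- rownames(means)
  cluster_rows <- FALSE
  if (!is.null(dendro)) {
    stopifnot(inherits(dendro, "gene_dendrogram"))
    row_order <- dendro$leaf_order
    means_plot <- means[row_order, , drop = FALSE]
  } else {
    means_plot <- means
  }
  clipped <- pmin(pmax(means_plot, scale_limits[1]), scale_limits[2])
  breaks <- seq(scale_limits[1], scale_limits[2], length.out = 101)
  cols <- grDevices::colorRampPalette(
    c("darkblue", "blue", "white", "red", "darkred"))(100)
  pheatmap::pheatmap(clipped, cluster_rows = FALSE, cluster_cols = FALSE,
                     color = cols, breaks = breaks,
                     filename = image_file, silent = TRUE,
                     fontsize_row = if (nrow(clipped) > 40) 2 else 8)
  out <- data.frame(row_rank = seq_len(nrow(means_plot)),
                    gene_id = rownames(means_plot),
                    means_plot, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, tsv_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(image_file = image_file, tsv_file = tsv_file,
                 row_order = row_order))
}
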