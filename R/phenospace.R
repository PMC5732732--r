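#' PCA of samples over a gene subset
#'
#' Observations are the sample columns; variables are the genes, each
#' centered and scaled to unit variance before the decomposition (covariance
#' PCA after explicit scaling). Zero-variance genes are dropped with a
#' warning. The sign of every component is fixed so that its largest-magnitude
#' loading is positive, making score tables reproducible across runs.
#'
#' @param m expression matrix.
#' @param genes optional `gene_list` (or character vector) restricting the
#'   variables; default: all genes.
#' @return object of class `pca_result`: `scores` (samples x components),
#'   `loadings` (genes x components), `var_explained` (percentages summing
#'   to 100).
#' @export
pca_samples <- function(m, genes = NULL) {
  validate_expression_matrix(m)
  if (!is.null(genes)) {
    idx <- match(as_symbols(genes), toupper(rownames(m)))
    idx <- idx[!is.na(idx)]
    m <- m[idx, , drop = FALSE]
  }
  if (ncol(m) < 2L) stop("PCA needs at least two samples")
  sdv <- apply(m, 1, stats::sd)
  if (any(sdv == 0)) {
    warning(sum(sdv == 0), " zero-variance gene(s) dropped before PCA")
    m <- m[sdv > 0, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("PCA needs at least two genes with non-zero variance")
  p <- stats::prcomp(t(m), center = TRUE, scale. = TRUE)
  for (k in seq_len(ncol(p$rotation))) {
    j <- which.max(abs(p$rotation[, k]))
    if (p$rotation[j, k] < 0) {
      p$rotation[, k] <- -p$rotation[, k]
      p$x[, k] <- -p$x[, k]
    }
  }
  var_explained <- 100 * p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = p$x, loadings = p$rotation,
                 var_explained = var_explained),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result: ", nrow(x$scores), " samples, ",
      ncol(x$scores), " components; PC1 ",
      sprintf("%.1f%%", x$var_explained[1]), ", PC2 ",
      if (length(x$var_explained) > 1)
        sprintf("%.1f%%", x$var_explained[2]) else "-", "\n", sep = "")
  invisible(x)
}

#' Hierarchical clustering of samples
#'
#' Complete-linkage agglomeration on Euclidean distances between sample
#' columns over the requested gene subset. Identical samples (zero distance)
#' merge first; merge heights are non-decreasing.
#'
#' @inheritParams pca_samples
#' @return an [stats::hclust] object (merge matrix plus heights).
#' @export
hcluster_samples <- function(m, genes = NULL) {
  validate_expression_matrix(m)
  if (!is.null(genes)) {
    idx <- match(as_symbols(genes), toupper(rownames(m)))
    idx <- idx[!is.na(idx)]
    m <- m[idx, , drop = FALSE]
  }
  if (ncol(m) < 2L) stop("clustering needs at least two samples")
  stats::hclust(stats::dist(t(m)), method = "complete")
}

#' First bipartition of a sample dendrogram
#'
#' @param hc an `hclust` object.
#' @return named integer vector of cluster labels (1/2) from cutting the tree
#'   into two groups.
#' @export
first_bipartition <- function(hc) {
  stats::cutree(hc, k = 2)
}

#' Render a dendrogram as a newick string
#'
#' @param hc an `hclust` object.
#' @return single newick string (with branch lengths from merge heights).
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Write PCA scores, loadings and variance-explained TSVs
#'
#' @param p a `pca_result`.
#' @param prefix path prefix; writes `<prefix>_scores.tsv`,
#'   `<prefix>_loadings.tsv`, `<prefix>_variance.tsv`.
#' @return character vector of the written paths, invisibly.
#' @export
write_pca <- function(p, prefix) {
  paths <- paste0(prefix, c("_scores.tsv", "_loadings.tsv", "_variance.tsv"))
  utils::write.table(data.frame(sample = rownames(p$scores), p$scores,
                                check.names = FALSE),
                     paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = rownames(p$loadings), p$loadings,
                                check.names = FALSE),
                     paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(component = seq_along(p$var_explained),
                                var_explained = p$var_explained),
                     paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
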