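#' Phenotype design: cell lines grouped by EMT class
#'
#' @param sheet sample sheet with a `phenotype` column.
#' @return object of class `phenotype_design`: list with character vectors
#'   `epithelial`, `hybrid`, `mesenchymal` of cell-line names.
#' @export
phenotype_design <- function(sheet) {
  validate_sample_sheet(sheet)
  groups <- lapply(c(epithelial = "epithelial", hybrid = "hybrid",
                     mesenchymal = "mesenchymal"),
                   function(ph) unique(sheet$cell_line[sheet$phenotype == ph]))
  empty <- names(groups)[vapply(groups, length, integer(1)) == 0L]
  if (length(empty) > 0L)
    stop("phenotype class(es) without any cell line: ",
         paste(empty, collapse = ", "))
  structure(groups, class = "phenotype_design")
}

match_candidates <- function(candidates, m, method) {
  idx <- match(candidates$symbols, toupper(rownames(m)))
  absent <- candidates$symbols[is.na(idx)]
  if (length(absent) > 0L)
    warning(method, ": ", length(absent),
            " candidate gene(s) absent from the matrix, excluded: ",
            paste(utils::head(absent, 5), collapse = ", "),
            if (length(absent) > 5) ", ..." else "")
  idx[!is.na(idx)]
}

selection_result <- function(method, genes, diagnostics, params) {
  structure(list(method = method, genes = genes, diagnostics = diagnostics,
                 params = params),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result [", x$method, "]: ", length(x$genes$symbols),
      " of ", nrow(x$diagnostics), " candidate genes selected\n", sep = "")
  invisible(x)
}

#' Cut-off (CO) selector: epithelial/mesenchymal contrast with flat epithelium
#'
#' Selects candidate genes whose mean log2 expression differs between the
#' epithelial and mesenchymal cell lines by at least `log2(between_fc)` while
#' varying among the epithelial cell lines by less than `log2(within_fc)`
#' (maximum pairwise difference).
#'
#' @param m expression matrix, one column per cell line (replicate-averaged).
#' @param design a [phenotype_design()].
#' @param candidates `gene_list` of candidate genes; candidates absent from
#'   the matrix are dropped with a warning.
#' @param between_fc linear fold-change threshold between the epithelial and
#'   mesenchymal means (default 2).
#' @param within_fc linear fold-change ceiling within the epithelial lines
#'   (default 1.5). Must satisfy `between_fc > within_fc >= 1`.
#' @return a `selection_result` (method `"CO"`); diagnostics report both
#'   log2 quantities per candidate.
#' @export
select_co <- function(m, design, candidates, between_fc = 2, within_fc = 1.5) {
  validate_expression_matrix(m)
  if (!(between_fc > within_fc && within_fc >= 1))
    stop("need between_fc > within_fc >= 1")
  if (length(design$epithelial) < 2L)
    stop("CO needs at least two epithelial cell lines")
  idx <- match_candidates(candidates, m, "CO")
  e <- m[idx, design$epithelial, drop = FALSE]
  mes <- m[idx, design$mesenchymal, drop = FALSE]
  between <- abs(rowMeans(e) - rowMeans(mes))
  within <- apply(e, 1, function(x) max(x) - min(x))
  sel <- between >= log2(between_fc) & within < log2(within_fc)
  genes <- toupper(rownames(m)[idx])
  diag <- data.frame(gene = genes, between_log2fc = unname(between),
                     within_log2fc = unname(within), selected = unname(sel))
  selection_result("CO", gene_list("CO", genes[sel], source = "cut-off selector"),
                   diag, list(between_fc = between_fc, within_fc = within_fc))
}

linear_svm_weights <- function(x, y, cost) {
  fit <- e1071::svm(x = x, y = factor(y), kernel = "linear", cost = cost,
                    scale = FALSE)
  drop(crossprod(fit$coefs, fit$SV))
}

#' SVM selector: hyperplane coefficients of three pairwise phenotype problems
#'
#' Standardizes each candidate gene across all replicate arrays (zero mean,
#' unit variance; constant genes become all-zero features with weight exactly
#' 0), fits a soft-margin linear support vector machine for each pairwise
#' phenotype problem (epithelial vs hybrid, hybrid vs mesenchymal, epithelial
#' vs mesenchymal) with replicate arrays as observations, and selects genes
#' whose hyperplane weight exceeds `coef_threshold` in absolute value in all
#' three problems.
#'
#' @param m expression matrix with per-array columns (not replicate-averaged).
#' @param sheet sample sheet covering every column.
#' @param candidates `gene_list` of candidate genes.
#' @param coef_threshold absolute-coefficient threshold (default 0.01).
#' @param cost soft-margin cost parameter (default 1).
#' @return a `selection_result` (method `"SVM"`); diagnostics hold the three
#'   weights per candidate.
#' @export
select_svm <- function(m, sheet, candidates, coef_threshold = 0.01, cost = 1) {
  validate_expression_matrix(m)
  validate_sample_sheet(sheet, m)
  idx <- match_candidates(candidates, m, "SVM")
  ph <- sheet$phenotype[match(colnames(m), sheet$sample_id)]
  counts <- table(factor(ph, levels = c("epithelial", "hybrid", "mesenchymal")))
  if (any(counts < 2L))
    stop("each phenotype class needs >= 2 samples; got ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  x <- t(m[idx, , drop = FALSE])
  colnames(x) <- toupper(rownames(m)[idx])
  if (!all(is.finite(x))) stop("non-finite feature values")
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  xs <- sweep(x, 2, mu, "-")
  xs <- sweep(xs, 2, ifelse(sdv > 0, sdv, 1), "/")
  xs[, sdv == 0] <- 0
  problems <- list(E_vs_H = c("epithelial", "hybrid"),
                   H_vs_M = c("hybrid", "mesenchymal"),
                   E_vs_M = c("epithelial", "mesenchymal"))
  w <- vapply(problems, function(pr) {
    take <- ph %in% pr
    linear_svm_weights(xs[take, , drop = FALSE], ph[take], cost)
  }, numeric(ncol(xs)))
  sel <- rowSums(abs(w) > coef_threshold) == ncol(w)
  genes <- colnames(xs)
  diag <- data.frame(gene = genes,
                     w_epithelial_vs_hybrid = unname(w[, "E_vs_H"]),
                     w_hybrid_vs_mesenchymal = unname(w[, "H_vs_M"]),
                     w_epithelial_vs_mesenchymal = unname(w[, "E_vs_M"]),
                     selected = unname(sel))
  selection_result("SVM", gene_list("SVM", genes[sel], source = "linear SVM selector"),
                   diag, list(coef_threshold = coef_threshold, cost = cost))
}

#' Profile-clustering (PROF) selector: dendrogram cut and trend screening
#'
#' Row-standardizes the candidate genes across cell lines, clusters them
#' hierarchically (complete linkage, Euclidean distance), cuts the dendrogram
#' into `n_clusters` groups, and retains each cluster whose centroid shows
#' modulation between the epithelial and mesenchymal lines
#' (`|centroid(E) - centroid(M)| >= delta`) and/or places the hybrid lines
#' apart from both (`|centroid(H) - centroid(E)| >= delta` and
#' `|centroid(H) - centroid(M)| >= delta`). Selected genes are the union of
#' the retained clusters.
#'
#' @param m expression matrix, one column per cell line.
#' @param design a [phenotype_design()].
#' @param candidates `gene_list` of candidate genes.
#' @param n_clusters number of clusters at the dendrogram cut (default 38).
#' @param delta centroid-difference threshold in standardized units
#'   (default 1).
#' @return a `selection_result` (method `"PROF"`); diagnostics report the
#'   cluster id and its centroid contrasts per candidate.
#' @export
select_prof <- function(m, design, candidates, n_clusters = 38, delta = 1) {
  validate_expression_matrix(m)
  idx <- match_candidates(candidates, m, "PROF")
  if (n_clusters < 1L || n_clusters > length(idx))
    stop("n_clusters must lie in [1, number of matched candidates (",
         length(idx), ")]")
  z <- m[idx, , drop = FALSE]
  rownames(z) <- toupper(rownames(m)[idx])
  mu <- rowMeans(z)
  sdv <- apply(z, 1, stats::sd)
  z <- sweep(z, 1, mu, "-")
  z <- sweep(z, 1, ifelse(sdv > 0, sdv, 1), "/")
  z[sdv == 0, ] <- 0
  hc <- stats::hclust(stats::dist(z), method = "complete")
  cl <- stats::cutree(hc, k = n_clusters)
  centro <- function(ids, lines) mean(colMeans(z[ids, lines, drop = FALSE]))
  info <- lapply(sort(unique(cl)), function(k) {
    ids <- names(cl)[cl == k]
    cE <- centro(ids, design$epithelial)
    cH <- centro(ids, design$hybrid)
    cM <- centro(ids, design$mesenchymal)
    keep <- abs(cE - cM) >= delta ||
      (abs(cH - cE) >= delta && abs(cH - cM) >= delta)
    list(k = k, ids = ids, d_em = cE - cM, d_he = cH - cE, d_hm = cH - cM,
         retained = keep)
  })
  per_gene <- do.call(rbind, lapply(info, function(ci) {
    data.frame(gene = ci$ids, cluster = ci$k,
               centroid_e_minus_m = ci$d_em,
               centroid_h_minus_e = ci$d_he,
               centroid_h_minus_m = ci$d_hm,
               selected = ci$retained)
  }))
  per_gene <- per_gene[match(rownames(z), per_gene$gene), ]
  rownames(per_gene) <- NULL
  sel_genes <- per_gene$gene[per_gene$selected]
  selection_result("PROF",
                   gene_list("PROF", sel_genes, source = "profile-cluster selector"),
                   per_gene, list(n_clusters = n_clusters, delta = delta))
}

#' Intersect selector outputs into a consensus signature
#'
#' @param results list (length >= 2) of `selection_result` objects.
#' @param name name for the intersection gene list (default "INT").
#' @return a `selection_result` (method `"INT"`) whose genes are the set
#'   intersection, ordered as in the first input; diagnostics record per-gene
#'   membership in each contributing method.
#' @export
intersect_selections <- function(results, name = "INT") {
  if (length(results) < 2L) stop("need at least two selection results")
  stopifnot(all(vapply(results, inherits, logical(1), "selection_result")))
  sets <- lapply(results, function(r) r$genes$symbols)
  common <- Reduce(intersect, sets)
  methods <- vapply(results, `[[`, character(1), "method")
  universe <- unique(unlist(sets))
  diag <- data.frame(gene = universe)
  for (i in seq_along(results))
    diag[[methods[i]]] <- universe %in% sets[[i]]
  diag$selected <- universe %in% common
  selection_result("INT",
                   gene_list(name, common,
                             source = paste(methods, collapse = " & ")),
                   diag, list(methods = methods))
}

#' Write a selection result (diagnostics TSV)
#' @param res a `selection_result`.
#' @param path output TSV.
#' @export
write_selection <- function(res, path) {
  utils::write.table(res$diagnostics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
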