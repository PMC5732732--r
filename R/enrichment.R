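#' Over-representation analysis against a term collection
#'
#' For every term, counts the overlap `k` between the query and the term
#' (both restricted to the background of `N` genes), computes the fold
#' enrichment `(k/n) / (K/N)` and an upper-tail hypergeometric p-value
#' `P(X >= k)`. The EASE variant (the default, mirroring DAVID's conservative
#' statistic) replaces `k` with `max(k - 1, 0)` in the tail probability.
#' Raw p-values are thresholded (`relevant = p < alpha`); a
#' Benjamini-Hochberg column is emitted for information only.
#'
#' @param query `gene_list` (or character vector) of genes to test; genes
#'   outside the background are dropped with a warning.
#' @param background `gene_list` (or character vector) defining the gene
#'   universe, typically all measured genes.
#' @param terms named list of `gene_list` objects (e.g. from [read_gmt()]).
#' @param mode `"ease"` (default) or `"hypergeometric"`.
#' @param alpha relevance threshold on the raw p-value (default 0.05).
#' @return data frame: `term_id`, `term_name`, `count`, `fold_enrichment`,
#'   `p_value`, `p_adjust`, `relevant`.
#' @export
ora <- function(query, background, terms, mode = c("ease", "hypergeometric"),
                alpha = 0.05) {
  mode <- match.arg(mode)
  bg <- unique(as_symbols(background))
  if (length(bg) == 0L) stop("empty background")
  if (length(terms) == 0L) stop("empty term collection")
  q <- unique(as_symbols(query))
  outside <- setdiff(q, bg)
  if (length(outside) > 0L) {
    warning(length(outside), " query gene(s) outside the background dropped")
    q <- intersect(q, bg)
  }
  N <- length(bg)
  n <- length(q)
  rows <- lapply(terms, function(tm) {
    t_bg <- intersect(tm$symbols, bg)
    K <- length(t_bg)
    k <- length(intersect(q, t_bg))
    fe <- if (k == 0L || K == 0L || n == 0L) 0 else (k / n) / (K / N)
    k_eff <- if (mode == "ease") max(k - 1L, 0L) else k
    p <- stats::phyper(k_eff - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tm$name,
               term_name = if (nzchar(tm$source)) tm$source else tm$name,
               count = k, fold_enrichment = fe, p_value = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  out$relevant <- out$p_value < alpha
  out
}

#' Relevance rule comparing a selection's enrichment with a reference
#'
#' Flags a term relevant when its raw p-value passes `alpha` AND its fold
#' enrichment in the selected list exceeds the fold enrichment of the same
#' term in the reference list (the pooled candidate list in the original
#' analysis). Terms absent from the reference count as reference fold
#' enrichment 0.
#'
#' @param selected enrichment table (from [ora()]) of the selected gene list.
#' @param reference enrichment table of the reference gene list over the same
#'   term collection.
#' @param alpha p-value threshold (default 0.05).
#' @return `selected` with an added `ref_fold_enrichment` column and the
#'   `relevant` flag re-derived under the comparison rule.
#' @export
compare_enrichment <- function(selected, reference, alpha = 0.05) {
  i <- match(selected$term_id, reference$term_id)
  ref_fe <- ifelse(is.na(i), 0, reference$fold_enrichment[i])
  selected$ref_fold_enrichment <- ref_fe
  selected$relevant <- selected$p_value < alpha &
    selected$fold_enrichment > ref_fe
  selected
}

#' Write an enrichment table as TSV
#'
#' Columns mirror the conventional report layout (term id, term, p-value,
#' count, fold enrichment) plus the relevance flag.
#'
#' @param tab enrichment table.
#' @param path output TSV.
#' @export
write_enrichment <- function(tab, path) {
  cols <- c("term_id", "term_name", "p_value", "count", "fold_enrichment",
            intersect("ref_fold_enrichment", colnames(tab)), "relevant")
  utils::write.table(tab[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
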