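default_params <- function() {
  list(quantile_normalize = TRUE,
       cutoff = 1, min_recurrence = 5, rank_mean_scope = "qualifying",
       between_fc = 2, within_fc = 1.5,
       coef_threshold = 0.01, cost = 1,
       n_clusters = 38, delta = 1,
       alpha = 0.05, ora_mode = "ease")
}

#' Run the full signature-selection pipeline
#'
#' Executes preprocessing (optional quantile normalization, replicate
#' averaging), recurrence-based differential expression, candidate-list
#' pooling and restriction, the three supervised selectors and their
#' intersection, PCA of every selection plus sample clustering, and (when a
#' term collection is supplied) over-representation analysis of the consensus
#' signature with the fold-enrichment comparison against the pooled candidate
#' list. Every stage output is written under `out_dir` and listed, with md5
#' checksums and the parameters used, in `manifest.json`; identical inputs
#' and parameters give identical checksums.
#'
#' @param m expression matrix (per-array columns, log2).
#' @param sheet sample sheet covering the columns of `m`.
#' @param lists named list of candidate `gene_list` objects (pooled into the
#'   combined candidate list).
#' @param terms optional named list of term `gene_list` objects (e.g. from
#'   [read_gmt()]) for enrichment.
#' @param out_dir output directory, created if needed.
#' @param params named list overriding entries of the default parameter set
#'   (`cutoff`, `min_recurrence`, `between_fc`, `within_fc`,
#'   `coef_threshold`, `cost`, `n_clusters`, `delta`, `alpha`, `ora_mode`,
#'   `quantile_normalize`, `rank_mean_scope`).
#' @return (invisibly) the manifest: list with `files` (named md5 vector),
#'   `params`, and `results` (key counts and the selection objects).
#' @export
run_pipeline <- function(m, sheet, lists, terms = NULL, out_dir,
                         params = list()) {
  p <- utils::modifyList(default_params(), params)
  validate_expression_matrix(m)
  validate_sample_sheet(sheet, m)
  if (p$min_recurrence > sum(unique(sheet[, c("cell_line", "status")])$status ==
                             "resistant"))
    stop("min_recurrence exceeds the number of resistant-vs-parental comparisons")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(out_dir, f)

  norm <- if (isTRUE(p$quantile_normalize)) quantile_normalize(m) else m
  write_expression(norm, out("normalized.tsv"))
  lines <- average_replicates(norm, sheet)
  write_expression(lines, out("cell_lines.tsv"))

  lfc <- pairwise_logfc(lines, sheet)
  diff <- differential_table(lfc, cutoff = p$cutoff,
                             min_recurrence = p$min_recurrence,
                             rank_mean_scope = p$rank_mean_scope)
  write_differential_table(diff, out("differential.tsv"))

  combo <- pool_gene_lists(lists, name = "COMBO")
  combo_measured <- restrict_to_measured(combo, lines)
  write_gene_list(combo_measured, out("combo_measured.txt"))
  design <- phenotype_design(sheet)

  co <- select_co(lines, design, combo_measured,
                  between_fc = p$between_fc, within_fc = p$within_fc)
  svm <- select_svm(norm, sheet, combo_measured,
                    coef_threshold = p$coef_threshold, cost = p$cost)
  prof <- select_prof(lines, design, combo_measured,
                      n_clusters = p$n_clusters, delta = p$delta)
  int <- intersect_selections(list(co, svm, prof))
  for (r in list(co, svm, prof, int))
    write_selection(r, out(sprintf("selection_%s.tsv", tolower(r$method))))
  sel_summary <- lapply(list(co, svm, prof, int), function(r)
    list(method = r$method, n_selected = length(r$genes$symbols),
         parameters = r$params))
  jsonlite::write_json(sel_summary, out("selection_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  for (r in list(co, svm, prof, int)) {
    if (length(r$genes$symbols) >= 2) {
      pca <- pca_samples(norm, r$genes)
      write_pca(pca, out(sprintf("pca_%s", tolower(r$method))))
    }
  }
  hc <- hcluster_samples(norm, combo_measured)
  writeLines(dendrogram_newick(hc), out("sample_dendrogram.nwk"))
  merges <- data.frame(step = seq_len(nrow(hc$merge)),
                       left = hc$merge[, 1], right = hc$merge[, 2],
                       height = hc$height)
  utils::write.table(merges, out("sample_dendrogram_merges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  enrich <- NULL
  if (!is.null(terms)) {
    background <- gene_list("background", rownames(lines))
    ref <- ora(combo_measured, background, terms, mode = p$ora_mode,
               alpha = p$alpha)
    enrich <- lapply(list(co, svm, prof, int), function(r) {
      tab <- ora(r$genes, background, terms, mode = p$ora_mode,
                 alpha = p$alpha)
      tab <- compare_enrichment(tab, ref, alpha = p$alpha)
      write_enrichment(tab, out(sprintf("enrichment_%s.tsv",
                                        tolower(r$method))))
      tab
    })
    names(enrich) <- c("CO", "SVM", "PROF", "INT")
    write_enrichment(ref, out("enrichment_combo_reference.tsv"))
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, out("manifest.json"))
  checksums <- tools::md5sum(sort(files))
  names(checksums) <- sub(paste0("^", out_dir, "/?"), "", names(checksums))
  manifest <- list(files = as.list(checksums), params = p,
                   inputs = list(matrix_md5 = unname(digest_matrix(m)),
                                 n_genes = nrow(m), n_samples = ncol(m)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(files = checksums, params = p,
                 results = list(diff = diff, co = co, svm = svm, prof = prof,
                                int = int, pca = NULL, enrichment = enrich)))
}

digest_matrix <- function(m) {
  tf <- tempfile()
  on.exit(unlink(tf))
  write_expression(m, tf)
  unname(tools::md5sum(tf))
}

#' Recompute the headline counts of the original study design
#'
#' Given a gene-level log2 matrix, its sample sheet and the five curated
#' candidate lists, recomputes the quantities reported for the deposited
#' cohort: thousands of per-line deregulated genes, the 5-of-6 recurrence
#' counts, the pooled and measured candidate-list sizes, the maximum pairwise
#' list overlap, and the four selection sizes. Intended for reproduction runs
#' against the deposited expression data and published supplementary lists;
#' also runs on the synthetic cohort.
#'
#' @param m gene-level expression matrix, per-array columns, log2 scale
#'   (already normalized).
#' @param sheet sample sheet.
#' @param lists named list of candidate `gene_list` objects.
#' @param params parameter overrides as in [run_pipeline()].
#' @return list of computed counts: `per_line_up`, `per_line_down`,
#'   `n_recurrent_up`, `n_recurrent_down`, `pooled_size`, `measured_size`,
#'   `max_pairwise_overlap`, `max_overlap_pair`, `n_co`, `n_svm`, `n_prof`,
#'   `n_int`, and the selection gene lists.
#' @export
reproduce_published_counts <- function(m, sheet, lists, params = list()) {
  p <- utils::modifyList(default_params(), params)
  norm <- if (isTRUE(p$quantile_normalize)) quantile_normalize(m) else m
  lines <- average_replicates(norm, sheet)
  lfc <- pairwise_logfc(lines, sheet)
  rec <- recurrent_genes(lfc, cutoff = p$cutoff,
                         min_recurrence = p$min_recurrence)
  combo <- pool_gene_lists(lists, name = "COMBO")
  combo_measured <- restrict_to_measured(combo, lines)
  ov <- pairwise_overlaps(lists)
  ov_off <- ov
  diag(ov_off) <- -1L
  imax <- which(ov_off == max(ov_off), arr.ind = TRUE)[1, ]
  design <- phenotype_design(sheet)
  n_cand <- length(combo_measured$symbols)
  co <- select_co(lines, design, combo_measured,
                  between_fc = p$between_fc, within_fc = p$within_fc)
  svm <- select_svm(norm, sheet, combo_measured,
                    coef_threshold = p$coef_threshold, cost = p$cost)
  prof <- select_prof(lines, design, combo_measured,
                      n_clusters = min(p$n_clusters, n_cand), delta = p$delta)
  int <- intersect_selections(list(co, svm, prof))
  list(per_line_up = colSums(lfc >= p$cutoff),
       per_line_down = colSums(lfc <= -p$cutoff),
       n_recurrent_up = length(rec$up$symbols),
       n_recurrent_down = length(rec$down$symbols),
       pooled_size = length(combo$symbols),
       measured_size = n_cand,
       max_pairwise_overlap = max(ov_off),
       max_overlap_pair = rownames(ov)[c(imax[1], imax[2])],
       n_co = length(co$genes$symbols),
       n_svm = length(svm$genes$symbols),
       n_prof = length(prof$genes$symbols),
       n_int = length(int$genes$symbols),
       selections = list(CO = co$genes, SVM = svm$genes, PROF = prof$genes,
                         INT = int$genes))
}
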