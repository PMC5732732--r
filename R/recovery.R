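jaccard <- function(a, b) {
  u <- union(a, b)
  if (length(u) == 0L) return(NA_real_)
  length(intersect(a, b)) / length(u)
}

precision <- function(selected, truth) {
  if (length(selected) == 0L) return(NA_real_)
  length(intersect(selected, truth)) / length(selected)
}

#' Parameter-recovery experiment on the synthetic cohort
#'
#' For each seed: generates a cohort, derives the candidate list by pooling
#' the synthetic curated-style lists and restricting to measured genes, runs
#' the three selectors and their intersection, and scores each selection
#' against the planted phenotype markers (Jaccard and precision). Also scores
#' the recurrence rule against the planted resistance genes (phenotype
#' markers, a known planted confound that shifts in every resistant line, are
#' excluded from that comparison), and records whether PC1 over the planted
#' markers orders the phenotypes epithelial < hybrid < mesenchymal (up to a
#' global sign).
#'
#' @param n_seeds number of independent cohorts (default 20).
#' @param base_seed seeds used are `base_seed + 0:(n_seeds-1)`.
#' @param config_args named list of overrides passed to [sim_config()]
#'   (besides `seed`).
#' @param list_args named list of overrides passed to
#'   [generate_gene_lists()] (besides `truth` and `seed`).
#' @return data frame with one row per seed: Jaccard and precision per
#'   selector, recurrence Jaccards, and the PC1 ordering flag.
#' @export
recovery_experiment <- function(n_seeds = 20, base_seed = 1,
                                config_args = list(), list_args = list()) {
  rows <- lapply(seq_len(n_seeds) - 1L, function(off) {
    seed <- base_seed + off
    cfg <- do.call(sim_config, c(list(seed = seed), config_args))
    sim <- simulate_cohort(cfg)
    lists <- do.call(generate_gene_lists,
                     c(list(truth = sim$truth, seed = seed), list_args))
    lines <- average_replicates(sim$matrix, sim$sheet)
    design <- phenotype_design(sim$sheet)
    candidates <- restrict_to_measured(pool_gene_lists(lists), lines)
    truth_markers <- toupper(c(sim$truth$marker_epithelial,
                               sim$truth$marker_mesenchymal))

    co <- select_co(lines, design, candidates)
    svm <- select_svm(sim$matrix, sim$sheet, candidates)
    prof <- select_prof(lines, design, candidates,
                        n_clusters = min(38, length(candidates$symbols)))
    int <- intersect_selections(list(co, svm, prof))

    lfc <- pairwise_logfc(lines, sim$sheet)
    rec <- recurrent_genes(lfc)
    planted <- planted_recurrent(sim)
    non_marker <- function(x) setdiff(toupper(x), toupper(planted$marker))

    pca <- pca_samples(sim$matrix, gene_list("truth", truth_markers))
    ph <- sim$sheet$phenotype[match(rownames(pca$scores),
                                    sim$sheet$sample_id)]
    pc1 <- pca$scores[, 1]
    mu <- tapply(pc1, ph, mean)
    span <- mu[["mesenchymal"]] - mu[["epithelial"]]
    ordered_ok <- (mu[["epithelial"]] < mu[["hybrid"]] &&
                   mu[["hybrid"]] < mu[["mesenchymal"]]) ||
                  (mu[["epithelial"]] > mu[["hybrid"]] &&
                   mu[["hybrid"]] > mu[["mesenchymal"]])

    data.frame(seed = seed,
               jaccard_co = jaccard(co$genes$symbols, truth_markers),
               jaccard_svm = jaccard(svm$genes$symbols, truth_markers),
               jaccard_prof = jaccard(prof$genes$symbols, truth_markers),
               jaccard_int = jaccard(int$genes$symbols, truth_markers),
               precision_co = precision(co$genes$symbols, truth_markers),
               precision_svm = precision(svm$genes$symbols, truth_markers),
               precision_prof = precision(prof$genes$symbols, truth_markers),
               precision_int = precision(int$genes$symbols, truth_markers),
               jaccard_recurrent_up = jaccard(non_marker(rec$up$symbols),
                                              non_marker(sim$truth$resistance_up)),
               jaccard_recurrent_down = jaccard(non_marker(rec$down$symbols),
                                                non_marker(sim$truth$resistance_down)),
               pc1_ordered = ordered_ok,
               pc1_span = unname(span))
  })
  do.call(rbind, rows)
}

#' Origin-batch clustering experiment
#'
#' Generates cohorts with a strong shared cell-line-of-origin offset and
#' checks whether the first bipartition of the sample dendrogram (complete
#' linkage, Euclidean, over the pooled candidate genes) separates the two
#' origins — the regime in which unsupervised clustering groups cell lines by
#' cellular origin rather than phenotype.
#'
#' @param n_seeds number of cohorts.
#' @param base_seed first seed.
#' @param origin_batch_sd sd of the origin offset; default twice the marker
#'   effect of the default configuration.
#' @return logical vector, one entry per seed: `TRUE` when the first split is
#'   exactly the origin partition.
#' @export
origin_split_experiment <- function(n_seeds = 5, base_seed = 1,
                                    origin_batch_sd = 2 * sim_config()$effect_marker) {
  design <- cohort_design()
  origin <- stats::setNames(design$origin, design$cell_line)
  vapply(seq_len(n_seeds) - 1L, function(off) {
    seed <- base_seed + off
    sim <- simulate_cohort(sim_config(seed = seed,
                                      origin_batch_sd = origin_batch_sd))
    lists <- generate_gene_lists(sim$truth, seed = seed)
    candidates <- restrict_to_measured(pool_gene_lists(lists), sim$matrix)
    hc <- hcluster_samples(sim$matrix, candidates)
    cl <- first_bipartition(hc)
    sample_origin <- origin[sim$sheet$cell_line[match(names(cl),
                                                      sim$sheet$sample_id)]]
    length(unique(paste(cl, sample_origin))) == 2L &&
      length(unique(cl)) == 2L
  }, logical(1))
}
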