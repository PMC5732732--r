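#' Fixed cohort design emulated by the simulator
#'
#' Eight cell lines: two epithelial parentals (HCC827, HCC4006), five hybrid
#' E/M resistant derivatives of HCC827 (RA1, RA2, RB1, RB1.1, RB2) and one
#' mesenchymal resistant derivative of HCC4006 (RC2.2).
#'
#' @return data frame with columns `cell_line`, `status`, `parent_line`,
#'   `phenotype`, `origin`.
#' @export
cohort_design <- function() {
  data.frame(
    cell_line = c("HCC827", "HCC4006", "RA1", "RA2", "RB1", "RB1.1", "RB2",
                  "RC2.2"),
    status = c("parental", "parental", rep("resistant", 6)),
    parent_line = c("HCC827", "HCC4006", rep("HCC827", 5), "HCC4006"),
    phenotype = c("epithelial", "epithelial", rep("hybrid", 5), "mesenchymal"),
    origin = c("HCC827", "HCC4006", rep("HCC827", 5), "HCC4006"),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults define the reference synthetic cohort: 5,000 genes on the log2
#' scale, 20 epithelial-high and 20 mesenchymal-high phenotype markers
#' separated by 3 log2 units between the epithelial and mesenchymal states
#' with hybrids at 35% of the axis, 30 + 30 recurrently up/down-regulated
#' resistance genes shifted by 2 log2 units in a random 5 of the 6 resistant
#' lines, a modest shared cell-line-of-origin offset (sd 0.2) on the
#' HCC4006-origin lines, array noise sd 0.3, and two replicate arrays per
#' line.
#'
#' @param n_genes total number of genes.
#' @param n_marker_epithelial,n_marker_mesenchymal planted phenotype marker
#'   counts.
#' @param n_resistance_up,n_resistance_down planted recurrent resistance gene
#'   counts.
#' @param effect_marker epithelial-to-mesenchymal marker separation, log2
#'   units.
#' @param hybrid_position fraction (in `[0, 1]`) of the marker effect
#'   expressed by the hybrid lines.
#' @param effect_resistance resistance shift, log2 units.
#' @param origin_batch_sd sd of the gene-wise origin offset shared by the
#'   HCC4006-origin lines, log2 units.
#' @param noise_sd sd of iid array noise, log2 units.
#' @param n_replicates replicate arrays per cell line.
#' @param seed integer RNG seed; one global stream drives every stochastic
#'   choice.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 5000,
                       n_marker_epithelial = 20,
                       n_marker_mesenchymal = 20,
                       n_resistance_up = 30,
                       n_resistance_down = 30,
                       effect_marker = 3,
                       hybrid_position = 0.35,
                       effect_resistance = 2,
                       origin_batch_sd = 0.2,
                       noise_sd = 0.3,
                       n_replicates = 2,
                       seed = 1L) {
  cfg <- list(n_genes = n_genes,
              n_marker_epithelial = n_marker_epithelial,
              n_marker_mesenchymal = n_marker_mesenchymal,
              n_resistance_up = n_resistance_up,
              n_resistance_down = n_resistance_down,
              effect_marker = effect_marker,
              hybrid_position = hybrid_position,
              effect_resistance = effect_resistance,
              origin_batch_sd = origin_batch_sd,
              noise_sd = noise_sd,
              n_replicates = as.integer(n_replicates),
              seed = as.integer(seed))
  counts <- c(n_marker_epithelial, n_marker_mesenchymal, n_resistance_up,
              n_resistance_down)
  if (any(counts < 0)) stop("planted gene counts must be >= 0")
  if (sum(counts) > n_genes)
    stop("planted gene counts exceed n_genes")
  if (hybrid_position < 0 || hybrid_position > 1)
    stop("hybrid_position must lie in [0, 1]")
  if (origin_batch_sd < 0 || noise_sd < 0) stop("sds must be >= 0")
  if (cfg$n_replicates < 1L) stop("n_replicates must be >= 1")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic resistance cohort with ground truth
#'
#' Baseline log2 expression per gene is drawn once from Normal(8, 1.5) and
#' shared across lines. Mesenchymal-high markers add `effect_marker` in
#' RC2.2, `hybrid_position * effect_marker` in the five hybrid lines and 0 in
#' the parentals; epithelial-high markers are mirrored. Resistance genes add
#' `+-effect_resistance` in a random 5 of the 6 resistant lines (recorded per
#' gene). Both HCC4006-origin lines share one gene-wise offset vector drawn
#' from Normal(0, `origin_batch_sd`). Each replicate array adds iid
#' Normal(0, `noise_sd`). The same seed reproduces the output exactly.
#'
#' @param config a [sim_config()].
#' @return list of class `emt_sim`: `matrix` (genes x arrays), `sheet`
#'   (sample sheet), `truth` (planted gene sets, affected lines, phenotype
#'   labels, gene universe), `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  design <- cohort_design()
  set.seed(config$seed)
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  n_planted <- config$n_marker_epithelial + config$n_marker_mesenchymal +
    config$n_resistance_up + config$n_resistance_down
  planted <- sample(genes, n_planted)
  splits <- rep(c("marker_epithelial", "marker_mesenchymal",
                  "resistance_up", "resistance_down"),
                c(config$n_marker_epithelial, config$n_marker_mesenchymal,
                  config$n_resistance_up, config$n_resistance_down))
  truth_sets <- split(planted, factor(splits, levels = unique(splits)))
  me <- truth_sets[["marker_epithelial"]]
  mm <- truth_sets[["marker_mesenchymal"]]
  ru <- truth_sets[["resistance_up"]]
  rd <- truth_sets[["resistance_down"]]

  base <- stats::rnorm(config$n_genes, mean = 8, sd = 1.5)
  effect <- matrix(0, config$n_genes, nrow(design),
                   dimnames = list(genes, design$cell_line))
  hybrid_lines <- design$cell_line[design$phenotype == "hybrid"]
  parental_lines <- design$cell_line[design$status == "parental"]
  resistant_lines <- design$cell_line[design$status == "resistant"]
  h <- config$hybrid_position
  em <- config$effect_marker
  # mesenchymal-high: 0 in parentals, h*em in hybrids, em in RC2.2
  effect[mm, hybrid_lines] <- h * em
  effect[mm, "RC2.2"] <- em
  # epithelial-high mirrored: em in parentals, (1-h)*em in hybrids, 0 in RC2.2
  effect[me, parental_lines] <- em
  effect[me, hybrid_lines] <- (1 - h) * em
  resistance_lines <- list()
  for (g in ru) {
    lines <- sort(sample(resistant_lines, 5))
    effect[g, lines] <- effect[g, lines] + config$effect_resistance
    resistance_lines[[g]] <- lines
  }
  for (g in rd) {
    lines <- sort(sample(resistant_lines, 5))
    effect[g, lines] <- effect[g, lines] - config$effect_resistance
    resistance_lines[[g]] <- lines
  }
  origin_offset <- stats::rnorm(config$n_genes, 0, config$origin_batch_sd)
  hcc4006_origin <- design$cell_line[design$origin == "HCC4006"]
  effect[, hcc4006_origin] <- effect[, hcc4006_origin] + origin_offset

  reps <- seq_len(config$n_replicates)
  sheet <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    data.frame(sample_id = paste(design$cell_line[i], reps, sep = "_r"),
               cell_line = design$cell_line[i],
               replicate = reps,
               status = design$status[i],
               parent_line = design$parent_line[i],
               phenotype = design$phenotype[i],
               stringsAsFactors = FALSE)
  }))
  line_values <- base + effect
  mat <- matrix(0, config$n_genes, nrow(sheet),
                dimnames = list(genes, sheet$sample_id))
  for (j in seq_len(nrow(sheet))) {
    mat[, j] <- line_values[, sheet$cell_line[j]] +
      stats::rnorm(config$n_genes, 0, config$noise_sd)
  }
  truth <- list(marker_epithelial = me,
                marker_mesenchymal = mm,
                resistance_up = ru,
                resistance_down = rd,
                resistance_lines = resistance_lines,
                phenotype = stats::setNames(design$phenotype, design$cell_line),
                gene_ids = genes)
  validate_sample_sheet(sheet, mat)
  structure(list(matrix = mat, sheet = sheet, truth = truth, config = config),
            class = "emt_sim")
}

#' @export
print.emt_sim <- function(x, ...) {
  cat("emt_sim: ", nrow(x$matrix), " genes x ", ncol(x$matrix), " arrays (",
      length(unique(x$sheet$cell_line)), " cell lines), seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Noise-free recurrence ground truth of a simulated cohort
#'
#' Recomputes, from the planted effects alone (noise and replicate scatter
#' set aside), which genes would qualify as recurrently up- or down-regulated
#' at the given cutoff and recurrence threshold. Phenotype markers deliberately
#' shift in every resistant line and are reported separately so recovery
#' comparisons can exclude them.
#'
#' @param sim an `emt_sim`.
#' @param cutoff log2 fold-change cutoff (default 1).
#' @param min_recurrence minimum qualifying comparisons (default 5).
#' @return list with character vectors `up`, `down` (all qualifying genes)
#'   and `marker` (the planted phenotype markers).
#' @export
planted_recurrent <- function(sim, cutoff = 1, min_recurrence = 5) {
  stopifnot(inherits(sim, "emt_sim"))
  cfg <- sim$config
  design <- cohort_design()
  res <- design[design$status == "resistant", ]
  shift <- matrix(0, cfg$n_genes, nrow(res),
                  dimnames = list(sim$truth$gene_ids, res$cell_line))
  h <- cfg$hybrid_position
  shift[sim$truth$marker_mesenchymal, ] <-
    rep(ifelse(res$phenotype == "mesenchymal", cfg$effect_marker,
               h * cfg$effect_marker),
        each = length(sim$truth$marker_mesenchymal))
  shift[sim$truth$marker_epithelial, ] <-
    rep(ifelse(res$phenotype == "mesenchymal", -cfg$effect_marker,
               -h * cfg$effect_marker),
        each = length(sim$truth$marker_epithelial))
  for (g in sim$truth$resistance_up)
    shift[g, sim$truth$resistance_lines[[g]]] <-
      shift[g, sim$truth$resistance_lines[[g]]] + cfg$effect_resistance
  for (g in sim$truth$resistance_down)
    shift[g, sim$truth$resistance_lines[[g]]] <-
      shift[g, sim$truth$resistance_lines[[g]]] - cfg$effect_resistance
  up <- rownames(shift)[rowSums(shift >= cutoff) >= min_recurrence]
  down <- rownames(shift)[rowSums(shift <= -cutoff) >= min_recurrence]
  list(up = up, down = down,
       marker = c(sim$truth$marker_epithelial, sim$truth$marker_mesenchymal))
}

#' Generate partially overlapping curated-style gene lists from truth
#'
#' Emulates independently curated EMT marker lists: each list samples a
#' `coverage` fraction of the planted phenotype markers and adds
#' `round(contamination * size)` genes drawn from genes belonging to no
#' planted set. Lists overlap partially, like published signatures with
#' little mutual overlap.
#'
#' @param truth `truth` element of an `emt_sim`.
#' @param n_lists number of lists (default 5).
#' @param coverage fraction (0, 1] of true markers sampled per list.
#' @param contamination non-marker genes added per list, as a fraction of the
#'   sampled marker count (>= 0).
#' @param seed RNG seed.
#' @return named list of [gene_list()] objects.
#' @export
generate_gene_lists <- function(truth, n_lists = 5, coverage = 0.6,
                                contamination = 0.15, seed = 1L) {
  if (coverage <= 0 || coverage > 1) stop("coverage must lie in (0, 1]")
  if (contamination < 0) stop("contamination must be >= 0")
  set.seed(as.integer(seed))
  markers <- c(truth$marker_epithelial, truth$marker_mesenchymal)
  pool <- setdiff(truth$gene_ids,
                  c(markers, truth$resistance_up, truth$resistance_down))
  lists <- lapply(seq_len(n_lists), function(i) {
    n_true <- max(1L, round(coverage * length(markers)))
    picked <- sample(markers, n_true)
    n_noise <- round(contamination * n_true)
    noise <- if (n_noise > 0) sample(pool, n_noise) else character()
    gene_list(sprintf("emt_list_%d", i), c(picked, noise),
              source = "synthetic curated-style marker list")
  })
  names(lists) <- vapply(lists, `[[`, character(1), "name")
  lists
}

#' Write a simulated cohort to disk
#'
#' Writes the expression TSV, sample sheet TSV and truth JSON.
#'
#' @param sim an `emt_sim`.
#' @param dir output directory (created if needed).
#' @return named character vector of paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "expression.tsv"),
             sheet = file.path(dir, "sample_sheet.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression(sim$matrix, paths["matrix"])
  write_sample_sheet(sim$sheet, paths["sheet"])
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(paths)
}
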