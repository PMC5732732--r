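small_cfg <- function(...) {
  sim_config(n_genes = 300, n_marker_epithelial = 8, n_marker_mesenchymal = 8,
             n_resistance_up = 10, n_resistance_down = 10, ...)
}

test_that("configuration invariants are enforced before generation", {
  expect_error(sim_config(n_genes = 10, n_marker_epithelial = 20),
               "exceed n_genes")
  expect_error(sim_config(hybrid_position = 1.5), "hybrid_position")
  expect_error(sim_config(noise_sd = -1), "sds must be")
  expect_error(sim_config(n_replicates = 0), "n_replicates")
  expect_error(sim_config(n_marker_epithelial = -1), "counts must be")
})

test_that("the same seed reproduces the cohort exactly", {
  a <- simulate_cohort(small_cfg(seed = 99))
  b <- simulate_cohort(small_cfg(seed = 99))
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_cohort(small_cfg(seed = 100))
  expect_false(identical(a$matrix, c2$matrix))
})

test_that("cohort dimensions and metadata follow the fixed design", {
  sim <- simulate_cohort(small_cfg(seed = 1, n_replicates = 3))
  expect_equal(dim(sim$matrix), c(300, 8 * 3))
  expect_setequal(colnames(sim$matrix), sim$sheet$sample_id)
  expect_equal(sort(unique(sim$sheet$cell_line)),
               sort(cohort_design()$cell_line))
  # truth sets are disjoint and labels match the 2/5/1 phenotype design
  sets <- sim$truth[c("marker_epithelial", "marker_mesenchymal",
                      "resistance_up", "resistance_down")]
  expect_equal(length(unique(unlist(sets))), sum(lengths(sets)))
  expect_equal(unname(table(sim$truth$phenotype)[c("epithelial", "hybrid",
                                                   "mesenchymal")]),
               c(2L, 5L, 1L), ignore_attr = TRUE)
  # every resistance gene is shifted in exactly 5 resistant lines
  expect_true(all(lengths(sim$truth$resistance_lines) == 5))
})

test_that("zero noise exposes the planted group structure exactly", {
  sim <- simulate_cohort(small_cfg(seed = 5, noise_sd = 0,
                                   origin_batch_sd = 0))
  m <- sim$matrix
  # replicates identical
  for (l in unique(sim$sheet$cell_line)) {
    ids <- sim$sheet$sample_id[sim$sheet$cell_line == l]
    expect_equal(m[, ids[1]], m[, ids[2]], ignore_attr = TRUE)
  }
  lines <- average_replicates(m, sim$sheet)
  h <- sim$config$hybrid_position
  em <- sim$config$effect_marker
  for (g in sim$truth$marker_mesenchymal) {
    expect_equal(unname(lines[g, "RC2.2"] - lines[g, "HCC827"]), em)
    expect_equal(unname(lines[g, "RA1"] - lines[g, "HCC827"]), h * em)
  }
  for (g in sim$truth$marker_epithelial) {
    expect_equal(unname(lines[g, "HCC827"] - lines[g, "RC2.2"]), em)
    expect_equal(unname(lines[g, "HCC827"] - lines[g, "RA1"]), h * em)
  }
  for (g in sim$truth$resistance_up) {
    affected <- sim$truth$resistance_lines[[g]]
    parent <- cohort_design()$parent_line[match(affected,
                                                cohort_design()$cell_line)]
    expect_equal(unname(lines[g, affected] - lines[g, parent]),
                 rep(sim$config$effect_resistance, 5))
  }
  # noise-free recurrence truth agrees with the pipeline on this cohort
  planted <- planted_recurrent(sim)
  rec <- recurrent_genes(pairwise_logfc(lines, sim$sheet))
  expect_setequal(rec$up$symbols, toupper(planted$up))
  expect_setequal(rec$down$symbols, toupper(planted$down))
})

test_that("synthetic gene lists respect coverage and contamination", {
  sim <- simulate_cohort(small_cfg(seed = 2))
  truth <- sim$truth
  markers <- c(truth$marker_epithelial, truth$marker_mesenchymal)
  # coverage 1, contamination 0, one list: exactly the truth set
  l1 <- generate_gene_lists(truth, n_lists = 1, coverage = 1,
                            contamination = 0, seed = 3)
  expect_setequal(l1[[1]]$symbols, toupper(markers))
  # contamination 0: every list within the truth set
  l0 <- generate_gene_lists(truth, n_lists = 4, coverage = 0.5,
                            contamination = 0, seed = 3)
  for (l in l0) expect_true(all(l$symbols %in% toupper(markers)))
  # overlap counts equal brute-force intersections of the emitted lists
  l5 <- generate_gene_lists(truth, n_lists = 5, coverage = 0.4, seed = 3)
  ov <- pairwise_overlaps(l5)
  for (i in 1:5) for (j in 1:5)
    expect_equal(ov[i, j],
                 length(intersect(l5[[i]]$symbols, l5[[j]]$symbols)))
  expect_error(generate_gene_lists(truth, coverage = 0), "coverage")
  expect_error(generate_gene_lists(truth, contamination = -1), "contamination")
})

test_that("cohorts round-trip through the on-disk representation", {
  sim <- simulate_cohort(small_cfg(seed = 8))
  dir <- withr::local_tempdir()
  paths <- write_cohort(sim, dir)
  expect_equal(read_expression(paths["matrix"]), sim$matrix)
  sheet <- read_sample_sheet(paths["sheet"])
  expect_equal(sheet$sample_id, sim$sheet$sample_id)
})
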