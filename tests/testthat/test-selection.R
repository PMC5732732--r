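# Cell-line-level fixture matrix over the eight-line design.
line_matrix <- function(values, genes) {
  d <- cohort_design()
  tiny_matrix(values, genes = genes, samples = d$cell_line)
}

toy_design <- function() phenotype_design(toy_sheet())

test_that("cut-off selector applies both fold-change rules", {
  # epithelial (5.0, 5.2), mesenchymal 7.5: within FC 2^0.2 < 1.5,
  # between FC 2^2.4 >= 2 -> selected; a constant gene never is.
  m <- line_matrix(rbind(c(5.0, 5.2, 6, 6, 6, 6, 6, 7.5),
                         rep(4, 8),
                         c(5.0, 6.0, 6, 6, 6, 6, 6, 7.5)),
                   genes = c("hit", "constant", "wobbly_epithelium"))
  res <- select_co(m, toy_design(), gene_list("cand", rownames(m)))
  expect_equal(res$genes$symbols, "HIT")
  d <- res$diagnostics
  expect_equal(d$between_log2fc[d$gene == "HIT"], 2.4)
  expect_equal(d$within_log2fc[d$gene == "HIT"], 0.2)
  expect_false(d$selected[d$gene == "WOBBLY_EPITHELIUM"]) # within FC 2 >= 1.5
  expect_error(select_co(m, toy_design(), gene_list("c", "HIT"),
                         between_fc = 1.2, within_fc = 1.5),
               "between_fc > within_fc")
  expect_warning(select_co(m, toy_design(),
                           gene_list("c", c("HIT", "ABSENT"))),
                 "absent from the matrix")
})

test_that("cut-off selection is monotone in its thresholds", {
  set.seed(17)
  m <- line_matrix(matrix(rnorm(30 * 8, 8, 1.5), 30, 8),
                   genes = sprintf("g%02d", 1:30))
  cand <- gene_list("cand", rownames(m))
  base <- length(select_co(m, toy_design(), cand, 2, 1.5)$genes$symbols)
  expect_lte(length(select_co(m, toy_design(), cand, 3, 1.5)$genes$symbols),
             base)
  expect_lte(length(select_co(m, toy_design(), cand, 2, 1.2)$genes$symbols),
             base)
})

test_that("SVM selector matches a primal-objective oracle on a toy problem", {
  sheet <- toy_sheet()
  ph <- sheet$phenotype
  set.seed(4)
  g1 <- ifelse(ph == "epithelial", -1, ifelse(ph == "hybrid", 0, 1))
  g2 <- rnorm(16, 0, 0.01)
  g3 <- rep(5, 16)
  m <- tiny_matrix(rbind(g1 + 8, g2 + 8, g3),
                   genes = c("signal", "noise", "constant"),
                   samples = sheet$sample_id)
  res <- select_svm(m, sheet, gene_list("cand", rownames(m)))
  expect_equal(res$genes$symbols, "SIGNAL")
  d <- res$diagnostics
  # constant features carry exactly zero weight in every problem
  expect_equal(unlist(d[d$gene == "CONSTANT", 2:4]), c(0, 0, 0),
               ignore_attr = TRUE)
  # weights agree with an independent numerical minimization of the primal
  xs <- scale(t(m[c("signal", "noise"), ]))
  problems <- list(c("epithelial", "hybrid"), c("hybrid", "mesenchymal"),
                   c("epithelial", "mesenchymal"))
  for (i in seq_along(problems)) {
    take <- ph %in% problems[[i]]
    y <- ifelse(ph[take] == problems[[i]][1], 1, -1)
    w_oracle <- oracle_svm_primal(xs[take, ], y)[1:2]
    w_pkg <- unlist(d[d$gene %in% c("SIGNAL", "NOISE"), 1 + i])
    expect_equal(abs(unname(w_pkg)), abs(unname(w_oracle)), tolerance = 0.02)
  }
})

test_that("SVM selection is invariant to sample order and feature scaling", {
  sheet <- toy_sheet()
  set.seed(31)
  m <- tiny_matrix(matrix(rnorm(16 * 6, 8), 6, 16),
                   genes = sprintf("g%d", 1:6), samples = sheet$sample_id)
  m["g1", ] <- m["g1", ] + ifelse(sheet$phenotype == "mesenchymal", 3,
                                  ifelse(sheet$phenotype == "hybrid", 1.5, 0))
  cand <- gene_list("cand", rownames(m))
  r0 <- select_svm(m, sheet, cand)
  perm <- sample(ncol(m))
  r1 <- select_svm(m[, perm], sheet, cand)
  expect_setequal(r0$genes$symbols, r1$genes$symbols)
  m2 <- m
  m2["g1", ] <- 5 * m2["g1", ] - 2  # affine rescale, absorbed by standardization
  r2 <- select_svm(m2, sheet, cand)
  expect_setequal(r0$genes$symbols, r2$genes$symbols)
  # a class with fewer than two samples is an error
  bad <- sheet
  keep <- bad$sample_id != "RC2.2_r2"
  expect_error(select_svm(m[, sheet$sample_id[keep]], bad[keep, ], cand),
               ">= 2 samples")
})

test_that("profile selector retains modulated clusters and rejects flat ones", {
  set.seed(6)
  e_high <- c(10, 10, 6, 6, 6, 6, 6, 2)
  m_high <- c(2, 2, 6, 6, 6, 6, 6, 10)
  vals <- rbind(e_high + rnorm(8, 0, 0.05), e_high + rnorm(8, 0, 0.05),
                e_high + rnorm(8, 0, 0.05),
                m_high + rnorm(8, 0, 0.05), m_high + rnorm(8, 0, 0.05),
                rep(5, 8), rep(7, 8))
  m <- line_matrix(vals, genes = c("e1", "e2", "e3", "m1", "m2", "f1", "f2"))
  res <- select_prof(m, toy_design(), gene_list("cand", rownames(m)),
                     n_clusters = 3, delta = 1)
  expect_setequal(res$genes$symbols, c("E1", "E2", "E3", "M1", "M2"))
  d <- res$diagnostics
  # hand-checked centroid contrast for the epithelial-high cluster: ~3.1 sd
  expect_equal(d$centroid_e_minus_m[d$gene == "E1"], 3.12, tolerance = 0.05)
  expect_false(any(d$selected[d$gene %in% c("F1", "F2")]))
  # singleton-cluster limit: per-gene trend test; flat genes never selected
  res1 <- select_prof(m, toy_design(), gene_list("cand", rownames(m)),
                      n_clusters = nrow(m), delta = 1)
  expect_false(any(c("F1", "F2") %in% res1$genes$symbols))
  expect_error(select_prof(m, toy_design(), gene_list("cand", rownames(m)),
                           n_clusters = 10), "n_clusters")
})

test_that("profile selection is invariant to candidate order", {
  set.seed(23)
  m <- line_matrix(matrix(rnorm(20 * 8, 8, 1.2), 20, 8),
                   genes = sprintf("g%02d", 1:20))
  cand <- gene_list("cand", rownames(m))
  r1 <- select_prof(m, toy_design(), cand, n_clusters = 8)
  r2 <- select_prof(m, toy_design(),
                    gene_list("cand", rev(rownames(m))), n_clusters = 8)
  expect_setequal(r1$genes$symbols, r2$genes$symbols)
})

test_that("intersection obeys the subset laws", {
  mk <- function(method, syms) {
    emtsig:::selection_result(method, gene_list(method, syms),
                              data.frame(gene = syms, selected = TRUE),
                              list())
  }
  a <- mk("CO", c("X", "Y", "Z"))
  b <- mk("SVM", c("Y", "Z", "W"))
  c3 <- mk("PROF", c("Z", "Q"))
  int <- intersect_selections(list(a, b, c3))
  expect_equal(int$genes$symbols, "Z")
  for (r in list(a, b, c3))
    expect_true(all(int$genes$symbols %in% r$genes$symbols))
  expect_lte(length(int$genes$symbols),
             min(lengths(list(a$genes$symbols, b$genes$symbols,
                              c3$genes$symbols))))
  # identical inputs reproduce the set; disjoint inputs empty it
  expect_equal(intersect_selections(list(a, a))$genes$symbols, a$genes$symbols)
  expect_length(intersect_selections(list(a, mk("P", "NOPE")))$genes$symbols, 0)
  expect_error(intersect_selections(list(a)), "at least two")
})
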