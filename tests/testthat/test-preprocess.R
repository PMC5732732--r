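test_that("expression TSV round-trips through write and read", {
  m <- tiny_matrix(matrix(c(1.5, 2.25, 3, 4.125, 5, 6.5), 3, 2),
                   genes = c("TP53", "CDH1", "VIM"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, path)
  expect_equal(read_expression(path), m)
})

test_that("TSV reader rejects malformed headers, duplicates and bad cells", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("notgene\ts1", "g1\t1.0"), path)
  expect_error(read_expression(path), "malformed header at line 1")
  writeLines(c("gene\ts1\ts1", "g1\t1.0\t2.0"), path)
  expect_error(read_expression(path), "duplicate sample columns")
  writeLines(c("gene\ts1\ts2", "g1\t1.0\toops"), path)
  expect_error(read_expression(path), "row 1.*column 's2'")
})

test_that("series-matrix reader extracts the inner table and skips metadata", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c('!Series_title\t"a study"',
               '!Sample_geo_accession\t"GSM1"\t"GSM2"',
               "!series_matrix_table_begin",
               "ID_REF\tGSM1\tGSM2",
               "p1\t5.5\t6.5",
               "p2\t7.0\t8.0",
               "!series_matrix_table_end",
               "!trailing_junk"), path)
  m <- read_expression(path, format = "geo_series_matrix")
  expect_equal(m, tiny_matrix(matrix(c(5.5, 7, 6.5, 8), 2, 2),
                              genes = c("p1", "p2"),
                              samples = c("GSM1", "GSM2")))
  writeLines("no markers here", path)
  expect_error(read_expression(path, format = "geo_series_matrix"),
               "series_matrix_table")
})

test_that("linear-scale input is log2-transformed on request", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1", "g1\t8", "g2\t1"), path)
  m <- read_expression(path, log2_input = FALSE)
  expect_equal(unname(m[, 1]), c(3, 0))
})

test_that("low-intensity filter applies the threshold rule row-wise", {
  m <- tiny_matrix(rbind(c(6, 7), c(4, 4), c(6, 4), c(9, 9)),
                   genes = c("keep", "low", "half", "ctrl"))
  # vacuous filter
  expect_equal(filter_low_intensity(m, min_log2 = 5, min_fraction = 0), m)
  # control row and all-low row removed at min_fraction = 1
  out <- filter_low_intensity(m, min_log2 = 5, min_fraction = 1,
                              control_ids = "ctrl")
  expect_equal(rownames(out), "keep")
  # -Inf threshold removes only controls
  out <- filter_low_intensity(m, min_log2 = -Inf, min_fraction = 1,
                              control_ids = "ctrl")
  expect_equal(rownames(out), c("keep", "low", "half"))
  expect_error(filter_low_intensity(m, min_log2 = 100, min_fraction = 1),
               "removed every row")
})

test_that("filter output shrinks monotonically with stricter thresholds", {
  set.seed(42)
  m <- tiny_matrix(matrix(rnorm(200, 7, 2), 50, 4))
  prev <- Inf
  for (thr in c(4, 6, 8)) {
    n <- nrow(filter_low_intensity(m, min_log2 = thr, min_fraction = 0.5))
    expect_lte(n, prev)
    prev <- n
  }
  n_frac <- vapply(c(0.25, 0.5, 1), function(f)
    nrow(filter_low_intensity(m, min_log2 = 6, min_fraction = f)), numeric(1))
  expect_true(all(diff(n_frac) <= 0))
})

test_that("quantile normalization matches the rank-mean oracle", {
  expect_equal(quantile_normalize(tiny_matrix(rbind(c(1, 3), c(5, 7)))),
               tiny_matrix(rbind(c(2, 2), c(6, 6))))
  set.seed(7)
  m <- tiny_matrix(matrix(rnorm(60, 8), 15, 4))
  expect_equal(quantile_normalize(m), oracle_quantile_normalize(m),
               tolerance = 1e-12)
})

test_that("quantile normalization fixed points and column invariants hold", {
  set.seed(1)
  col <- sort(rnorm(20, 8))
  m <- tiny_matrix(cbind(col, rev(col), sample(col)))
  out <- quantile_normalize(m)
  # identical distributions are a fixed point
  expect_equal(out, m, tolerance = 1e-12)
  # single column unchanged
  single <- tiny_matrix(matrix(rnorm(10), 10, 1))
  expect_equal(quantile_normalize(single), single)
  # post-op: all columns share the same sorted values and mean
  m2 <- tiny_matrix(matrix(rnorm(80, 8, 2), 20, 4))
  out2 <- quantile_normalize(m2)
  sorted <- apply(out2, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-9)
  expect_lt(max(abs(colMeans(out2) - mean(out2[, 1]))), 1e-9)
})

test_that("probe collapse averages within genes", {
  m <- tiny_matrix(rbind(c(4, 5), c(6, 7)), genes = c("p1", "p2"))
  # 1:1 mapping relabels without changing values
  out <- collapse_probes(m, c(p1 = "A", p2 = "B"))
  expect_equal(sort(rownames(out)), c("A", "B"))
  expect_equal(unname(out["A", ]), c(4, 5))
  # two probes average
  out <- collapse_probes(m, c(p1 = "A", p2 = "A"))
  expect_equal(unname(out["A", ]), c(5, 6))
  # 6 probes, 3 genes: equals brute-force group means
  set.seed(3)
  m6 <- tiny_matrix(matrix(rnorm(12, 8), 6, 2), genes = sprintf("p%d", 1:6))
  map <- c(p1 = "A", p2 = "A", p3 = "B", p4 = "B", p5 = "B", p6 = "C")
  out <- collapse_probes(m6, map)
  expect_equal(nrow(out), 3)
  for (g in c("A", "B", "C"))
    expect_equal(out[g, ], colMeans(m6[names(map)[map == g], , drop = FALSE]))
  expect_error(collapse_probes(m, character()), "empty probe-to-gene mapping")
  expect_error(collapse_probes(m, c(p1 = "A"), drop_unmapped = FALSE),
               "without gene mapping")
})

test_that("replicate averaging means per cell line in sheet order", {
  sheet <- toy_sheet()
  set.seed(11)
  m <- tiny_matrix(matrix(rnorm(16 * 5, 8), 5, 16), samples = sheet$sample_id)
  out <- average_replicates(m, sheet)
  expect_equal(colnames(out), unique(sheet$cell_line))
  for (l in colnames(out)) {
    ids <- sheet$sample_id[sheet$cell_line == l]
    expect_equal(out[, l], rowMeans(m[, ids]))
  }
  # mean of an explicit duplicate pair
  m2 <- tiny_matrix(matrix(c(7, 9), 1, 2), genes = "g",
                    samples = c("L_r1", "L_r2"))
  sh2 <- data.frame(sample_id = c("L_r1", "L_r2"), cell_line = "L",
                    replicate = 1:2, status = "parental", parent_line = "L",
                    phenotype = "epithelial")
  expect_equal(unname(average_replicates(m2, sh2)[1, 1]), 8)
  # column missing from sheet is an error naming it
  colnames(m)[1] <- "mystery"
  expect_error(average_replicates(m, sheet), "mystery")
})

test_that("probe collapse and replicate averaging commute", {
  sheet <- toy_sheet()
  set.seed(5)
  m <- tiny_matrix(matrix(rnorm(16 * 8, 8), 8, 16),
                   genes = sprintf("p%d", 1:8), samples = sheet$sample_id)
  map <- setNames(rep(c("A", "B", "C"), c(3, 3, 2)), rownames(m))
  a <- average_replicates(collapse_probes(m, map), sheet)
  b <- collapse_probes(average_replicates(m, sheet), map)
  expect_equal(a, b)
})
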