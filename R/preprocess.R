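#' Remove control probes and low-intensity rows
#'
#' Drops rows listed in `control_ids` and rows whose log2 intensity fails to
#' reach `min_log2` in at least `ceiling(min_fraction * n_samples)` samples.
#' Columns are never touched.
#'
#' @param m expression matrix (probes or genes x samples).
#' @param min_log2 intensity threshold on the log2 scale. Default: the 20th
#'   percentile of the whole matrix.
#' @param min_fraction fraction of samples (in `[0, 1]`) that must reach the
#'   threshold for a row to survive. Default 0.25.
#' @param control_ids identifiers of control rows to drop regardless of
#'   intensity.
#' @return filtered expression matrix.
#' @export
filter_low_intensity <- function(m,
                                 min_log2 = stats::quantile(m, 0.20),
                                 min_fraction = 0.25,
                                 control_ids = character()) {
  validate_expression_matrix(m)
  if (min_fraction < 0 || min_fraction > 1)
    stop("min_fraction must lie in [0, 1]")
  keep <- !(rownames(m) %in% control_ids)
  need <- ceiling(min_fraction * ncol(m))
  keep <- keep & (rowSums(m >= min_log2) >= need)
  if (!any(keep))
    stop("filter_low_intensity removed every row; review min_log2 (",
         format(min_log2), ") and min_fraction (", min_fraction, ")")
  m[keep, , drop = FALSE]
}

#' Quantile-normalize sample columns
#'
#' Forces every column to share one empirical distribution: each value is
#' replaced by the mean, across columns, of the values at its within-column
#' rank; ties receive the average of the rank means over the tied positions.
#' Delegates to [limma::normalizeQuantiles()] with tie averaging.
#'
#' @param m expression matrix with at least one column.
#' @return normalized matrix with unchanged dimnames.
#' @export
quantile_normalize <- function(m) {
  validate_expression_matrix(m)
  if (ncol(m) < 1L || nrow(m) < 1L) stop("cannot quantile-normalize an empty matrix")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Summarize probes into genes by averaging
#'
#' Probes mapping to the same gene symbol are collapsed into one row holding
#' their arithmetic mean on the log2 scale.
#'
#' @param m expression matrix with probe identifiers as row names.
#' @param probe_to_gene named character vector, names are probe ids, values
#'   gene symbols.
#' @param drop_unmapped drop probes absent from the map (default `TRUE`);
#'   with `FALSE`, unmapped probes are an error.
#' @return expression matrix with one row per distinct mapped gene symbol
#'   (rows ordered by symbol).
#' @export
collapse_probes <- function(m, probe_to_gene, drop_unmapped = TRUE) {
  validate_expression_matrix(m)
  if (length(probe_to_gene) == 0L) stop("empty probe-to-gene mapping")
  if (is.null(names(probe_to_gene))) stop("probe_to_gene must be named by probe id")
  mapped <- rownames(m) %in% names(probe_to_gene)
  if (!drop_unmapped && !all(mapped))
    stop("probes without gene mapping: ",
         paste(utils::head(rownames(m)[!mapped], 5), collapse = ", "))
  mm <- m[mapped, , drop = FALSE]
  grp <- unname(probe_to_gene[rownames(mm)])
  sums <- rowsum(mm, group = grp)
  counts <- as.vector(table(grp)[rownames(sums)])
  out <- sums / counts
  validate_expression_matrix(out)
  out
}

#' Average replicate arrays into one column per cell line
#'
#' @param m expression matrix with per-array columns.
#' @param sheet sample sheet covering every column of `m`.
#' @return expression matrix with one column per cell line (arithmetic mean of
#'   its replicate columns), columns ordered by first appearance in the sheet.
#' @export
average_replicates <- function(m, sheet) {
  validate_expression_matrix(m)
  validate_sample_sheet(sheet, m)
  lines <- unique(sheet$cell_line)
  out <- vapply(lines, function(l) {
    ids <- intersect(sheet$sample_id[sheet$cell_line == l], colnames(m))
    if (length(ids) == 0L)
      stop("cell line ", l, " has no sample columns in the matrix")
    rowMeans(m[, ids, drop = FALSE])
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m), dimnames = list(rownames(m), lines))
  out
}
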