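#' Validate a log2 expression matrix
#'
#' The whole workflow carries expression data as a plain numeric matrix on the
#' log2 scale with gene symbols as row names and sample (or cell line) labels
#' as column names. This checks the container invariants: named dimensions,
#' no duplicated gene or sample labels, and all values finite.
#'
#' @param m numeric matrix, genes in rows, samples in columns.
#' @return `m`, invisibly, after validation.
#' @export
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression data must be a numeric matrix (genes x samples)")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix must have gene row names and sample column names")
  if (anyDuplicated(rownames(m)))
    stop("duplicate gene identifiers in expression matrix: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample identifiers in expression matrix: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (!all(is.finite(m)))
    stop("expression matrix contains non-finite values")
  invisible(m)
}

warn_symbol_case_collisions <- function(ids) {
  up <- toupper(ids)
  if (anyDuplicated(up)) {
    coll <- unique(up[duplicated(up)])
    warning("gene identifiers collide after case folding: ",
            paste(utils::head(coll, 5), collapse = ", "),
            if (length(coll) > 5) ", ..." else "")
  }
  invisible(ids)
}

#' Read a log2 expression matrix
#'
#' Reads either a plain TSV (first column header `gene`, one column per
#' sample) or the table embedded in a GEO Series Matrix text file (the block
#' between `!series_matrix_table_begin` and `!series_matrix_table_end`;
#' metadata lines outside the block are skipped).
#'
#' @param path file to read.
#' @param format `"tsv"` or `"geo_series_matrix"`.
#' @param log2_input if `FALSE` the values are treated as linear-scale
#'   intensities and log2-transformed after reading (all values must then be
#'   strictly positive). Default `TRUE`: values are passed through untouched.
#' @return numeric matrix, genes x samples, log2 scale.
#' @export
read_expression <- function(path, format = c("tsv", "geo_series_matrix"),
                            log2_input = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    if (length(header) < 2L || tolower(header[1]) != "gene")
      stop("malformed header at line 1 of ", path,
           ": expected first column 'gene' followed by sample ids")
    df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                            colClasses = "character", quote = "")
  } else {
    lines <- readLines(path)
    b <- grep("^!series_matrix_table_begin", lines)
    e <- grep("^!series_matrix_table_end", lines)
    if (length(b) != 1L || length(e) != 1L || e <= b + 1L)
      stop("malformed series matrix file ", path,
           ": missing or empty !series_matrix_table_begin/end block")
    df <- utils::read.delim(text = lines[(b + 1L):(e - 1L)], header = TRUE,
                            sep = "\t", check.names = FALSE,
                            colClasses = "character")
  }
  ids <- df[[1]]
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample columns in ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- suppressWarnings(vapply(df[-1], as.numeric, numeric(nrow(df))))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(df))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-numeric value in ", path, " at row ", bad[1, 1], " (gene '",
         ids[bad[1, 1]], "'), sample column '", samples[bad[1, 2]], "'")
  rownames(vals) <- ids
  colnames(vals) <- samples
  warn_symbol_case_collisions(ids)
  if (!log2_input) {
    if (any(vals <= 0))
      stop("linear-scale input contains values <= 0; cannot log2-transform")
    vals <- log2(vals)
  }
  validate_expression_matrix(vals)
  vals
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()] for the TSV format.
#'
#' @param m expression matrix.
#' @param path output file.
#' @export
write_expression <- function(m, path) {
  validate_expression_matrix(m)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

sample_sheet_columns <- c("sample_id", "cell_line", "replicate", "status",
                          "parent_line", "phenotype")

#' Validate a sample sheet
#'
#' A sample sheet assigns each array a cell line, replicate number, status
#' (`parental`/`resistant`), the parental cell line it derives from (itself
#' for parentals) and a phenotype class (`epithelial`/`hybrid`/`mesenchymal`).
#'
#' @param sheet data frame with columns `sample_id`, `cell_line`, `replicate`,
#'   `status`, `parent_line`, `phenotype`.
#' @param m optional expression matrix; if given, every column of `m` must be
#'   a `sample_id` of the sheet.
#' @return `sheet`, invisibly.
#' @export
validate_sample_sheet <- function(sheet, m = NULL) {
  missing_cols <- setdiff(sample_sheet_columns, colnames(sheet))
  if (length(missing_cols) > 0L)
    stop("sample sheet lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  if (!all(sheet$status %in% c("parental", "resistant")))
    stop("status must be 'parental' or 'resistant'")
  if (!all(sheet$phenotype %in% c("epithelial", "hybrid", "mesenchymal")))
    stop("phenotype must be epithelial, hybrid or mesenchymal")
  if (any(sheet$replicate < 1))
    stop("replicate numbers must be >= 1")
  parental_lines <- unique(sheet$cell_line[sheet$status == "parental"])
  res <- sheet[sheet$status == "resistant", ]
  orphan <- setdiff(unique(res$parent_line), parental_lines)
  if (length(orphan) > 0L)
    stop("resistant samples reference parental line(s) absent from the sheet: ",
         paste(orphan, collapse = ", "))
  ph_per_line <- tapply(sheet$phenotype, sheet$cell_line,
                        function(x) length(unique(x)))
  if (any(ph_per_line > 1L))
    stop("phenotype must be constant within a cell line; offending line(s): ",
         paste(names(ph_per_line)[ph_per_line > 1L], collapse = ", "))
  if (!is.null(m)) {
    unknown <- setdiff(colnames(m), sheet$sample_id)
    if (length(unknown) > 0L)
      stop("expression columns missing from sample sheet: ",
           paste(unknown, collapse = ", "))
  }
  invisible(sheet)
}

#' Read a sample sheet TSV
#'
#' @param path TSV with exactly the sample sheet columns.
#' @return validated data frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE,
                             colClasses = "character")
  sheet$replicate <- as.integer(sheet$replicate)
  validate_sample_sheet(sheet)
  sheet
}

#' Write a sample sheet TSV
#'
#' @param sheet sample sheet data frame.
#' @param path output file.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  utils::write.table(sheet[, sample_sheet_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
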