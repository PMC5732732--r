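#' Construct a named gene list
#'
#' Symbols are normalized to uppercase with surrounding whitespace stripped
#' and de-duplicated preserving first appearance. No alias resolution is
#' attempted: lists are matched on official symbols.
#'
#' @param name non-empty list name.
#' @param symbols character vector of gene symbols.
#' @param source free-text provenance.
#' @return object of class `gene_list` with elements `name`, `symbols`,
#'   `source`.
#' @export
gene_list <- function(name, symbols, source = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("gene list name must be a non-empty string")
  symbols <- toupper(trimws(as.character(symbols)))
  symbols <- symbols[nzchar(symbols)]
  symbols <- symbols[!duplicated(symbols)]
  structure(list(name = name, symbols = symbols, source = source),
            class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat("gene_list '", x$name, "': ", length(x$symbols), " symbols",
      if (nzchar(x$source)) paste0(" [", x$source, "]"), "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_list <- function(x) length(x$symbols)

as_symbols <- function(x) {
  if (inherits(x, "gene_list")) x$symbols
  else toupper(trimws(as.character(x)))
}

#' Read a gene list from plain text
#'
#' One symbol per line; `#` starts a comment; blank lines ignored.
#'
#' @param path file to read.
#' @param name list name (default: file name without extension).
#' @return a [gene_list()].
#' @export
read_gene_list <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  gene_list(name, lines[nzchar(trimws(lines))], source = path)
}

#' Write a gene list as plain text
#' @param x a `gene_list`.
#' @param path output file.
#' @export
write_gene_list <- function(x, path) {
  writeLines(x$symbols, path)
  invisible(path)
}

#' Read a GMT file into a gene list collection
#'
#' Standard GMT: tab-separated lines of name, description, then symbols.
#'
#' @param path GMT file.
#' @return named list of [gene_list()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lists <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line (need name, description, >=1 gene): ", l)
    gene_list(f[1], f[-(1:2)], source = f[2])
  })
  names(lists) <- vapply(lists, `[[`, character(1), "name")
  if (anyDuplicated(names(lists))) stop("duplicate term names in ", path)
  lists
}

#' Write a gene list collection as GMT
#' @param lists named list of `gene_list` objects.
#' @param path output file.
#' @export
write_gmt <- function(lists, path) {
  lines <- vapply(lists, function(x) {
    paste(c(x$name, if (nzchar(x$source)) x$source else "na", x$symbols),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Pool several gene lists into one
#'
#' Union of symbols, each counted once (first-appearance order). The returned
#' list carries a `membership` attribute recording, per symbol, the names of
#' the contributing lists.
#'
#' @param lists list of `gene_list` objects.
#' @param name name for the pooled list.
#' @return a [gene_list()].
#' @export
pool_gene_lists <- function(lists, name = "pooled") {
  if (length(lists) < 1L) stop("need at least one list to pool")
  stopifnot(all(vapply(lists, inherits, logical(1), "gene_list")))
  all_syms <- unlist(lapply(lists, `[[`, "symbols"), use.names = FALSE)
  pooled <- gene_list(name, all_syms,
                      source = paste(vapply(lists, `[[`, character(1), "name"),
                                     collapse = "+"))
  membership <- lapply(pooled$symbols, function(s) {
    names(lists)[vapply(lists, function(l) s %in% l$symbols, logical(1))]
  })
  names(membership) <- pooled$symbols
  attr(pooled, "membership") <- membership
  pooled
}

#' Restrict a gene list to genes measured in a matrix
#'
#' Matching is case-insensitive; input order is preserved. An empty
#' intersection is a warning, not an error.
#'
#' @param x a `gene_list`.
#' @param m expression matrix.
#' @return a `gene_list` of the measured subset.
#' @export
restrict_to_measured <- function(x, m) {
  validate_expression_matrix(m)
  measured <- x$symbols[x$symbols %in% toupper(rownames(m))]
  if (length(measured) == 0L)
    warning("no gene of list '", x$name, "' is measured in the matrix")
  gene_list(x$name, measured, source = x$source)
}

#' Pairwise overlap counts among gene lists
#'
#' @param lists list (length >= 2) of `gene_list` objects.
#' @return symmetric integer matrix; entry (i, j) is the intersection size,
#'   the diagonal holds list sizes.
#' @export
pairwise_overlaps <- function(lists) {
  if (length(lists) < 2L) stop("need at least two lists")
  nm <- vapply(lists, `[[`, character(1), "name")
  n <- length(lists)
  out <- matrix(0L, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- length(intersect(lists[[i]]$symbols, lists[[j]]$symbols))
  out
}
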