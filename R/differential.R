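#' Resistant-versus-parental log fold-changes
#'
#' For a replicate-averaged matrix with one column per cell line, computes
#' `logfc(gene, r) = m[gene, r] - m[gene, parent(r)]` for every resistant
#' line `r` declared in the sample sheet.
#'
#' @param m expression matrix, one column per cell line.
#' @param sheet sample sheet; `cell_line`/`status`/`parent_line` drive the
#'   comparisons.
#' @return numeric matrix, genes x resistant lines, log2 fold-change units.
#' @export
pairwise_logfc <- function(m, sheet) {
  validate_expression_matrix(m)
  validate_sample_sheet(sheet)
  res <- unique(sheet[sheet$status == "resistant", c("cell_line", "parent_line")])
  if (nrow(res) == 0L) stop("sample sheet declares no resistant cell line")
  missing_r <- setdiff(res$cell_line, colnames(m))
  if (length(missing_r) > 0L)
    stop("resistant line(s) absent from matrix columns: ",
         paste(missing_r, collapse = ", "))
  missing_p <- setdiff(res$parent_line, colnames(m))
  if (length(missing_p) > 0L)
    stop("parental line(s) absent from matrix columns: ",
         paste(missing_p, collapse = ", "))
  out <- m[, res$cell_line, drop = FALSE] - m[, res$parent_line, drop = FALSE]
  colnames(out) <- res$cell_line
  out
}

#' Per-gene recurrence table across resistant-line comparisons
#'
#' Counts, per gene, the comparisons with log fold-change at or above
#' `cutoff` (`n_up`) and at or below `-cutoff` (`n_down`), calls the gene
#' `up`/`down` when a count reaches `min_recurrence`, and reports the mean
#' log fold-change used for ranking.
#'
#' @param lfc log fold-change matrix from [pairwise_logfc()].
#' @param cutoff positive log2 fold-change cutoff (default 1).
#' @param min_recurrence minimum number of qualifying comparisons (default 5).
#' @param rank_mean_scope `"qualifying"` (default) averages the log
#'   fold-change over the comparisons that passed the cutoff in the called
#'   direction; `"all"` averages over every comparison.
#' @return data frame: `gene`, one column per comparison, `n_up`, `n_down`,
#'   `mean_logfc` (`NA` when call is `none`), `call`.
#' @export
differential_table <- function(lfc, cutoff = 1, min_recurrence = 5,
                               rank_mean_scope = c("qualifying", "all")) {
  rank_mean_scope <- match.arg(rank_mean_scope)
  if (cutoff <= 0) stop("cutoff must be positive")
  if (min_recurrence > ncol(lfc))
    stop("min_recurrence (", min_recurrence, ") exceeds the number of comparisons (",
         ncol(lfc), ")")
  n_up <- rowSums(lfc >= cutoff)
  n_down <- rowSums(lfc <= -cutoff)
  call <- rep("none", nrow(lfc))
  call[n_up >= min_recurrence & n_up > n_down] <- "up"
  call[n_down >= min_recurrence & n_down > n_up] <- "down"
  mean_logfc <- rep(NA_real_, nrow(lfc))
  for (i in which(call != "none")) {
    qual <- if (call[i] == "up") lfc[i, ] >= cutoff else lfc[i, ] <= -cutoff
    mean_logfc[i] <- if (rank_mean_scope == "qualifying")
      mean(lfc[i, qual]) else mean(lfc[i, ])
  }
  data.frame(gene = rownames(lfc), lfc, n_up = n_up, n_down = n_down,
             mean_logfc = mean_logfc, call = call,
             check.names = FALSE, row.names = NULL)
}

#' Recurrently up- and down-regulated genes
#'
#' Genes whose log fold-change passes the cutoff in the same direction in at
#' least `min_recurrence` of the comparisons.
#'
#' @inheritParams differential_table
#' @return list with `gene_list` elements `up` and `down`, plus the full
#'   `table` from [differential_table()].
#' @export
recurrent_genes <- function(lfc, cutoff = 1, min_recurrence = 5,
                            rank_mean_scope = c("qualifying", "all")) {
  d <- differential_table(lfc, cutoff, min_recurrence, match.arg(rank_mean_scope))
  mk <- function(dir) {
    g <- d$gene[d$call == dir]
    gene_list(paste0("recurrent_", dir), g,
              source = sprintf("|logfc| >= %g in >= %d/%d comparisons",
                               cutoff, min_recurrence, ncol(lfc)))
  }
  list(up = mk("up"), down = mk("down"), table = d)
}

#' Rank recurrent genes by mean log fold-change
#'
#' Orders the genes called in the requested direction by decreasing absolute
#' mean log fold-change; ties broken by symbol.
#'
#' @param d table from [differential_table()].
#' @param direction `"up"` or `"down"`.
#' @return data frame `gene`, `mean_logfc` in rank order (possibly empty).
#' @export
rank_recurrent <- function(d, direction = c("up", "down")) {
  direction <- match.arg(direction)
  sub <- d[d$call == direction, c("gene", "mean_logfc")]
  sub <- sub[order(-abs(sub$mean_logfc), sub$gene), ]
  rownames(sub) <- NULL
  sub
}

#' Write a differential table as TSV
#' @param d table from [differential_table()].
#' @param path output file.
#' @export
write_differential_table <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
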