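#!/usr/bin/env Rscript
# Resistant-vs-parental differential expression with the recurrence rule:
# |log2 FC| >= 1 in at least 5 of the 6 comparisons, ranked by mean
# qualifying log fold-change.

library(emtsig)

lines <- read_expression("results/cell_lines.tsv")
sheet <- read_sample_sheet("results/data/sample_sheet.tsv")

lfc <- pairwise_logfc(lines, sheet)
rec <- recurrent_genes(lfc, cutoff = 1, min_recurrence = 5)
write_differential_table(rec$table, "results/differential.tsv")

cat("per-line deregulated genes at |logFC| >= 1:\n")
print(rbind(up = colSums(lfc >= 1), down = colSums(lfc <= -1)))
cat("recurrent (>=5/6):", length(rec$up$symbols), "up,",
    length(rec$down$symbols), "down\n")

for (dir in c("up", "down")) {
  ranked <- rank_recurrent(rec$table, dir)
  utils::write.table(ranked, sprintf("results/recurrent_%s_ranked.tsv", dir),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat("top", dir, "genes:",
      paste(utils::head(ranked$gene, 5), collapse = ", "), "\n")
}
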