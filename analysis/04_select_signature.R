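#!/usr/bin/env Rscript
# The three supervised selectors over the pooled candidate list, and their
# consensus intersection: CO (epithelial/mesenchymal fold-change cut-off with
# flat epithelium), SVM (linear hyperplane coefficients over three pairwise
# phenotype problems), PROF (dendrogram cut of standardized profiles with a
# centroid-trend screen).

library(emtsig)

norm <- read_expression("results/normalized.tsv")
lines <- read_expression("results/cell_lines.tsv")
sheet <- read_sample_sheet("results/data/sample_sheet.tsv")
list_files <- list.files("results/data/lists", full.names = TRUE)
lists <- lapply(list_files, read_gene_list)
names(lists) <- vapply(lists, `[[`, character(1), "name")

cat("pairwise overlaps among candidate lists:\n")
print(pairwise_overlaps(lists))

combo <- pool_gene_lists(lists, name = "COMBO")
cand <- restrict_to_measured(combo, lines)
write_gene_list(cand, "results/combo_candidates.txt")
cat("pooled", length(combo$symbols), "genes;", length(cand$symbols),
    "measured on the array\n")

design <- phenotype_design(sheet)
co <- select_co(lines, design, cand)
svm <- select_svm(norm, sheet, cand)
prof <- select_prof(lines, design, cand,
                    n_clusters = min(38, length(cand$symbols)))
int <- intersect_selections(list(co, svm, prof))

for (r in list(co, svm, prof, int)) {
  write_selection(r, sprintf("results/selection_%s.tsv", tolower(r$method)))
  write_gene_list(r$genes,
                  sprintf("results/signature_%s.txt", tolower(r$method)))
  cat(sprintf("%-4s selected %d genes\n", r$method,
              length(r$genes$symbols)))
}
cat("consensus signature:", paste(int$genes$symbols, collapse = ", "), "\n")
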