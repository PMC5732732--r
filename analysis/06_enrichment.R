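#!/usr/bin/env Rscript
# Over-representation of each selected signature against the term collection
# (EASE statistic), with the relevance rule requiring both p < 0.05 and a
# fold enrichment above that of the pooled candidate list.

library(emtsig)

lines <- read_expression("results/cell_lines.tsv")
terms <- read_gmt("results/data/terms.gmt")
background <- gene_list("background", rownames(lines))
cand <- read_gene_list("results/combo_candidates.txt")

ref <- ora(cand, background, terms)
write_enrichment(ref, "results/enrichment_combo_reference.tsv")

for (meth in c("co", "svm", "prof", "int")) {
  sig <- read_gene_list(sprintf("results/signature_%s.txt", meth))
  tab <- compare_enrichment(ora(sig, background, terms), ref)
  write_enrichment(tab, sprintf("results/enrichment_%s.tsv", meth))
  rel <- tab[tab$relevant, ]
  cat(toupper(meth), ": ", nrow(rel), " relevant term(s)",
      if (nrow(rel) > 0) paste0(": ", paste(
        sprintf("%s (FE %.1f vs %.1f, p %.2g)", rel$term_id,
                rel$fold_enrichment, rel$ref_fold_enrichment, rel$p_value),
        collapse = "; ")), "\n", sep = "")
}
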