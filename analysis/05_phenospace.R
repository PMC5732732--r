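#!/usr/bin/env Rscript
# Phenotype space: PCA of the replicate arrays over each selected signature
# (genes scaled to unit variance), and unsupervised sample clustering
# (complete linkage, Euclidean) over the pooled candidate list.

library(emtsig)

norm <- read_expression("results/normalized.tsv")
sheet <- read_sample_sheet("results/data/sample_sheet.tsv")

for (meth in c("co", "svm", "prof", "int")) {
  sig <- read_gene_list(sprintf("results/signature_%s.txt", meth))
  pca <- pca_samples(norm, sig)
  write_pca(pca, sprintf("results/pca_%s", meth))
  pc1 <- pca$scores[, 1]
  ph <- sheet$phenotype[match(names(pc1), sheet$sample_id)]
  mu <- tapply(pc1, ph, mean)
  cat(sprintf("%-4s: PC1 %.1f%%, PC2 %.1f%%; PC1 means E %.2f / H %.2f / M %.2f\n",
              toupper(meth), pca$var_explained[1], pca$var_explained[2],
              mu[["epithelial"]], mu[["hybrid"]], mu[["mesenchymal"]]))
}

cand <- read_gene_list("results/combo_candidates.txt")
hc <- hcluster_samples(norm, cand)
writeLines(dendrogram_newick(hc), "results/sample_dendrogram.nwk")
cl <- first_bipartition(hc)
cat("first dendrogram split:\n")
print(split(names(cl), cl))
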