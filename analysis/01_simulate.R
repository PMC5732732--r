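#!/usr/bin/env Rscript
# Generate the reference synthetic cohort: 8 cell lines (2 epithelial
# parentals, 5 hybrid E/M resistant derivatives, 1 mesenchymal resistant
# derivative) x 2 replicate arrays, with planted phenotype markers,
# recurrent resistance genes and a shared cell-line-of-origin offset.
# Also emits five partially overlapping curated-style candidate gene lists.

library(emtsig)

seed <- 20260921L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)
sim <- simulate_cohort(cfg)
paths <- write_cohort(sim, out)

lists <- generate_gene_lists(sim$truth, seed = seed)
dir.create(file.path(out, "lists"), showWarnings = FALSE)
for (l in lists)
  write_gene_list(l, file.path(out, "lists", paste0(l$name, ".txt")))

terms <- list(
  mes_markers = gene_list("mes_markers", sim$truth$marker_mesenchymal,
                          "planted mesenchymal-high markers"),
  epi_markers = gene_list("epi_markers", sim$truth$marker_epithelial,
                          "planted epithelial-high markers"),
  resistance_up = gene_list("resistance_up", sim$truth$resistance_up,
                            "planted recurrently upregulated genes"),
  random_200 = gene_list("random_200", sim$truth$gene_ids[1:200],
                         "arbitrary background slice"))
write_gmt(terms, file.path(out, "terms.gmt"))

cat("cohort:", nrow(sim$matrix), "genes x", ncol(sim$matrix), "arrays ->",
    out, "\n")
cat("candidate lists:", paste(names(lists), collapse = ", "), "\n")
cat("planted: ", length(sim$truth$marker_epithelial), "epithelial-high +",
    length(sim$truth$marker_mesenchymal), "mesenchymal-high markers;",
    length(sim$truth$resistance_up), "up +",
    length(sim$truth$resistance_down), "down resistance genes\n")
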