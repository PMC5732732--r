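#!/usr/bin/env Rscript
# Normalize the cohort: quantile-normalize the replicate arrays so every
# column shares one empirical distribution, then average replicates into one
# column per cell line. (The synthetic cohort is gene-level; the
# probe-collapse step applies when starting from probe-level data.)

library(emtsig)

m <- read_expression("results/data/expression.tsv")
sheet <- read_sample_sheet("results/data/sample_sheet.tsv")

norm <- quantile_normalize(m)
lines <- average_replicates(norm, sheet)

write_expression(norm, "results/normalized.tsv")
write_expression(lines, "results/cell_lines.tsv")

cat("normalized", nrow(norm), "genes x", ncol(norm), "arrays;",
    "column means now agree to",
    format(max(abs(colMeans(norm) - mean(norm[, 1]))), digits = 3), "\n")
cat("replicate-averaged matrix:", ncol(lines), "cell lines\n")
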