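#!/usr/bin/env Rscript

# Stage 4: report the strategy x kernel table.

suppressPackageStartupMessages(library(flexstates))

metrics <- utils::read.table("results/metrics.tsv", header = TRUE, sep = "\t")
perm <- jsonlite::read_json("results/metrics.json")$permutation_p

cat("Fold-mean performance of the four SVM kernels under each selection strategy\n\n")
report_metrics(metrics)
cat("\nPermutation p-values (Spearman selection, 200 permutations):\n")
for (k in names(perm)) cat(sprintf("  %s: p = %.4f\n", k, perm[[k]]))
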