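#!/usr/bin/env Rscript
# Stage 2 — normalization and per-contrast differential expression:
# median-of-ratios size factors, log2 normalization, then a Welch test of
# each aphid treatment against control at the same timepoint with BH
# correction within contrast (DEG = FDR < 0.05 and fold change > 2).

library(switchnet)

counts <- read_counts("results/data/counts.tsv")
design <- read_design("results/data/design.tsv")

norm <- normalize_counts(counts)
deg <- call_degs(norm, design)

dir.create("results", showWarnings = FALSE)
utils::write.table(deg, "results/deg.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

tab <- aggregate(is_deg ~ treatment + timepoint, deg, sum)
message("DEG calls per contrast (FDR < 0.05, fold > 2):")
for (i in seq_len(nrow(tab)))
  message(sprintf("  %s at %2d DAI: %4d", tab$treatment[i],
                  tab$timepoint[i], tab$is_deg[i]))
message("Total DEG calls: ", sum(deg$is_deg), " across ",
        length(unique(deg$gene[deg$is_deg])), " genes.")
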