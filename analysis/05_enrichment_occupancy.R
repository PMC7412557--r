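#!/usr/bin/env Rscript
# Stage 5 — pathway enrichment and transcript/metabolite occupancy:
# Fisher's exact enrichment of modules and TF subnetworks against the
# expressed-gene background, metabolite ANOVA + Tukey HSD per timepoint,
# and the pathway-occupancy percentages for both molecular layers.

library(switchnet)

counts <- read_counts("results/data/counts.tsv")
design <- read_design("results/data/design.tsv")
ann <- read_annotations("results/data/annotations.tsv")
met <- read_metabolites("results/data/metabolites.tsv",
                        "results/data/metabolite_pathways.tsv")
deg <- utils::read.delim("results/deg.tsv", stringsAsFactors = FALSE)
mods <- utils::read.delim("results/modules.tsv", stringsAsFactors = FALSE)
subnets <- utils::read.delim("results/subnetworks.tsv",
                             stringsAsFactors = FALSE)

norm <- normalize_counts(counts)
expressed <- filter_expressed(norm)

# gene -> pathways map from the annotation table
pw_pairs <- do.call(rbind, lapply(seq_len(nrow(ann)), function(i) {
  ps <- strsplit(ann$pathways[i], ";", fixed = TRUE)[[1]]
  if (length(ps)) data.frame(gene = ann$gene_id[i], pathway = ps)
}))
gene_pathways <- split(pw_pairs$gene, pw_pairs$pathway)

enr <- list()
for (m in setdiff(unique(mods$module), "unassigned"))
  enr[[m]] <- fisher_enrichment(mods$gene[mods$module == m], expressed,
                                gene_pathways, unit = m)
for (tf in unique(subnets$tf))
  enr[[tf]] <- fisher_enrichment(subnets$member[subnets$tf == tf],
                                 expressed, gene_pathways, unit = tf)
enrichment <- do.call(rbind, enr)
utils::write.table(enrichment, "results/enrichment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

da <- metabolite_da(met$abundance, design)
utils::write.table(da, "results/metabolite_da.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

occ_t <- transcript_occupancy(deg, gene_pathways, expressed)
occ_m <- metabolite_occupancy(da, met$pathway_map, rownames(met$abundance))
utils::write.table(occ_t, "results/occupancy_transcript.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(occ_m, "results/occupancy_metabolite.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

n_sig_mod <- sum(enrichment$significant &
                   enrichment$unit %in% mods$module)
message("Significant module-pathway enrichments (raw p <= 0.05): ",
        n_sig_mod)
message("Differentially abundant metabolite calls: ",
        sum(da$significant), " of ", nrow(da),
        " metabolite x timepoint x treatment tests.")
message("Occupancy cells written: ", nrow(occ_t), " transcript, ",
        nrow(occ_m), " metabolite; maxima ",
        sprintf("%.1f%% / %.1f%%", max(occ_t$percent), max(occ_m$percent)))
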