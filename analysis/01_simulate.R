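#!/usr/bin/env Rscript
# Stage 1 — simulate the study: 3 treatments (control, GB, YSA) x
# 3 timepoints (5/10/15 DAI) x 3 replicates, six planted co-expression
# modules with hub TFs, planted pathway enrichments, and four metabolite
# response sets. Writes all input tables for the later stages.

library(switchnet)

seed <- 1L
out <- "results/data"
ds <- simulate_dataset(seed = seed)
write_dataset(ds, out)

message("Simulated ", nrow(ds$counts), " genes x ", ncol(ds$counts),
        " samples (", length(unique(ds$truth$module)) - 1,
        " planted modules, ",
        length(unlist(ds$truth$hub_tfs)), " hub TFs, ",
        nrow(ds$metabolites$abundance), " metabolites).")
message("Tables written under ", out, "/ (counts, design, annotations, ",
        "metabolites, metabolite pathways, truth.json).")
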