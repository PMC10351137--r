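#!/usr/bin/env Rscript
## Stage 0: generate the synthetic study — a phased haplotype panel with a
## planted causal SNP, annotation layers (peaks, eQTL table, motif,
## sequence), a contact table with a planted loop, a clustered single-cell
## matrix and a reporter plate — and write everything as standard-format
## files under results/study/.

suppressPackageStartupMessages(library(snp2enhancer))

cfg <- sim_config(seed = 1)
out <- "results/study"
study <- simulate_to_dir(cfg, out)

message("wrote synthetic study to ", out)
message("  haplotypes: ", nrow(study$panel$alleles),
        "  SNPs: ", nrow(study$panel$variants))
message("  planted causal SNP: ", study$truth$causal_rsid,
        "  index SNP: ", study$truth$index_rsid)
message(sprintf("  realized index-causal r2: %.3f (target %.2f)",
                study$truth$realized_r2, cfg$target_r2))
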