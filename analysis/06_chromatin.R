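#!/usr/bin/env Rscript
## Stage 6: distance-normalized (observed/expected) contact profile from
## the candidate SNP's bin, reporting bins with O/E >= 2.00 and any gene
## promoters they contain.

suppressPackageStartupMessages(library(snp2enhancer))

cfg <- sim_config(seed = 1)
contacts <- read_contacts("results/study/contacts.tsv", cfg$bin_size)
tss_bed <- read_bed("results/study/tss.bed")
tss <- data.frame(gene = tss_bed$name, chrom = tss_bed$chrom,
                  tss_pos = tss_bed$end)
truth <- jsonlite::read_json("results/study/truth.json")
panel <- read_vcf("results/study/panel.vcf")
bait_pos <- panel$variants$pos[panel$variants$rsid == truth$causal_rsid]

prof <- bait_query(contacts, bait_pos, tss, threshold = 2.00)
write.table(prof$profile, "results/bait_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("bait bin ", prof$bait_bin, ": ", nrow(prof$reported),
        " bin(s) at O/E >= 2.00")
for (i in seq_len(nrow(prof$promoter_hits)))
  message(sprintf("  promoter contact: %s in bin %d (O/E %.2f)",
                  prof$promoter_hits$gene[i], prof$promoter_hits$bin[i],
                  prof$promoter_hits$normalized[i]))
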