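#!/usr/bin/env Rscript
## Stage 2-3: annotate the LD candidates with eQTL effects (harmonized to
## the alt allele) and with TF ChIP-seq / regulatory-region peak overlaps.

suppressPackageStartupMessages(library(snp2enhancer))

panel <- read_vcf("results/study/panel.vcf")
ld <- read.table("results/ld.tsv", sep = "\t", header = TRUE)
eqtl <- read_eqtl("results/study/eqtl.tsv")
peaks <- read_bed_manifest("results/study/manifest.tsv")

v <- panel$variants
cand <- v[match(ld$proxy_rsid, v$rsid), ]
class(cand) <- c("variant_table", "data.frame")

eqtl_ann <- annotate_eqtl(cand, eqtl, gene = "AGTR2", tissue = "uterus")
overlaps <- annotate_overlaps(cand, peaks)
annotated <- merge(eqtl_ann, overlaps, by = "rsid")
write.table(annotated, "results/annotated.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sum(eqtl_ann$has_eqtl), " of ", nrow(cand),
        " candidates are uterus eQTLs for AGTR2")
message(sum(overlaps$n_tf > 0 & overlaps$n_reg > 0),
        " candidate(s) sit in both a TF ChIP-seq peak and a regulatory region")
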