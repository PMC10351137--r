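#!/usr/bin/env Rscript
## Stage 7: per-cluster expression frequency, enrichment fold and
## hypergeometric p-value for the target gene in the clustered cell x gene
## matrix.

suppressPackageStartupMessages(library(snp2enhancer))

counts <- Matrix::readMM("results/study/counts.mtx")
rownames(counts) <- readLines("results/study/genes.tsv")
colnames(counts) <- readLines("results/study/cells.tsv")
clusters <- read.table("results/study/clusters.tsv", sep = "\t",
                       header = TRUE)

en <- enrichment_by_cluster(counts, clusters, "AGTR2")
write.table(en, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

top <- en[1, ]
message(sprintf(
  "AGTR2 most enriched in %s: frequency %.1f%%, fold %.1f, p = %.1e",
  top$cluster, 100 * top$frequency, top$fold, top$pvalue))
message(sprintf("overall detection frequency: %.2f%% of %d cells",
                100 * top$overall_frequency, ncol(counts)))
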