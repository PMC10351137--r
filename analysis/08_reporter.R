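#!/usr/bin/env Rscript
## Stage 8: dual-luciferase analysis. Nano/firefly ratios, backbone
## normalization per condition, and the pooled-variance Student's t-test
## between the non-risk (T) and risk (C) constructs.

suppressPackageStartupMessages(library(snp2enhancer))

wells <- read.table("results/study/reporter.tsv", sep = "\t", header = TRUE)
res <- reporter_analysis(wells, condition = "decidualized")

write.table(res$normalized$summary, "results/reporter_activity.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(res$test, "results/reporter_test.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

t <- res$test
message(sprintf("normalized activity: T %.2f, C %.2f (ratio C/T %.2f)",
                t$mean_a, t$mean_b, t$activity_ratio))
message(sprintf("pooled t = %.3f (df %d), two-sided p = %.2e",
                t$t, t$df, t$pvalue))
message("direction: ", if (t$mean_b < t$mean_a)
  "risk C allele shows lower enhancer activity" else
  "no activity decrease for the risk allele")
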