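test_that("generators are pure functions of the config (same seed, same bytes)", {
  cfg <- sim_config(seed = 5, n_haplotypes = 200L, n_snps = 20L,
                    n_cells = 500L, n_genes = 5L)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$panel$alleles, b$panel$alleles)
  expect_identical(a$eqtl, b$eqtl)
  expect_identical(a$motif$pfm, b$motif$pfm)
  expect_identical(a$contacts$entries, b$contacts$entries)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$reporter, b$reporter)
})

test_that("planted causal/index r2 lands near target and target_r2 = 1 is exact", {
  sim <- simulate_panel(sim_config(seed = 1))
  expect_lt(abs(sim$truth$realized_r2 - 0.9), 0.05)

  sim1 <- simulate_panel(sim_config(seed = 2, target_r2 = 1))
  expect_equal(sim1$truth$realized_r2, 1)
  expect_equal(sim1$truth$flip_prob, 0)
})

test_that("degenerate single-founder panel is monomorphic and flagged", {
  cfg <- sim_config(seed = 3, founder_count = 1L, switch_rate = 0,
                    mutation_rate = 0, n_haplotypes = 50L, n_snps = 10L)
  expect_warning(sim <- simulate_panel(cfg), "monomorphic")
  ## every haplotype copies the single founder: all rows identical
  expect_true(all(apply(sim$panel$alleles, 2,
                        function(x) length(unique(x)) == 1L)))
  expect_length(sim$truth$monomorphic_columns, 10L)
  expect_true(is.na(sim$truth$realized_r2))
})

test_that("config invariants are validated", {
  expect_error(sim_config(target_r2 = 1.5), "target_r2")
  expect_error(sim_config(cluster_freq = 0.01, background_freq = 0.02),
               "background_freq")
  expect_error(sim_config(reporter_effect = 0), "reporter_effect")
  expect_error(sim_config(motif_length = 1L), "motif_length")
})

test_that("causal SNP sits in planted peaks; most decoys are peak-free", {
  cfg <- sim_config(seed = 4)
  sim <- simulate_panel(cfg)
  ann <- simulate_annotations(cfg, sim)
  v <- sim$panel$variants
  ov <- annotate_overlaps(v, ann$peaksets)
  ci <- cfg$causal_index
  expect_gte(ov$n_tf[ci], 2L)
  expect_gte(ov$n_reg[ci], 1L)
  decoys <- setdiff(seq_len(cfg$n_snps), c(ci, cfg$index_index))
  frac_clean <- mean(ov$n_tf[decoys] + ov$n_reg[decoys] == 0L)
  expect_gte(frac_clean, 0.8)
})

test_that("planted motif prefers the non-risk reference base at the SNP", {
  cfg <- sim_config(seed = 6)
  sim <- simulate_panel(cfg)
  ann <- simulate_annotations(cfg, sim)
  v <- sim$panel$variants
  ci <- cfg$causal_index
  snp_col <- (cfg$motif_length %/% 2L) + 1L
  e <- pfm_to_energy(ann$motif)$energies
  bases <- c("A", "C", "G", "T")
  e_ref <- e[snp_col, match(v$ref[ci], bases)]
  e_alt <- e[snp_col, match(v$alt[ci], bases)]
  expect_lt(e_ref, 0)          # preferred base: favorable (negative) energy
  expect_gt(e_alt, e_ref)      # risk base costs more energy
  ## the sequence carries the reference allele at every SNP
  seq_chars <- strsplit(ann$sequence$seq, "")[[1]]
  expect_identical(seq_chars[v$pos - 1L - ann$sequence$start + 1L], v$ref)
})

test_that("eQTL slope magnitude is maximal at the causal SNP across seeds", {
  for (seed in 1:10) {
    cfg <- sim_config(seed = seed)
    sim <- simulate_panel(cfg)
    ann <- simulate_annotations(cfg, sim)
    harm <- annotate_eqtl(sim$panel$variants, ann$eqtl, cfg$gene, cfg$tissue)
    ci <- cfg$causal_index
    expect_equal(which.min(harm$slope_alt), ci)
    expect_true(all(harm$slope_alt[harm$has_eqtl] <= 0))
  }
})

test_that("contact generator: no loop and no noise gives O/E of exactly 1", {
  cfg <- sim_config(seed = 8, contact_noise_sd = 0)
  hic <- simulate_contacts(cfg)
  ## strip the planted loop to get the pure decay surface
  e <- hic$contacts$entries
  loop <- e$bin_i == min(hic$truth$bait_bin, hic$truth$promoter_bin) &
    e$bin_j == max(hic$truth$bait_bin, hic$truth$promoter_bin)
  e$count[loop] <- e$count[loop] / cfg$loop_strength
  ct <- contact_table(hic$contacts$chrom, hic$contacts$bin_size, e)
  prof <- bait_query(ct, hic$bait_pos, threshold = 2, min_pairs = 1)
  expect_equal(prof$profile$normalized,
               rep(1, nrow(prof$profile)), tolerance = 1e-9)
})

test_that("single-cell generator hits its detection frequencies", {
  cfg <- sim_config(seed = 9)
  sc <- simulate_counts(cfg)
  expr <- detect_expressing(sc$counts, cfg$gene)
  labels <- sc$clusters$cluster
  in_cl <- labels == cfg$planted_cluster
  expect_lt(abs(mean(expr[in_cl]) - cfg$cluster_freq), 0.015)
  expect_lt(abs(mean(expr[!in_cl]) - cfg$background_freq), 0.005)
})

test_that("reporter generator recovers the planted allelic effect", {
  ratios <- vapply(1:25, function(s) {
    wells <- simulate_reporter(sim_config(seed = s))
    reporter_analysis(wells)$test$activity_ratio
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.5), 0.05)
})

test_that("simulate_to_dir writes files that reload to the same objects", {
  d <- withr::local_tempdir()
  cfg <- sim_config(seed = 10, n_haplotypes = 100L, n_snps = 15L,
                    causal_index = 8L, index_index = 7L,
                    n_cells = 400L, n_genes = 4L)
  study <- simulate_to_dir(cfg, d)
  expect_true(all(file.exists(file.path(
    d, c("panel.vcf", "manifest.tsv", "eqtl.tsv", "motif_cisbp.txt",
         "motif.meme", "sequence.fa", "contacts.tsv", "tss.bed",
         "counts.mtx", "clusters.tsv", "reporter.tsv", "truth.json")))))
  p <- read_vcf(file.path(d, "panel.vcf"))
  expect_identical(p$alleles, study$panel$alleles)
  ps <- read_bed_manifest(file.path(d, "manifest.tsv"))
  expect_equal(length(ps), length(study$peaksets))
  m <- read_motif(file.path(d, "motif_cisbp.txt"), "cisbp_pwm")
  expect_equal(m$pfm, study$motif$pfm, tolerance = 1e-5)
  sq <- read_sequence(file.path(d, "sequence.fa"))
  expect_identical(sq$seq, study$sequence$seq)
  cts <- as.matrix(Matrix::readMM(file.path(d, "counts.mtx")))
  expect_equal(unname(cts), unname(as.matrix(study$counts)))
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_equal(truth$causal_rsid, study$truth$causal_rsid)
})
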