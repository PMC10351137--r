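## 8 haplotypes at two sites: (1,1)x3, (1,0)x1, (0,1)x1, (0,0)x3
worked_panel <- function() {
  alleles <- rbind(matrix(1L, 3, 2), c(1L, 0L), c(0L, 1L), matrix(0L, 3, 2))
  vt <- variant_table(c("chrX", "chrX"), c(100L, 200L), c("rsA", "rsB"),
                     c("A", "C"), c("G", "T"))
  haplotype_panel(vt, alleles, sprintf("s%d", 1:4),
                  hap_sample = rep(1:4, each = 2L))
}

test_that("worked haplotype-counting example: r2 = 0.25, D' = 0.5", {
  ld <- pairwise_ld(worked_panel(), 1, 2)
  expect_equal(ld$r2, 0.25)
  expect_equal(ld$d_prime, 0.5)
  expect_equal(ld$d, 0.125)
})

test_that("self-LD is exactly 1 and complement columns give r2 = 1, D < 0", {
  p <- worked_panel()
  self <- pairwise_ld(p, 1, 1)
  expect_equal(self$r2, 1)
  expect_equal(self$d_prime, 1)

  alleles <- cbind(c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L))
  vt <- variant_table(c("chr1", "chr1"), c(10L, 20L), c("a", "b"),
                     c("A", "A"), c("T", "T"))
  pc <- haplotype_panel(vt, alleles, c("s1", "s2"),
                        hap_sample = rep(1:2, each = 2L))
  comp <- pairwise_ld(pc, 1, 2)
  expect_equal(comp$r2, 1)
  expect_equal(comp$d, -0.25)
})

test_that("r2 equals squared Pearson correlation on random panels", {
  for (seed in 1:25) {
    p <- random_panel(2L * sample(10:60, 1), 6L, seed = seed)
    for (pair in list(c(1, 2), c(3, 6), c(2, 5))) {
      ld <- pairwise_ld(p, pair[1], pair[2])
      expect_equal(ld$r2,
                   r2_pearson(p$alleles[, pair[1]], p$alleles[, pair[2]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("r2 is invariant to swapping ref/alt labels at either site", {
  p <- random_panel(60L, 4L, seed = 3)
  base <- pairwise_ld(p, 1, 2)$r2
  p_flip <- p
  p_flip$alleles[, 1] <- 1L - p_flip$alleles[, 1]
  expect_equal(pairwise_ld(p_flip, 1, 2)$r2, base, tolerance = 1e-12)
  p_flip$alleles[, 2] <- 1L - p_flip$alleles[, 2]
  expect_equal(pairwise_ld(p_flip, 1, 2)$r2, base, tolerance = 1e-12)
})

test_that("0 <= r2 <= D' <= 1 for all biallelic pairs", {
  for (seed in 26:40) {
    p <- random_panel(40L, 5L, seed = seed)
    for (b in 2:5) {
      ld <- pairwise_ld(p, 1, b)
      expect_gte(ld$r2, 0)
      expect_lte(ld$r2, ld$d_prime + 1e-12)
      expect_lte(ld$d_prime, 1 + 1e-12)
    }
  }
})

test_that("monomorphic columns give an 'undefined LD' error naming the column", {
  p <- worked_panel()
  p$alleles[, 2] <- 1L
  expect_error(pairwise_ld(p, 1, 2), "monomorphic")
  expect_error(pairwise_ld(p, 1, 2), "rsB")
})

test_that("ld_expand applies a strict threshold and reports the index first", {
  p <- random_panel(400L, 8L, seed = 5)
  out <- ld_expand(p, "rs001", r2_threshold = 0)
  expect_true(out$is_index[1])
  expect_equal(out$r2[1], 1)
  expect_true(all(diff(out$r2[-1]) <= 1e-12))
  ## strict ">" at threshold 1.0 excludes even the index's self-r2 of 1
  empty <- ld_expand(p, "rs001", r2_threshold = 1.0)
  expect_equal(nrow(empty), 0L)
})

test_that("ld_expand respects the physical window and missing index errors", {
  p <- random_panel(100L, 6L, seed = 9)
  ## variants are 100 bp apart; window of 150 keeps only direct neighbors
  out <- ld_expand(p, "rs003", r2_threshold = 0, window_bp = 150)
  expect_true(all(abs(out$pos - p$variants$pos[3]) <= 150))
  expect_error(ld_expand(p, "rs999"), "nearest")
})

test_that("planted causal SNP enters the LD set; decoys at low r2 are excluded", {
  hits <- 0L
  for (seed in 1:20) {
    study_panel <- simulate_panel(sim_config(seed = seed))
    out <- ld_expand(study_panel$panel, study_panel$truth$index_rsid)
    if (study_panel$truth$causal_rsid %in% out$proxy_rsid) hits <- hits + 1L
  }
  expect_gte(hits, 19L)

  ## index and causal in perfect LD, all decoys near r2 = 0
  set.seed(77)
  n <- 400L
  idx <- rbinom(n, 1L, 0.5)
  decoys <- matrix(rbinom(n * 3L, 1L, 0.5), ncol = 3L)
  alleles <- cbind(idx, decoys[, 1], idx, decoys[, 2:3])
  vt <- variant_table(rep("chr5", 5), 100L * (1:5), sprintf("rs%d", 1:5),
                     rep("A", 5), rep("G", 5))
  p <- haplotype_panel(vt, alleles, sprintf("s%d", seq_len(n / 2)),
                       hap_sample = rep(seq_len(n / 2), each = 2L))
  out <- ld_expand(p, "rs1", r2_threshold = 0.8)
  expect_setequal(out$proxy_rsid, c("rs1", "rs3"))
})
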