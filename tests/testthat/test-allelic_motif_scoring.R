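test_that("log-odds weights follow the stated smoothing arithmetic", {
  m <- motif_model("m", rbind(c(1, 0, 0, 0), c(0.25, 0.25, 0.25, 0.25)),
                   pseudocount = 0.1)
  w <- pfm_to_logodds(m)
  expect_equal(unname(w[1, "A"]), log2((1.025 / 1.1) / 0.25),
               tolerance = 1e-12)
  expect_equal(unname(w[1, c("C", "G", "T")]),
               rep(log2((0.025 / 1.1) / 0.25), 3), tolerance = 1e-12)
  ## doubling a background base drops its weights by exactly one bit
  m2 <- motif_model("m", m$pfm, pseudocount = 0.1,
                    background = c(0.5, 0.25, 0.125, 0.125))
  expect_equal(pfm_to_logodds(m2)[, "A"], w[, "A"] - 1, tolerance = 1e-12)
})

test_that("energy matrix is mean-centered with favorable bases negative", {
  m <- motif_model("m", rbind(c(0.85, 0.05, 0.05, 0.05),
                              c(0.25, 0.25, 0.25, 0.25)))
  e <- pfm_to_energy(m)$energies
  expect_equal(rowSums(e), c(0, 0), tolerance = 1e-9)
  expect_lt(e[1, "A"], 0)
  expect_true(all(e[1, c("C", "G", "T")] > 0))
  expect_equal(unname(e[2, ]), rep(0, 4), tolerance = 1e-12)
  ## most-preferred base has the minimum energy in every column
  set.seed(1)
  pfm <- matrix(stats::runif(20), ncol = 4); pfm <- pfm / rowSums(pfm)
  e2 <- pfm_to_energy(motif_model("r", pfm))$energies
  expect_identical(apply(e2, 1, which.min), apply(pfm, 1, which.max))
  ## logo heights are the negated energies
  logo <- energy_logo_table(m)
  expect_equal(logo$height, -logo$energy)
})

test_that("uniform motif scores both alleles at zero", {
  m <- motif_model("u", matrix(0.25, 4, 4))
  v <- variant_table("chrX", 50L, "rs1", "T", "C")
  sc <- score_alleles(v, "AAATAAA", 4L, m)
  expect_equal(sc$score_ref, 0, tolerance = 1e-12)
  expect_equal(sc$score_alt, 0, tolerance = 1e-12)
  expect_equal(sc$delta, 0, tolerance = 1e-12)
})

test_that("best placement equals exhaustive enumeration on small motifs", {
  set.seed(2)
  v <- variant_table("chrX", 50L, "rs1", "A", "G")
  for (rep in 1:20) {
    pfm <- matrix(stats::runif(8), ncol = 4); pfm <- pfm / rowSums(pfm)
    m <- motif_model("m2", pfm)                 # L = 2 motif
    ctx <- c(sample(c("A", "C", "G", "T"), 3, replace = TRUE), "A",
             sample(c("A", "C", "G", "T"), 2, replace = TRUE))
    sc <- score_alleles(v, paste(ctx, collapse = ""), 4L, m)
    chars_ref <- ctx
    chars_alt <- ctx; chars_alt[4] <- "G"
    expect_equal(sc$score_ref, brute_best_score(chars_ref, 4L, pfm),
                 tolerance = 1e-12)
    expect_equal(sc$score_alt, brute_best_score(chars_alt, 4L, pfm),
                 tolerance = 1e-12)
  }
})

test_that("scores are invariant under reverse-complementing the context", {
  set.seed(3)
  pfm <- matrix(stats::runif(24), ncol = 4); pfm <- pfm / rowSums(pfm)
  m <- motif_model("m6", pfm)
  v <- variant_table("chrX", 50L, "rs1", "C", "T")
  ctx <- c("G", "A", "T", "T", "A", "C", "C", "G", "A", "C", "A")
  ctx[6] <- "C"
  fwd <- score_alleles(v, paste(ctx, collapse = ""), 6L, m)
  rc_map <- c(A = "T", C = "G", G = "C", T = "A")
  ctx_rc <- rev(unname(rc_map[ctx]))
  ## on the reverse strand the alleles read as their complements
  v_rc <- variant_table("chrX", 50L, "rs1", "G", "A")
  rev_ <- score_alleles(v_rc, paste(ctx_rc, collapse = ""),
                        length(ctx) - 6L + 1L, m)
  expect_equal(rev_$score_ref, fwd$score_ref, tolerance = 1e-12)
  expect_equal(rev_$score_alt, fwd$score_alt, tolerance = 1e-12)
})

test_that("delta is antisymmetric under swapping ref and alt", {
  set.seed(4)
  pfm <- matrix(stats::runif(16), ncol = 4); pfm <- pfm / rowSums(pfm)
  m <- motif_model("m4", pfm)
  a <- variant_table("chrX", 50L, "rs1", "A", "T")
  b <- variant_table("chrX", 50L, "rs1", "T", "A")
  ctx_a <- "CCGATGG"   # base 4 = A matches a's ref
  ctx_b <- "CCGTTGG"   # base 4 = T matches b's ref
  expect_equal(score_alleles(a, ctx_a, 4L, m)$delta,
               -score_alleles(b, ctx_b, 4L, m)$delta, tolerance = 1e-12)
})

test_that("log-odds and energy parameterizations agree in rank", {
  set.seed(5)
  pfm <- matrix(stats::runif(20), ncol = 4); pfm <- pfm / rowSums(pfm)
  m <- motif_model("m5", pfm)
  w <- pfm_to_logodds(m)
  e <- pfm_to_energy(m)$energies
  windows <- replicate(30, sample(c("A", "C", "G", "T"), 5, replace = TRUE),
                       simplify = FALSE)
  scores <- vapply(windows, function(win) {
    idx <- match(win, c("A", "C", "G", "T"))
    sum(w[cbind(1:5, idx)])
  }, numeric(1))
  energies <- vapply(windows, function(win) {
    idx <- match(win, c("A", "C", "G", "T"))
    sum(e[cbind(1:5, idx)])
  }, numeric(1))
  expect_equal(order(scores), order(-energies))
})

test_that("risk C allele scores below the non-risk T on the printed probe", {
  ## site-consistent motif whose SNP-position column prefers T over C,
  ## scanned on the printed probe context (SNP at position 20): flanking
  ## columns follow the probe so the best placement keeps the SNP under the
  ## discriminating column
  probe_chars <- strsplit(probe_T, "")[[1]]
  pfm <- rbind(c(0.10, 0.10, 0.10, 0.70),   # col 2 of window = SNP column
               c(0.05, 0.05, 0.05, 0.85),
               c(0.10, 0.10, 0.10, 0.70))
  win <- probe_chars[(probe_snp_index - 1L):(probe_snp_index + 1L)]
  for (j in c(1L, 3L)) {
    pfm[j, ] <- 0.1
    pfm[j, match(win[j], c("A", "C", "G", "T"))] <- 0.7
  }
  m <- motif_model("Tpref", pfm)
  v <- variant_table("chrX", 1000L, "rs_probe", "T", "C")
  sc <- score_alleles(v, probe_T, probe_snp_index, m)
  expect_lt(sc$delta, 0)
})

test_that("ambiguous bases skip placements; all-skipped errors", {
  m <- motif_model("m", matrix(0.25, 2, 4))
  v <- variant_table("chrX", 50L, "rs1", "A", "G")
  expect_error(score_alleles(v, "NAN", 2L, m), "skipped")
  ## context base must match the reference allele
  expect_error(score_alleles(v, "CCC", 2L, m), "does not match ref")
})

test_that("the ChIP gate suppresses flags without a matching factor peak", {
  cfg <- sim_config(seed = 11)
  sim <- simulate_panel(cfg)
  ann <- simulate_annotations(cfg, sim)
  v <- sim$panel$variants
  ci <- cfg$causal_index
  cand <- v[c(ci, ci + 2L), , drop = FALSE]
  class(cand) <- c("variant_table", "data.frame")
  ov <- annotate_overlaps(cand, ann$peaksets)
  gated <- differential_binding_scan(cand, ann$sequence, list(ann$motif),
                                     chip_gate = ov)
  expect_true(gated$predicted_differential[gated$rsid == v$rsid[ci]])
  expect_false(any(gated$predicted_differential[gated$rsid != v$rsid[ci]]))
  ## with a gate present but no tf_chip overlap anywhere, nothing is flagged
  no_tf <- ov; no_tf$tf_factors <- ""
  none <- differential_binding_scan(cand, ann$sequence, list(ann$motif),
                                    chip_gate = no_tf)
  expect_false(any(none$predicted_differential))
  ## delta_threshold = 0 flags every gate-passing pair with delta != 0
  all_ <- differential_binding_scan(cand, ann$sequence, list(ann$motif),
                                    chip_gate = NULL, delta_threshold = 0)
  expect_true(all(all_$predicted_differential[all_$delta != 0]))
})
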