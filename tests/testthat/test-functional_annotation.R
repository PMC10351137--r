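cand2 <- function() {
  variant_table(c("chrX", "chrX"), c(100L, 300L), c("rs1", "rs2"),
                c("T", "A"), c("C", "G"))
}

test_that("eQTL harmonization flips slope to the alt allele", {
  tab <- data.frame(variant_id = "chrX_100_T_C_b37", gene_id = "G",
                    tissue = "uterus", effect_allele = "T", slope = 2,
                    pval = 1e-5, stringsAsFactors = FALSE)
  ann <- annotate_eqtl(cand2(), tab, "G", "uterus")
  expect_equal(ann$slope_alt[1], -2)     # effect allele was ref: sign flip
  expect_equal(ann$direction_label[1], "alt_lower")
  expect_true(ann$has_eqtl[1])
  ## candidate absent from the table: null annotation, not an error
  expect_false(ann$has_eqtl[2])
  expect_true(is.na(ann$slope_alt[2]))
})

test_that("harmonization is an involution under effect-allele flip", {
  tab1 <- data.frame(variant_id = "chrX_100_T_C_b37", gene_id = "G",
                     tissue = "uterus", effect_allele = "C", slope = -1.3,
                     pval = 0.01, stringsAsFactors = FALSE)
  tab2 <- tab1
  tab2$effect_allele <- "T"; tab2$slope <- 1.3
  a1 <- annotate_eqtl(cand2(), tab1, "G", "uterus")
  a2 <- annotate_eqtl(cand2(), tab2, "G", "uterus")
  expect_equal(a1$slope_alt[1], a2$slope_alt[1])
})

test_that("mismatched effect allele is skipped with a warning", {
  tab <- data.frame(variant_id = "chrX_100_T_C_b37", gene_id = "G",
                    tissue = "uterus", effect_allele = "G", slope = 1,
                    pval = 0.01, stringsAsFactors = FALSE)
  expect_warning(ann <- annotate_eqtl(cand2(), tab, "G", "uterus"),
                 "neither candidate allele")
  expect_false(ann$has_eqtl[1])
})

test_that("tissue matching normalizes case, spaces and hyphens", {
  tab <- data.frame(variant_id = "chrX_100_T_C_b37", gene_id = "G",
                    tissue = "Adrenal Gland", effect_allele = "C",
                    slope = 1, pval = 0.01, stringsAsFactors = FALSE)
  ann <- annotate_eqtl(cand2(), tab, "G", "adrenal_gland")
  expect_true(ann$has_eqtl[1])
})

test_that("pvalue_max filters records out of the significant set", {
  tab <- data.frame(variant_id = "chrX_100_T_C_b37", gene_id = "G",
                    tissue = "uterus", effect_allele = "C", slope = 1,
                    pval = 0.2, stringsAsFactors = FALSE)
  expect_true(annotate_eqtl(cand2(), tab, "G", "uterus")$has_eqtl[1])
  expect_false(
    annotate_eqtl(cand2(), tab, "G", "uterus", pvalue_max = 0.05)$has_eqtl[1])
})

test_that("overlap counting honors the half-open convention", {
  v <- variant_table("chrX", 100L, "rs1", "A", "G")
  in_pk <- peak_set(data.frame(chrom = "chrX", start = 99L, end = 100L,
                               name = "a"), "d1", "histone")
  out_pk <- peak_set(data.frame(chrom = "chrX", start = 100L, end = 200L,
                                name = "b"), "d2", "histone")
  ov <- annotate_overlaps(v, list(in_pk, out_pk))
  expect_equal(ov$n_reg, 1L)
  expect_equal(ov$reg_datasets, "d1")
})

test_that("hits are partitioned by assay class with factors recorded", {
  v <- variant_table("chrX", 100L, "rs1", "A", "G")
  iv <- data.frame(chrom = "chrX", start = 90L, end = 110L, name = "pk")
  ps <- list(peak_set(iv, "tf1", "tf_chip", factor = "CEBPB"),
             peak_set(iv, "tf2", "tf_chip", factor = "HOXA10"),
             peak_set(iv, "h1", "histone"))
  ov <- annotate_overlaps(v, ps)
  expect_equal(ov$n_tf, 2L)
  expect_equal(ov$n_reg, 1L)
  expect_setequal(strsplit(ov$tf_factors, ";")[[1]], c("CEBPB", "HOXA10"))
})

test_that("chromosome aliasing 'X' vs 'chrX' is normalized; others miss", {
  v <- variant_table("chrX", 100L, "rs1", "A", "G")
  ps_alias <- peak_set(data.frame(chrom = "X", start = 90L, end = 110L,
                                  name = "pk"), "d", "histone")
  ps_other <- peak_set(data.frame(chrom = "chr7", start = 90L, end = 110L,
                                  name = "pk"), "d2", "histone")
  ov <- annotate_overlaps(v, list(ps_alias, ps_other))
  expect_equal(ov$n_reg, 1L)
})

test_that("overlap summary equals a brute-force membership oracle", {
  set.seed(12)
  for (rep in 1:10) {
    n_iv <- 15L
    start <- sample(0:400, n_iv)
    end <- start + sample(1:30, n_iv, replace = TRUE)
    iv <- data.frame(chrom = "chr2", start = start, end = end,
                     name = sprintf("p%d", seq_len(n_iv)))
    ps <- peak_set(iv, "ds", "histone")
    pos <- sample(1:420, 5L)
    v <- variant_table(rep("chr2", 5), pos, sprintf("rs%d", 1:5),
                       rep("A", 5), rep("G", 5))
    ov <- annotate_overlaps(v, list(ps))
    brute <- vapply(pos, function(p)
      sum(overlap_bruteforce(p, iv$start, iv$end)) > 0, logical(1))
    expect_identical(ov$n_reg > 0L, brute)
  }
})
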