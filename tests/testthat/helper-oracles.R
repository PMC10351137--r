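## Independent oracles and small random fixtures shared across tests.
## Each oracle is written from the definition, not from the implementation
## it checks.

## random phased panel with guaranteed-polymorphic columns
random_panel <- function(n_hap, n_snps, seed) {
  set.seed(seed)
  repeat {
    alleles <- matrix(rbinom(n_hap * n_snps, 1L, runif(1, 0.2, 0.8)),
                      nrow = n_hap)
    p <- colMeans(alleles)
    if (all(p > 0 & p < 1)) break
  }
  ref <- sample(c("A", "C", "G", "T"), n_snps, replace = TRUE)
  alt <- vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  vt <- variant_table(rep("chrX", n_snps),
                      1000L + seq_len(n_snps) * 100L,
                      sprintf("rs%03d", seq_len(n_snps)), ref, alt)
  haplotype_panel(vt, alleles,
                  sample_ids = sprintf("s%d", seq_len(n_hap %/% 2L)),
                  hap_sample = rep(seq_len(n_hap %/% 2L), each = 2L))
}

## squared Pearson correlation of the 0/1 columns: the r2 oracle
r2_pearson <- function(x, y) unname(stats::cor(x, y)^2)

## brute-force per-base overlap: is 1-based pos covered by [s, e)?
overlap_bruteforce <- function(pos, start, end) {
  vapply(seq_along(start), function(i)
    any((start[i]:(end[i] - 1L)) == pos - 1L), logical(1))
}

## exhaustive best-placement allele score, written from the scan definition:
## max log-odds over all L placements covering the SNP, both strands
revcomp_chr <- function(b) rev(c(A = "T", C = "G", G = "C", T = "A")[b])
brute_best_score <- function(chars, snp_i, pfm, pc = 0.1,
                             bg = rep(0.25, 4)) {
  L <- nrow(pfm)
  sp <- (pfm + pc / 4) / (1 + pc)
  w <- log2(sweep(sp, 2, bg, "/"))
  best <- -Inf
  for (start in seq_len(length(chars) - L + 1L)) {
    if (snp_i < start || snp_i > start + L - 1L) next
    win <- chars[start:(start + L - 1L)]
    for (ws in list(win, unname(revcomp_chr(win)))) {
      idx <- match(ws, c("A", "C", "G", "T"))
      if (anyNA(idx)) next
      best <- max(best, sum(w[cbind(seq_len(L), idx)]))
    }
  }
  best
}

## exhaustive upper-tail hypergeometric by enumeration of draw outcomes
hyper_uppertail_enum <- function(k, K, N, n) {
  js <- max(0L, n - (N - K)):min(K, n)
  js <- js[js >= k]
  if (length(js) == 0L) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

## closed-form pooled-variance two-sample t and two-sided p
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(-abs(t), na + nb - 2))
}

## EMSA probe contexts printed for the locus: 39 nt, SNP at position 20
probe_T <- "AACCCAAAAGCAAATGCAATAAAAACAAAGATAAATAGC"
probe_snp_index <- 20L
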