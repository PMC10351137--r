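## Haplotype-based linkage disequilibrium: r2 and D' from phased 0/1 columns.

#' Pairwise LD between two panel columns
#'
#' Computes haplotype-based D, r-squared and D-prime from the joint alt-alt
#' haplotype frequency: with pA, pB the alt-allele frequencies and pAB the
#' joint frequency, D = pAB - pA*pB, r2 = D^2 / (pA(1-pA)pB(1-pB)), and
#' D' = |D| / Dmax where Dmax = min(pA*pB, (1-pA)(1-pB)) for D < 0 and
#' min(pA(1-pB), (1-pA)pB) otherwise. Both columns must be polymorphic.
#'
#' @param panel a [haplotype_panel()].
#' @param a,b column indices (1-based) into the panel's variants.
#' @return a one-row data.frame: index_rsid, proxy_rsid, chrom, pos, r2,
#'   d_prime, n_hap, d.
#' @export
pairwise_ld <- function(panel, a, b) {
  x <- panel$alleles[, a]
  y <- panel$alleles[, b]
  n <- length(x)
  pA <- mean(x)
  pB <- mean(y)
  if (pA <= 0 || pA >= 1)
    stop(sprintf("undefined LD: column %d (%s) is monomorphic",
                 a, panel$variants$rsid[a]))
  if (pB <= 0 || pB >= 1)
    stop(sprintf("undefined LD: column %d (%s) is monomorphic",
                 b, panel$variants$rsid[b]))
  pAB <- mean(x == 1L & y == 1L)
  D <- pAB - pA * pB
  ## clamp: floating division can land a hair above the theoretical bound 1
  r2 <- min(1, D^2 / (pA * (1 - pA) * pB * (1 - pB)))
  dmax <- if (D < 0) min(pA * pB, (1 - pA) * (1 - pB))
          else       min(pA * (1 - pB), (1 - pA) * pB)
  d_prime <- if (D == 0) 0 else min(1, abs(D) / dmax)
  data.frame(index_rsid = panel$variants$rsid[a],
             proxy_rsid = panel$variants$rsid[b],
             chrom = panel$variants$chrom[b],
             pos = panel$variants$pos[b],
             r2 = r2, d_prime = d_prime, n_hap = n, d = D,
             stringsAsFactors = FALSE)
}

#' LD proxy expansion around an index SNP
#'
#' Returns every variant within `window_bp` of the index whose r2 with the
#' index strictly exceeds `r2_threshold`, sorted by descending r2. The index
#' SNP itself (self-r2 = 1, flagged `is_index`) is listed first whenever 1
#' exceeds the threshold; at a threshold of 1.0 the strict inequality returns
#' an empty set. Monomorphic candidate columns are skipped with a warning
#' (their LD with the index is undefined).
#'
#' @param panel a [haplotype_panel()].
#' @param index_rsid rsid of the index SNP (must be present in the panel).
#' @param r2_threshold strict lower bound on r2 (default 0.8).
#' @param window_bp half-width of the physical window (default 1e6).
#' @return data.frame of LD records with an `is_index` logical column.
#' @export
ld_expand <- function(panel, index_rsid, r2_threshold = 0.8,
                      window_bp = 1e6) {
  v <- panel$variants
  ai <- which(v$rsid == index_rsid)
  if (length(ai) == 0L) {
    near <- v$rsid[order(adist(v$rsid, index_rsid))][seq_len(min(3, nrow(v)))]
    stop(sprintf("index SNP '%s' not in panel; nearest rsids: %s",
                 index_rsid, paste(near, collapse = ", ")))
  }
  ai <- ai[1]
  in_window <- v$chrom == v$chrom[ai] & abs(v$pos - v$pos[ai]) <= window_bp
  rows <- list()
  skipped <- character()
  for (bi in which(in_window)) {
    p <- mean(panel$alleles[, bi])
    if (p <= 0 || p >= 1) {
      skipped <- c(skipped, v$rsid[bi])
      next
    }
    rec <- pairwise_ld(panel, ai, bi)
    rec$is_index <- bi == ai
    rows[[length(rows) + 1L]] <- rec
  }
  if (length(skipped) > 0L)
    warning(sprintf("skipped %d monomorphic column(s): %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  out <- do.call(rbind, rows)
  out <- out[out$r2 > r2_threshold, , drop = FALSE]
  if (nrow(out) > 0L)
    out <- out[order(-out$is_index, -out$r2, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
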