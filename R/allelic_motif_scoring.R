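## Allele-dependent TF binding prediction: log-odds PWM scan of both alleles
## over every motif placement covering the SNP, on both strands, plus the
## relative binding free-energy (ddG) parameterization used for energy logos.

#' Smoothed position probabilities
#'
#' Frequencies are smoothed as (f + pc/4) / (1 + pc) with pc the total
#' pseudocount, guaranteeing strictly positive probabilities.
#' @keywords internal
.smoothed_pfm <- function(motif) {
  (motif$pfm + motif$pseudocount / 4) / (1 + motif$pseudocount)
}

#' Log-odds weight matrix from a PFM
#'
#' w(i, b) = log2( smoothed f(i, b) / background(b) ), in bits.
#'
#' @param motif a [motif_model()].
#' @return L x 4 numeric matrix (columns A,C,G,T).
#' @export
pfm_to_logodds <- function(motif) {
  sp <- .smoothed_pfm(motif)
  w <- log2(sweep(sp, 2, motif$background, "/"))
  colnames(w) <- BASES
  w
}

#' Relative binding free-energy matrix from a PFM
#'
#' With g(i, b) = ln of the smoothed frequency, the energy is
#' e(i, b) = -(g(i, b) - mean_b' g(i, b')), in RT units (dimensionless
#' multiples of gas constant x temperature). Rows are mean-centered;
#' preferred bases get negative (favorable) energies, so in an energy logo
#' they plot above the axis with height -e.
#'
#' @param motif a [motif_model()].
#' @return list of class `energy_matrix`: name, energies (L x 4),
#'   derivation = "from_pfm".
#' @export
pfm_to_energy <- function(motif) {
  g <- log(.smoothed_pfm(motif))
  e <- -(g - rowMeans(g))
  colnames(e) <- BASES
  structure(list(name = motif$name, energies = e, derivation = "from_pfm"),
            class = "energy_matrix")
}

#' Per-position letter heights for an energy logo
#'
#' Height = -energy: preferred bases are positive ("above the dashed line").
#'
#' @param motif a [motif_model()].
#' @return data.frame(position, base, height, energy).
#' @export
energy_logo_table <- function(motif) {
  e <- pfm_to_energy(motif)$energies
  data.frame(position = rep(seq_len(nrow(e)), each = 4L),
             base = rep(BASES, nrow(e)),
             height = -as.vector(t(e)),
             energy = as.vector(t(e)),
             stringsAsFactors = FALSE)
}

#' Reverse complement of a base vector
#' @keywords internal
.revcomp <- function(bases) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[bases]))
}

## score one window (character vector of length L) against a weight matrix;
## NA when the window contains an ambiguous base
.score_window <- function(window, w) {
  idx <- match(window, BASES)
  if (anyNA(idx)) return(NA_real_)
  sum(w[cbind(seq_along(idx), idx)])
}

.best_placement <- function(chars, snp_i, w, e, L) {
  best <- list(score = -Inf, offset = NA_integer_, strand = NA_character_,
               energy = NA_real_)
  n_valid <- 0L
  for (off in seq_len(L)) {           # motif column occupied by the SNP
    s <- snp_i - off + 1L
    if (s < 1L || s + L - 1L > length(chars)) next
    win <- chars[s:(s + L - 1L)]
    for (strand in c("+", "-")) {
      win_s <- if (strand == "+") win else .revcomp(win)
      sc <- .score_window(win_s, w)
      if (is.na(sc)) next
      n_valid <- n_valid + 1L
      ## ties broken by (smaller offset, + strand first): strict > keeps the
      ## earlier candidate, and the loop visits offsets ascending, + before -
      if (sc > best$score) {
        idx <- match(win_s, BASES)
        best <- list(score = sc, offset = off, strand = strand,
                     energy = sum(e[cbind(seq_along(idx), idx)]))
      }
    }
  }
  best$n_valid <- n_valid
  best
}

#' Score both alleles of a SNP against a motif
#'
#' For each allele, substitutes the base at the SNP, evaluates the log-odds
#' score at every placement of the motif window that covers the SNP (L
#' placements) on both strands, and takes the maximum. Energies (RT units)
#' are reported at each allele's best placement; delta = score_alt -
#' score_ref. Placements containing an ambiguous base are skipped; if all
#' placements are skipped the call errors.
#'
#' @param variant one-row [variant_table()] (or list with ref/alt/rsid).
#' @param context_seq character scalar: sequence surrounding the SNP,
#'   covering at least L-1 bases on each side.
#' @param snp_index 1-based index of the SNP base within `context_seq`; the
#'   context base there must equal the ref allele.
#' @param motif a [motif_model()].
#' @return one-row data.frame: rsid, motif, score_ref, score_alt, delta,
#'   energy_ref, energy_alt, best_offset_ref, best_strand_ref,
#'   best_offset_alt, best_strand_alt.
#' @export
score_alleles <- function(variant, context_seq, snp_index, motif) {
  chars <- strsplit(toupper(context_seq), "")[[1]]
  L <- nrow(motif$pfm)
  if (snp_index < 1L || snp_index > length(chars))
    stop("snp_index outside context sequence")
  if (chars[snp_index] != variant$ref)
    stop(sprintf("context base '%s' at SNP does not match ref allele '%s'",
                 chars[snp_index], variant$ref))
  w <- pfm_to_logodds(motif)
  e <- pfm_to_energy(motif)$energies

  score_one <- function(base) {
    ch <- chars; ch[snp_index] <- base
    .best_placement(ch, snp_index, w, e, L)
  }
  br <- score_one(variant$ref)
  ba <- score_one(variant$alt)
  if (br$n_valid == 0L || ba$n_valid == 0L)
    stop("all motif placements skipped (ambiguous bases or short context)")
  data.frame(rsid = variant$rsid, motif = motif$name,
             score_ref = br$score, score_alt = ba$score,
             delta = ba$score - br$score,
             energy_ref = br$energy, energy_alt = ba$energy,
             best_offset_ref = br$offset, best_strand_ref = br$strand,
             best_offset_alt = ba$offset, best_strand_alt = ba$strand,
             stringsAsFactors = FALSE)
}

#' Extract a SNP-centered context window from a region sequence
#'
#' @param sequence list(chrom, start, seq) with `start` the 0-based offset
#'   of the sequence.
#' @param variant one-row [variant_table()].
#' @param flank bases on each side of the SNP (>= motif length - 1).
#' @return list(seq, snp_index).
#' @export
sequence_context <- function(sequence, variant, flank) {
  pos0 <- variant$pos - 1L
  i <- pos0 - sequence$start + 1L    # 1-based index into seq
  lo <- max(1L, i - flank); hi <- min(nchar(sequence$seq), i + flank)
  if (i < 1L || i > nchar(sequence$seq))
    stop("variant lies outside the supplied sequence")
  list(seq = substr(sequence$seq, lo, hi), snp_index = i - lo + 1L)
}

#' Scan candidates against a motif library for differential binding
#'
#' Scores every (candidate, motif) pair; a pair is flagged
#' `predicted_differential` when |delta| >= `delta_threshold` and, with the
#' ChIP gate on, the candidate overlaps a TF ChIP-seq peak set whose factor
#' matches the motif name. The gate encodes the requirement that a predicted
#' binding change be supported by observed binding of that factor at the
#' site.
#'
#' @param candidates a [variant_table()].
#' @param sequence region sequence (list(chrom, start, seq)).
#' @param motif_library list of [motif_model()] objects (non-empty).
#' @param chip_gate NULL (gate off) or the [annotate_overlaps()] result for
#'   the same candidates.
#' @param delta_threshold |delta| cutoff in bits (default 2.0).
#' @return data.frame of per-pair [score_alleles()] rows plus
#'   `gate_passed` and `predicted_differential`.
#' @export
differential_binding_scan <- function(candidates, sequence, motif_library,
                                      chip_gate = NULL,
                                      delta_threshold = 2.0) {
  if (length(motif_library) == 0L) stop("motif library is empty")
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, , drop = FALSE]
    for (motif in motif_library) {
      L <- nrow(motif$pfm)
      ctx <- tryCatch(sequence_context(sequence, cand, L - 1L),
                      error = function(e) NULL)
      if (is.null(ctx) || nchar(ctx$seq) < L) next
      sc <- score_alleles(cand, ctx$seq, ctx$snp_index, motif)
      gate_passed <- TRUE
      if (!is.null(chip_gate)) {
        g <- chip_gate[chip_gate$rsid == cand$rsid, , drop = FALSE]
        facs <- if (nrow(g) > 0L && nzchar(g$tf_factors[1]))
          strsplit(g$tf_factors[1], ";")[[1]] else character()
        gate_passed <- motif$name %in% facs
      }
      sc$gate_passed <- gate_passed
      sc$predicted_differential <-
        gate_passed && abs(sc$delta) >= delta_threshold
      rows[[length(rows) + 1L]] <- sc
    }
  }
  if (length(rows) == 0L)
    return(data.frame(rsid = character(), motif = character(),
                      score_ref = numeric(), score_alt = numeric(),
                      delta = numeric(), gate_passed = logical(),
                      predicted_differential = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
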