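## Evidence cascade: LD set -> eQTL -> peak overlap -> motif disruption,
## then a fully keyed deterministic ranking.

#' Assemble per-candidate evidence records
#'
#' Joins the LD expansion, eQTL annotation, overlap summary and motif scan
#' into one row per candidate.
#'
#' @param ld data.frame from [ld_expand()].
#' @param eqtl_ann data.frame from [annotate_eqtl()].
#' @param overlaps data.frame from [annotate_overlaps()].
#' @param motif_scan data.frame from [differential_binding_scan()].
#' @return data.frame of candidate records (one row per candidate).
#' @export
candidate_records <- function(ld, eqtl_ann, overlaps, motif_scan) {
  rec <- data.frame(rsid = ld$proxy_rsid, chrom = ld$chrom, pos = ld$pos,
                    r2_with_index = ld$r2, is_index = ld$is_index,
                    stringsAsFactors = FALSE)
  rec <- merge(rec, eqtl_ann[, c("rsid", "slope_alt", "pvalue",
                                 "direction_label", "has_eqtl")],
               by = "rsid", all.x = TRUE, sort = FALSE)
  rec$has_eqtl[is.na(rec$has_eqtl)] <- FALSE
  rec <- merge(rec, overlaps[, c("rsid", "n_tf", "n_reg", "tf_factors")],
               by = "rsid", all.x = TRUE, sort = FALSE)
  rec$n_tf[is.na(rec$n_tf)] <- 0L
  rec$n_reg[is.na(rec$n_reg)] <- 0L
  flags <- motif_scan[motif_scan$predicted_differential, , drop = FALSE]
  rec$n_motif_flags <- vapply(rec$rsid, function(r)
    sum(flags$rsid == r), integer(1))
  rec$flagged_motifs <- vapply(rec$rsid, function(r)
    paste(flags$motif[flags$rsid == r], collapse = ";"), character(1))
  abs_d <- vapply(rec$rsid, function(r) {
    d <- motif_scan$delta[motif_scan$rsid == r & motif_scan$gate_passed]
    if (length(d) == 0L) 0 else max(abs(d))
  }, numeric(1))
  rec$max_abs_delta <- abs_d
  rec
}

#' Assign evidence tiers (monotone cascade)
#'
#' Tier 1: in the LD set. Tier 2: tier 1 and a significant eQTL for the
#' target gene/tissue. Tier 3: tier 2 and at least one regulatory-region
#' peak and one TF ChIP-seq peak. Tier 4: tier 3 and at least one flagged
#' allele-dependent motif. Each tier requires the previous one, so removing
#' an evidence layer can never raise a tier.
#'
#' @param records data.frame from [candidate_records()].
#' @return records with a `tier` integer column (1-4).
#' @export
assign_tiers <- function(records) {
  t2 <- records$has_eqtl
  t3 <- t2 & records$n_reg >= 1L & records$n_tf >= 1L
  t4 <- t3 & records$n_motif_flags >= 1L
  records$tier <- 1L + t2 + t3 + t4
  records
}

#' Rank candidates
#'
#' Deterministic total order on the sort key (tier desc, max |delta| desc,
#' n_tf desc, r2 desc, pos asc). A composite score,
#' tier + 0.5 * tanh(max|delta| / 4), is reported for transparency; ranking
#' uses the full key, not the score.
#'
#' @param records data.frame from [assign_tiers()].
#' @return records ordered best-first with `rank` and `composite_score`.
#' @export
rank_candidates <- function(records) {
  stopifnot("tier" %in% names(records))
  o <- order(-records$tier, -records$max_abs_delta, -records$n_tf,
             -records$r2_with_index, records$pos)
  out <- records[o, , drop = FALSE]
  out$composite_score <- out$tier + 0.5 * tanh(out$max_abs_delta / 4)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Run the full prioritization cascade on a simulated or assembled study
#'
#' LD expansion around the index SNP, eQTL and peak annotation of the
#' resulting candidates, the gated differential-binding scan, tier
#' assignment and ranking.
#'
#' @param study list as returned by [simulate_study()] (or assembled from
#'   files: panel, peaksets, eqtl, motif(s), sequence, plus gene/tissue in
#'   `cfg`).
#' @param index_rsid index SNP rsid; defaults to the study truth record.
#' @param r2_threshold LD cutoff (strict; default 0.8).
#' @param delta_threshold motif |delta| cutoff in bits (default 2.0).
#' @param gate apply the TF ChIP gate to motif flags (default TRUE).
#' @return list: ranked (data.frame), ld, eqtl_ann, overlaps, motif_scan,
#'   parameters.
#' @export
run_pipeline <- function(study, index_rsid = study$truth$index_rsid,
                         r2_threshold = 0.8, delta_threshold = 2.0,
                         gate = TRUE) {
  ld <- ld_expand(study$panel, index_rsid, r2_threshold = r2_threshold)
  if (nrow(ld) == 0L)
    return(list(ranked = data.frame(), ld = ld,
                parameters = list(r2_threshold = r2_threshold)))
  v <- study$panel$variants
  cand <- v[match(ld$proxy_rsid, v$rsid), , drop = FALSE]
  class(cand) <- c("variant_table", "data.frame")
  eqtl_ann <- annotate_eqtl(cand, study$eqtl, study$cfg$gene,
                            study$cfg$tissue)
  overlaps <- annotate_overlaps(cand, study$peaksets)
  motifs <- if (inherits(study$motif, "motif_model")) list(study$motif)
            else study$motif
  scan <- differential_binding_scan(cand, study$sequence, motifs,
                                    chip_gate = if (gate) overlaps else NULL,
                                    delta_threshold = delta_threshold)
  rec <- candidate_records(ld, eqtl_ann, overlaps, scan)
  ranked <- rank_candidates(assign_tiers(rec))
  list(ranked = ranked, ld = ld, eqtl_ann = eqtl_ann, overlaps = overlaps,
       motif_scan = scan,
       parameters = list(index_rsid = index_rsid,
                         r2_threshold = r2_threshold,
                         delta_threshold = delta_threshold, gate = gate))
}
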