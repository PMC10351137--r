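## eQTL and epigenomic-peak annotation of LD-expanded candidates.

#' Annotate candidates with eQTL effects harmonized to the alt allele
#'
#' Matches candidates to eQTL records on (chrom, pos, ref, alt) for one
#' gene/tissue and re-orients each slope to the candidate's alternate
#' allele: slope_alt = slope if the record's effect allele is the alt
#' allele, else -slope. Candidates without a matching record receive a null
#' annotation (NA columns) so they fail the eQTL tier rather than the
#' pipeline. Records whose effect allele matches neither candidate allele
#' are skipped with a warning (possible strand or allele mismatch).
#'
#' @param candidates a [variant_table()] (or data.frame with chrom, pos,
#'   rsid, ref, alt).
#' @param eqtl_table data.frame from [read_eqtl()].
#' @param gene,tissue labels to select from the table; tissue matching is
#'   exact on a lowercased, underscored normalization.
#' @param pvalue_max records with pval above this are treated as absent
#'   (default 1.0: keep everything the table calls significant).
#' @return data.frame: rsid, gene, tissue, slope_alt, pvalue,
#'   direction_label ("alt_lower"/"alt_higher"), has_eqtl.
#' @export
annotate_eqtl <- function(candidates, eqtl_table, gene, tissue,
                          pvalue_max = 1.0) {
  norm_tissue <- function(x) gsub("[ -]+", "_", tolower(x))
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(eqtl_table))) {
    parts <- strsplit(eqtl_table$variant_id, "_")
    eqtl_table$chrom <- vapply(parts, `[`, character(1), 1)
    eqtl_table$pos <- as.integer(vapply(parts, `[`, character(1), 2))
    eqtl_table$ref <- toupper(vapply(parts, `[`, character(1), 3))
    eqtl_table$alt <- toupper(vapply(parts, `[`, character(1), 4))
  }
  tab <- eqtl_table[eqtl_table$gene_id == gene &
                      norm_tissue(eqtl_table$tissue) == norm_tissue(tissue) &
                      eqtl_table$pval <= pvalue_max, , drop = FALSE]
  out <- data.frame(rsid = candidates$rsid, gene = gene, tissue = tissue,
                    slope_alt = NA_real_, pvalue = NA_real_,
                    direction_label = NA_character_, has_eqtl = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) return(out)
  key_c <- paste(normalize_chrom(candidates$chrom), candidates$pos)
  key_t <- paste(normalize_chrom(tab$chrom), tab$pos)
  for (i in seq_len(nrow(candidates))) {
    j <- which(key_t == key_c[i])
    if (length(j) == 0L) next
    j <- j[1]
    ## allele harmonization: accept either orientation of ref/alt
    cr <- candidates$ref[i]; ca <- candidates$alt[i]
    if (!setequal(c(tab$ref[j], tab$alt[j]), c(cr, ca))) next
    ea <- toupper(tab$effect_allele[j])
    if (ea == ca) {
      slope_alt <- tab$slope[j]
    } else if (ea == cr) {
      slope_alt <- -tab$slope[j]
    } else {
      warning(sprintf(
        "eQTL record %s: effect allele %s matches neither candidate allele (%s/%s); skipped",
        tab$variant_id[j], ea, cr, ca))
      next
    }
    out$slope_alt[i] <- slope_alt
    out$pvalue[i] <- tab$pval[j]
    out$direction_label[i] <- if (slope_alt < 0) "alt_lower" else "alt_higher"
    out$has_eqtl[i] <- TRUE
  }
  out
}

#' Annotate candidates with peak overlaps
#'
#' A SNP at 1-based position p hits a half-open interval \[s, e) iff
#' s <= p-1 < e. Hits are partitioned by assay class: TF ChIP-seq datasets
#' (with their factor) versus regulatory datasets (histone marks and open
#' chromatin). Chromosome names are normalized ("X" vs "chrX") before
#' comparison; a chromosome absent from a peak set simply yields no hits.
#'
#' @param candidates a [variant_table()].
#' @param peaksets list of [peak_set()] objects.
#' @return data.frame: rsid, n_tf, n_reg, tf_datasets (";"-joined
#'   "dataset_id:factor"), tf_factors (";"-joined unique factors),
#'   reg_datasets (";"-joined ids).
#' @export
annotate_overlaps <- function(candidates, peaksets) {
  n <- nrow(candidates)
  tf_ds <- vector("list", n); reg_ds <- vector("list", n)
  tf_fac <- vector("list", n)
  cand_chrom <- normalize_chrom(candidates$chrom)
  for (ps in peaksets) {
    iv <- ps$intervals
    if (nrow(iv) == 0L) next
    iv_chrom <- normalize_chrom(iv$chrom)
    for (i in seq_len(n)) {
      same <- iv_chrom == cand_chrom[i]
      if (!any(same)) next
      hit <- any(point_in_intervals(candidates$pos[i],
                                    iv$start[same], iv$end[same]))
      if (!hit) next
      if (ps$assay_class == "tf_chip") {
        tf_ds[[i]] <- c(tf_ds[[i]], ps$dataset_id)
        tf_fac[[i]] <- c(tf_fac[[i]], ps$factor)
      } else {
        reg_ds[[i]] <- c(reg_ds[[i]], ps$dataset_id)
      }
    }
  }
  data.frame(
    rsid = candidates$rsid,
    n_tf = vapply(tf_ds, length, integer(1)),
    n_reg = vapply(reg_ds, length, integer(1)),
    tf_datasets = vapply(seq_len(n), function(i)
      paste(paste0(tf_ds[[i]], ":", tf_fac[[i]]), collapse = ";"),
      character(1)),
    tf_factors = vapply(tf_fac, function(x)
      paste(unique(x), collapse = ";"), character(1)),
    reg_datasets = vapply(reg_ds, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
}
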