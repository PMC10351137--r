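## Distance-normalized (observed/expected) contact analysis from a bait bin.

#' Construct a binned contact table
#'
#' Stores the upper triangle (bin_i <= bin_j) of a symmetric within-chromosome
#' contact matrix at a fixed bin size.
#'
#' @param chrom chromosome name.
#' @param bin_size bin width in bp.
#' @param entries data.frame(bin_i, bin_j, count) with bin_i <= bin_j,
#'   count >= 0, bin indices >= 0.
#' @return object of class `contact_table`.
#' @export
contact_table <- function(chrom, bin_size, entries) {
  stopifnot(all(c("bin_i", "bin_j", "count") %in% names(entries)))
  if (nrow(entries) == 0L) stop("contact table is empty")
  if (any(entries$bin_i > entries$bin_j))
    stop("entries must satisfy bin_i <= bin_j (upper triangle)")
  if (any(entries$count < 0)) stop("counts must be >= 0")
  if (any(entries$bin_i < 0)) stop("bin indices must be >= 0")
  structure(list(chrom = chrom, bin_size = bin_size, entries = entries),
            class = "contact_table")
}

#' Read a contacts TSV (chrom, bin_i, bin_j, count)
#' @param path TSV path.
#' @param bin_size bin width in bp of the table.
#' @return a [contact_table()].
#' @export
read_contacts <- function(path, bin_size) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  contact_table(df$chrom[1], bin_size,
                df[, c("bin_i", "bin_j", "count")])
}

#' Expected contact count by genomic distance
#'
#' The expected count at bin separation d is the mean count over all bin
#' pairs of the table's bin range at that separation (absent entries count
#' as zero). Separations with fewer than `min_pairs` pair slots are pooled
#' with their nearest smaller separation until the pooled slot count reaches
#' `min_pairs`, so the far-distance tail is not estimated from a handful of
#' pairs.
#'
#' @param table a [contact_table()].
#' @param min_pairs minimum pair slots per distance estimate (default 10).
#' @return data.frame(distance, expected, n_pairs) with one row per bin
#'   separation 0..max.
#' @export
expected_by_distance <- function(table, min_pairs = 10L) {
  e <- table$entries
  lo <- min(e$bin_i); hi <- max(e$bin_j)
  n_bins <- hi - lo + 1L
  d_max <- n_bins - 1L
  sums <- numeric(d_max + 1L)
  dd <- e$bin_j - e$bin_i
  agg <- tapply(e$count, dd, sum)
  sums[as.integer(names(agg)) + 1L] <- agg
  slots <- n_bins - 0:d_max

  ## pool distances (ascending) whose slot count is below min_pairs with the
  ## running pool; assign each pool its pooled mean
  expected <- numeric(d_max + 1L)
  pool_sum <- 0; pool_slots <- 0L; pool_members <- integer()
  flush <- function() {
    if (length(pool_members) > 0L)
      expected[pool_members] <<- pool_sum / pool_slots
  }
  for (d in 0:d_max) {
    pool_sum <- pool_sum + sums[d + 1L]
    pool_slots <- pool_slots + slots[d + 1L]
    pool_members <- c(pool_members, d + 1L)
    if (pool_slots >= min_pairs) {
      flush()
      pool_sum <- 0; pool_slots <- 0L; pool_members <- integer()
    }
  }
  if (length(pool_members) > 0L) {
    ## tail too small on its own: merge into the previous pooled estimate
    prev <- pool_members[1] - 1L
    if (prev >= 1L) {
      prev_val <- expected[prev]
      prev_members <- which(expected == prev_val &
                              seq_along(expected) < pool_members[1])
      prev_slots <- sum(slots[prev_members])
      pooled <- (prev_val * prev_slots + pool_sum) / (prev_slots + pool_slots)
      expected[c(prev_members, pool_members)] <- pooled
    } else {
      expected[pool_members] <- pool_sum / max(pool_slots, 1L)
    }
  }
  data.frame(distance = 0:d_max, expected = expected, n_pairs = slots)
}

#' Observed/expected bait profile (virtual 4C)
#'
#' For the bin containing `bait_position_bp`, computes
#' normalized(j) = observed(bait, j) / expected(|bait - j|) for every bin of
#' the table, reports the bins whose distance-normalized frequency reaches
#' `threshold`, and lists genes whose promoter (TSS +/- `promoter_window`)
#' falls in a reported bin.
#'
#' @param table a [contact_table()].
#' @param bait_position_bp 1-based bp position of the bait (e.g. the SNP).
#' @param tss_annotation data.frame(gene, chrom, tss_pos) with 1-based TSS.
#' @param threshold distance-normalized frequency cutoff (default 2.00).
#' @param promoter_window half-width of the promoter window in bp
#'   (default 2000).
#' @param min_pairs passed to [expected_by_distance()].
#' @return list of class `bait_profile`: bait_bin, profile (data.frame with
#'   bin, observed, expected, normalized), reported (subset with
#'   normalized >= threshold), promoter_hits (gene, bin, normalized).
#' @export
bait_query <- function(table, bait_position_bp, tss_annotation = NULL,
                       threshold = 2.00, promoter_window = 2000L,
                       min_pairs = 10L) {
  e <- table$entries
  lo <- min(e$bin_i); hi <- max(e$bin_j)
  bait_bin <- (bait_position_bp - 1L) %/% table$bin_size
  if (bait_bin < lo || bait_bin > hi)
    stop(sprintf("bait position %d maps to bin %d, outside table range [%d, %d]",
                 bait_position_bp, bait_bin, lo, hi))
  exp_d <- expected_by_distance(table, min_pairs = min_pairs)

  bins <- lo:hi
  obs <- numeric(length(bins))
  sel <- e$bin_i == bait_bin | e$bin_j == bait_bin
  be <- e[sel, , drop = FALSE]
  other <- ifelse(be$bin_i == bait_bin, be$bin_j, be$bin_i)
  obs[match(other, bins)] <- obs[match(other, bins)] + be$count
  ## diagonal entry counted once
  if (sum(obs) == 0) {
    warning("bait bin has zero marginal contacts; empty profile")
    return(structure(list(bait_bin = bait_bin,
                          profile = data.frame(bin = bins, observed = obs,
                                               expected = NA_real_,
                                               normalized = NA_real_),
                          reported = data.frame(), promoter_hits = data.frame()),
                     class = "bait_profile"))
  }
  expected <- exp_d$expected[abs(bins - bait_bin) + 1L]
  normalized <- ifelse(expected > 0, obs / expected, NA_real_)
  profile <- data.frame(bin = bins, observed = obs, expected = expected,
                        normalized = normalized)
  reported <- profile[!is.na(profile$normalized) &
                        profile$normalized >= threshold, , drop = FALSE]

  promoter_hits <- data.frame(gene = character(), bin = integer(),
                              normalized = numeric(), stringsAsFactors = FALSE)
  if (!is.null(tss_annotation) && nrow(reported) > 0L) {
    for (g in seq_len(nrow(tss_annotation))) {
      if (normalize_chrom(tss_annotation$chrom[g]) !=
          normalize_chrom(table$chrom)) next
      tss0 <- tss_annotation$tss_pos[g] - 1L
      b_lo <- (tss0 - promoter_window) %/% table$bin_size
      b_hi <- (tss0 + promoter_window) %/% table$bin_size
      hit <- reported[reported$bin >= b_lo & reported$bin <= b_hi, ,
                      drop = FALSE]
      if (nrow(hit) > 0L)
        promoter_hits <- rbind(promoter_hits, data.frame(
          gene = tss_annotation$gene[g], bin = hit$bin,
          normalized = hit$normalized, stringsAsFactors = FALSE))
    }
  }
  structure(list(bait_bin = bait_bin, profile = profile, reported = reported,
                 promoter_hits = promoter_hits),
            class = "bait_profile")
}

#' @export
print.bait_profile <- function(x, ...) {
  cat(sprintf("bait_profile: bait bin %d, %d bins, %d above threshold, %d promoter hit(s)\n",
              x$bait_bin, nrow(x$profile), nrow(x$reported),
              nrow(x$promoter_hits)))
  invisible(x)
}
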