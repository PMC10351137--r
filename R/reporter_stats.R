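## Dual-luciferase normalization and the allelic comparison.

#' Normalize reporter wells
#'
#' Per well, ratio = nano / firefly (controls transfection efficiency and
#' cell number); each ratio is then divided by the mean backbone ratio of
#' the same condition (controls baseline vector activity), so the backbone
#' construct normalizes to mean 1 within its condition.
#'
#' @param wells data.frame(construct, condition, replicate_id, nano,
#'   firefly) with strictly positive readings.
#' @param backbone label of the empty-backbone construct
#'   (default "backbone").
#' @return list of class `normalized_activity`: `wells` (input plus ratio
#'   and normalized columns) and `summary` (per construct x condition:
#'   n, mean, sd).
#' @export
normalize_wells <- function(wells, backbone = "backbone") {
  need <- c("construct", "condition", "replicate_id", "nano", "firefly")
  stopifnot(all(need %in% names(wells)))
  if (any(wells$nano <= 0) || any(wells$firefly <= 0))
    stop("nano and firefly readings must be strictly positive")
  wells$ratio <- wells$nano / wells$firefly
  wells$normalized <- NA_real_
  for (cond in unique(wells$condition)) {
    in_cond <- wells$condition == cond
    bb <- in_cond & wells$construct == backbone
    if (!any(bb))
      stop(sprintf("no '%s' wells in condition '%s'", backbone, cond))
    wells$normalized[in_cond] <- wells$ratio[in_cond] / mean(wells$ratio[bb])
  }
  summ <- do.call(rbind, lapply(
    split(wells, list(wells$construct, wells$condition), drop = TRUE),
    function(g) data.frame(construct = g$construct[1],
                           condition = g$condition[1],
                           n = nrow(g), mean = mean(g$normalized),
                           sd = stats::sd(g$normalized),
                           stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  structure(list(wells = wells, summary = summ),
            class = "normalized_activity")
}

#' Two-sample Student's t-test between allelic constructs
#'
#' Pooled-variance two-sided Student's t by default (Welch behind a flag).
#' Group 1 is conventionally the non-risk allele and group 2 the risk
#' allele, so a negative difference in means (group2 - group1 < 0) means
#' lower activity for the risk allele.
#'
#' @param norm_a,norm_b numeric vectors of normalized activities (>= 2
#'   values each, nonzero variance overall).
#' @param welch use Welch's unequal-variance t instead of pooled
#'   (default FALSE).
#' @return one-row data.frame: n_a, n_b, mean_a, mean_b, t, df, pvalue.
#' @export
allelic_test <- function(norm_a, norm_b, welch = FALSE) {
  if (length(norm_a) < 2L || length(norm_b) < 2L)
    stop("need >= 2 wells per group")
  if (stats::var(norm_a) + stats::var(norm_b) == 0)
    stop("zero pooled variance: degenerate input")
  tt <- stats::t.test(norm_a, norm_b, var.equal = !welch)
  data.frame(n_a = length(norm_a), n_b = length(norm_b),
             mean_a = mean(norm_a), mean_b = mean(norm_b),
             t = unname(tt$statistic), df = unname(tt$parameter),
             pvalue = tt$p.value)
}

#' Full reporter analysis for one condition
#'
#' Normalizes the well table and compares the two allelic constructs within
#' `condition`.
#'
#' @param wells raw well table (see [normalize_wells()]).
#' @param construct_a,construct_b labels of the non-risk and risk allele
#'   constructs.
#' @param condition condition to test within (default "decidualized").
#' @param welch passed to [allelic_test()].
#' @return list: normalized ([normalize_wells()] result), test (the
#'   [allelic_test()] row with construct labels and the activity ratio
#'   mean_b / mean_a).
#' @export
reporter_analysis <- function(wells, construct_a = "T_haplotype",
                              construct_b = "C_haplotype",
                              condition = "decidualized", welch = FALSE) {
  norm <- normalize_wells(wells)
  w <- norm$wells
  va <- w$normalized[w$construct == construct_a & w$condition == condition]
  vb <- w$normalized[w$construct == construct_b & w$condition == condition]
  if (length(va) == 0L || length(vb) == 0L)
    stop("allelic constructs not found in the requested condition")
  test <- allelic_test(va, vb, welch = welch)
  test$construct_a <- construct_a
  test$construct_b <- construct_b
  test$condition <- condition
  test$activity_ratio <- test$mean_b / test$mean_a
  list(normalized = norm, test = test)
}
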