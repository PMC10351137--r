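## Per-cluster expression frequency, enrichment fold and hypergeometric
## p-value for one gene in a clustered cell x gene count matrix.

#' Flag cells expressing a gene
#'
#' A cell expresses the gene iff its raw count is at least `min_count`
#' (presence/absence on raw counts; no normalization).
#'
#' @param counts genes x cells matrix (dense or Matrix sparse) with gene
#'   rownames.
#' @param gene gene identifier (must be a rowname).
#' @param min_count detection threshold (default 1).
#' @return named logical vector over cells.
#' @export
detect_expressing <- function(counts, gene, min_count = 1) {
  if (!gene %in% rownames(counts)) {
    near <- agrep(gene, rownames(counts), max.distance = 0.3, value = TRUE)
    stop(sprintf("gene '%s' not in matrix%s", gene,
                 if (length(near) > 0)
                   paste0("; near matches: ",
                          paste(utils::head(near, 5), collapse = ", "))
                 else ""))
  }
  x <- counts[gene, ]
  stats::setNames(as.numeric(x) >= min_count, colnames(counts))
}

#' Cluster expression enrichment
#'
#' frequency = expressing cells in the cluster / cluster size;
#' fold = frequency / overall frequency; p-value is the upper tail of the
#' hypergeometric distribution, P\[X >= k\] with population N = all cells,
#' K = all expressing cells, n = cluster size.
#'
#' @param expressing logical vector per cell (from [detect_expressing()]).
#' @param cluster_labels character vector of cluster labels, same order and
#'   length as `expressing`.
#' @param cluster target cluster label.
#' @return one-row data.frame: cluster, n_cells_cluster,
#'   n_expressing_cluster, frequency, overall_frequency, fold, pvalue.
#' @export
cluster_enrichment <- function(expressing, cluster_labels, cluster) {
  if (length(expressing) != length(cluster_labels))
    stop("labels must cover all cells")
  in_cl <- cluster_labels == cluster
  n <- sum(in_cl)
  if (n == 0L) stop(sprintf("cluster '%s' is empty", cluster))
  N <- length(expressing)
  K <- sum(expressing)
  k <- sum(expressing & in_cl)
  frequency <- k / n
  overall <- K / N
  fold <- if (overall > 0) frequency / overall else NA_real_
  pvalue <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(cluster = cluster, n_cells_cluster = n,
             n_expressing_cluster = k, frequency = frequency,
             overall_frequency = overall, fold = fold, pvalue = pvalue,
             stringsAsFactors = FALSE)
}

#' Enrichment across all clusters of a labelled matrix
#'
#' @param counts genes x cells matrix.
#' @param clusters data.frame(cell, cluster) covering every column.
#' @param gene gene identifier.
#' @param min_count detection threshold.
#' @return data.frame with one [cluster_enrichment()] row per cluster,
#'   sorted by ascending p-value.
#' @export
enrichment_by_cluster <- function(counts, clusters, gene, min_count = 1) {
  expr <- detect_expressing(counts, gene, min_count)
  labels <- clusters$cluster[match(colnames(counts), clusters$cell)]
  if (anyNA(labels)) stop("cluster labels must cover all cells")
  out <- do.call(rbind, lapply(unique(labels), function(cl)
    cluster_enrichment(expr, labels, cl)))
  out[order(out$pvalue), , drop = FALSE]
}
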