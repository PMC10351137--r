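## Seeded generators for every pipeline input, with a planted causal SNP.
## Haplotypes follow a founder-mosaic copying model; the causal column is a
## noisy copy of the index column with the flip probability solved so the
## expected haplotype r2 matches target_r2.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic study into one validated list.
#' Defaults describe the locus the pipeline is designed around: a ~120 kb
#' LD block on chromosome X, a target-gene TSS > 200 kb away, a 23,110-cell
#' uterine single-cell experiment with 8 clusters, and a dual-luciferase
#' plate with three experiments of three replicates.
#'
#' @param seed RNG seed (integer).
#' @param n_haplotypes number of haplotype rows (even; diploid females).
#' @param n_snps number of SNP columns.
#' @param founder_count founder haplotypes for the mosaic model.
#' @param switch_rate per-site founder-switch probability.
#' @param mutation_rate per-site allele-flip probability.
#' @param causal_index,index_index columns of the planted causal / GWAS
#'   index SNP; default to the middle of the grid, two sites apart.
#' @param target_r2 desired haplotype r2 between index and causal columns.
#' @param chrom,region_start,snp_spacing physical layout of the SNP grid.
#' @param motif_length planted motif width (>= 2).
#' @param planted_tf name of the TF whose motif and ChIP peaks are planted.
#' @param peak_halfwidth half-width (bp) of planted peaks.
#' @param decoy_peak_frac fraction of decoy SNPs covered by a decoy peak.
#' @param eqtl_slope_scale |slope| of the causal SNP's eQTL record; proxies
#'   scale with their r2 to the causal SNP.
#' @param gene,tissue labels used in the eQTL table and TSS annotation.
#' @param bin_size,n_bins,contact_scale,decay_tau,contact_noise_sd Hi-C
#'   contact-table geometry: counts decay as exp(-d/tau) in bin units with
#'   multiplicative lognormal noise.
#' @param loop_strength multiplier planted at the bait x promoter bin pair.
#' @param tss_offset_bp distance from the region start to the target TSS.
#' @param n_cells,n_genes,cluster_props single-cell matrix geometry.
#' @param planted_cluster name of the enriched cluster.
#' @param cluster_freq,background_freq probability that the target gene is
#'   detected (count > 0) inside / outside the planted cluster. The defaults
#'   (0.052 inside, 0.0094 outside, planted cluster 15% of cells) put the
#'   expected all-cell detection frequency at 0.0158, so the expected
#'   enrichment fold is 0.052 / 0.0158 = 3.3.
#' @param nb_dispersion negative-binomial dispersion of nonzero counts.
#' @param reporter_effect multiplicative activity of the risk-allele
#'   construct relative to the non-risk construct.
#' @param reporter_cv coefficient of variation of the reporter noise.
#' @param n_experiments,n_replicates reporter plate layout.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_haplotypes = 2000L, n_snps = 60L,
                       founder_count = 8L, switch_rate = 0.1,
                       mutation_rate = 0.01,
                       causal_index = NULL, index_index = NULL,
                       target_r2 = 0.9,
                       chrom = "chrX", region_start = 115000000L,
                       snp_spacing = 2000L,
                       motif_length = 8L, planted_tf = "CEBPB",
                       peak_halfwidth = 250L, decoy_peak_frac = 0.1,
                       eqtl_slope_scale = 0.5,
                       gene = "AGTR2", tissue = "uterus",
                       bin_size = 40000L, n_bins = 40L,
                       contact_scale = 100, decay_tau = 5,
                       contact_noise_sd = 0.1, loop_strength = 3,
                       tss_offset_bp = 360000L,
                       n_cells = 23110L, n_genes = 20L,
                       cluster_props = c(0.18, 0.28, 0.08, 0.07,
                                         0.06, 0.10, 0.15, 0.08),
                       planted_cluster = "Stromal-2",
                       cluster_freq = 0.052, background_freq = 0.0094,
                       nb_dispersion = 0.5,
                       reporter_effect = 0.5, reporter_cv = 0.15,
                       n_experiments = 3L, n_replicates = 3L) {
  cfg <- as.list(environment())
  ## planted columns default to the middle of the SNP grid (32/30 at the
  ## default 60 SNPs), two sites apart
  if (is.null(cfg$index_index)) cfg$index_index <- cfg$n_snps %/% 2L
  if (is.null(cfg$causal_index)) cfg$causal_index <- cfg$n_snps %/% 2L + 2L
  if (!(cfg$target_r2 > 0 && cfg$target_r2 <= 1))
    stop("target_r2 must lie in (0, 1]")
  if (!(cfg$background_freq >= 0 && cfg$background_freq < cfg$cluster_freq &&
        cfg$cluster_freq <= 1))
    stop("need 0 <= background_freq < cluster_freq <= 1")
  if (cfg$reporter_effect <= 0) stop("reporter_effect must be > 0")
  if (cfg$motif_length < 2) stop("motif_length must be >= 2")
  if (cfg$founder_count < 1) stop("founder_count must be >= 1")
  if (length(cfg$cluster_props) < 2) stop("need >= 2 clusters")
  if (cfg$n_replicates * cfg$n_experiments < 3)
    stop("need >= 3 wells per construct")
  if (cfg$causal_index > cfg$n_snps || cfg$index_index > cfg$n_snps)
    stop("causal_index / index_index out of range")
  class(cfg) <- "sim_config"
  cfg
}

snp_positions <- function(cfg) {
  cfg$region_start + (seq_len(cfg$n_snps) - 1L) * cfg$snp_spacing + 1L
}

## expected haplotype r2 between a 0/1 column with alt frequency p and its
## copy with per-row flip probability q
.expected_r2 <- function(p, q) {
  pY <- p * (1 - q) + (1 - p) * q
  p * (1 - p) * (1 - 2 * q)^2 / (pY * (1 - pY))
}

#' Simulate a phased haplotype panel with a planted causal SNP
#'
#' Haplotypes are mosaics of `founder_count` founder haplotypes: each row
#' copies its current founder's allele, switching founders with probability
#' `switch_rate` per site and flipping the copied allele with probability
#' `mutation_rate`. The causal column is then rebuilt from the index column
#' by flipping each haplotype's allele with the probability q that makes the
#' expected r2 equal `target_r2`; the realized r2 is recorded in the truth
#' record because it is stochastic.
#'
#' @param cfg a [sim_config()].
#' @return list(panel = [haplotype_panel()], truth = list(causal_index,
#'   index_index, causal_rsid, index_rsid, realized_r2, flip_prob,
#'   monomorphic_columns)).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_haplotypes; m <- cfg$n_snps; K <- cfg$founder_count
  founders <- matrix(rbinom(K * m, 1L, 0.5), nrow = K)
  f <- sample.int(K, n, replace = TRUE)
  alleles <- matrix(0L, nrow = n, ncol = m)
  for (s in seq_len(m)) {
    if (s > 1L) {
      sw <- runif(n) < cfg$switch_rate
      if (any(sw)) f[sw] <- sample.int(K, sum(sw), replace = TRUE)
    }
    a <- founders[cbind(f, s)]
    flip <- runif(n) < cfg$mutation_rate
    alleles[, s] <- ifelse(flip, 1L - a, a)
  }

  pos <- snp_positions(cfg)
  ref <- sample(BASES, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), character(1))
  rsid <- sprintf("rs%06d", seq_len(m))
  vt <- variant_table(rep(cfg$chrom, m), pos, rsid, ref, alt)

  mono <- which(colMeans(alleles) %in% c(0, 1))
  realized_r2 <- NA_real_; q <- NA_real_
  p <- mean(alleles[, cfg$index_index])
  if (p > 0 && p < 1) {
    target <- cfg$target_r2
    q <- if (target == 1) 0 else
      uniroot(function(qq) .expected_r2(p, qq) - target,
              c(0, 0.5 - 1e-9), tol = 1e-12)$root
    flips <- runif(n) < q
    causal <- ifelse(flips, 1L - alleles[, cfg$index_index],
                     alleles[, cfg$index_index])
    alleles[, cfg$causal_index] <- as.integer(causal)
    pc <- mean(causal)
    if (pc > 0 && pc < 1) {
      realized_r2 <- unname(cor(alleles[, cfg$index_index], causal)^2)
    } else {
      warning("planted causal column came out monomorphic; try another seed")
    }
    mono <- which(colMeans(alleles) %in% c(0, 1))
  } else {
    warning(sprintf(
      "index column %d is monomorphic: target_r2 unreachable; try another seed or frequency",
      cfg$index_index))
  }

  n_samples <- n %/% 2L
  if (2L * n_samples != n) stop("n_haplotypes must be even (diploid samples)")
  ids <- sprintf("S%04d", seq_len(n_samples))
  panel <- haplotype_panel(vt, alleles, ids,
                           hap_sample = rep(seq_len(n_samples), each = 2L),
                           sexes = rep("F", n_samples))
  truth <- list(causal_index = cfg$causal_index,
                index_index = cfg$index_index,
                causal_rsid = rsid[cfg$causal_index],
                index_rsid = rsid[cfg$index_index],
                realized_r2 = realized_r2, flip_prob = q,
                monomorphic_columns = mono)
  list(panel = panel, truth = truth)
}

#' Simulate annotation layers around a panel
#'
#' Writes the genomic context the annotation stages consume: a sequence over
#' the SNP region whose base at every SNP equals the reference allele; a
#' motif of length `motif_length` whose highest-information column sits on
#' the causal SNP with the reference (non-risk) base preferred (0.85) and the
#' risk base disfavored (0.05); one histone and two TF ChIP-seq peaks over
#' the causal SNP (plus decoy histone peaks over `decoy_peak_frac` of the
#' decoy SNPs); and a GTEx-style eQTL table in which each SNP's
#' alt-oriented slope is -eqtl_slope_scale * r2(SNP, causal) with a p-value
#' decreasing in r2.
#'
#' @param cfg a [sim_config()].
#' @param sim result of [simulate_panel()] (panel + truth).
#' @return list(peaksets, eqtl, motif, sequence = list(chrom, start, seq)).
#' @export
simulate_annotations <- function(cfg, sim) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  panel <- sim$panel
  v <- panel$variants
  ci <- cfg$causal_index
  L <- cfg$motif_length

  ## sequence covering the region with reference alleles planted
  margin <- L + 10L
  seq_start0 <- (min(v$pos) - 1L) - margin          # 0-based
  seq_end0 <- max(v$pos) + margin                   # exclusive
  seq_chars <- sample(BASES, seq_end0 - seq_start0, replace = TRUE)
  seq_chars[v$pos - 1L - seq_start0 + 1L] <- v$ref

  ## planted motif: SNP sits at column snp_col; flanking columns prefer the
  ## planted sequence so shifted placements score poorly
  snp_col <- (L %/% 2L) + 1L
  win_start0 <- (v$pos[ci] - 1L) - (snp_col - 1L)   # 0-based motif start
  pfm <- matrix(0.1, nrow = L, ncol = 4)
  for (j in seq_len(L)) {
    b <- seq_chars[win_start0 + j - 1L - seq_start0 + 1L]
    pfm[j, ] <- 0.1
    pfm[j, match(b, BASES)] <- 0.7
  }
  pfm[snp_col, ] <- 0.05
  pfm[snp_col, match(v$ref[ci], BASES)] <- 0.85
  motif <- motif_model(cfg$planted_tf, pfm)

  ## peaks: causal SNP inside one histone + two tf_chip peaks
  hw <- cfg$peak_halfwidth
  causal0 <- v$pos[ci] - 1L
  mk_iv <- function(center0, name)
    data.frame(chrom = cfg$chrom, start = center0 - hw, end = center0 + hw + 1L,
               name = name, stringsAsFactors = FALSE)
  peaksets <- list(
    peak_set(mk_iv(causal0, "h3k27ac_pk"), "H3K27ac_uterus", "histone",
             cell_type = "uterus"),
    peak_set(mk_iv(causal0, paste0(cfg$planted_tf, "_pk")),
             paste0(cfg$planted_tf, "_chip_1"), "tf_chip",
             factor = cfg$planted_tf, cell_type = "decidualized_hESF"),
    peak_set(mk_iv(causal0, "HOXA10_pk"), "HOXA10_chip_1", "tf_chip",
             factor = "HOXA10", cell_type = "decidualized_hESF"))
  decoys <- setdiff(seq_len(cfg$n_snps), c(ci, cfg$index_index))
  n_decoy_pk <- floor(cfg$decoy_peak_frac * length(decoys))
  if (n_decoy_pk > 0L) {
    covered <- sample(decoys, n_decoy_pk)
    iv <- do.call(rbind, lapply(covered, function(i)
      mk_iv(v$pos[i] - 1L, paste0("decoy_", v$rsid[i]))))
    peaksets[[length(peaksets) + 1L]] <-
      peak_set(iv, "H3K4me1_decoy", "histone", cell_type = "other")
  }

  ## eQTL table: alt-oriented slope tracks r2 with the causal column;
  ## effect_allele randomized to exercise harmonization
  ac <- panel$alleles[, ci]
  r2s <- vapply(seq_len(cfg$n_snps), function(i) {
    x <- panel$alleles[, i]
    if (length(unique(x)) < 2L || length(unique(ac)) < 2L) return(NA_real_)
    unname(cor(x, ac)^2)
  }, numeric(1))
  keep <- which(!is.na(r2s))
  ea_is_alt <- runif(length(keep)) < 0.5
  slope_alt <- -cfg$eqtl_slope_scale * r2s[keep]
  eqtl <- data.frame(
    variant_id = sprintf("%s_%d_%s_%s_b37", v$chrom[keep], v$pos[keep],
                         v$ref[keep], v$alt[keep]),
    gene_id = cfg$gene, tissue = cfg$tissue,
    effect_allele = ifelse(ea_is_alt, v$alt[keep], v$ref[keep]),
    slope = ifelse(ea_is_alt, slope_alt, -slope_alt),
    pval = pmin(1, 10^-(1 + 8 * r2s[keep])),
    stringsAsFactors = FALSE)

  list(peaksets = peaksets, eqtl = eqtl, motif = motif,
       sequence = list(chrom = cfg$chrom, start = seq_start0,
                       seq = paste(seq_chars, collapse = "")))
}

#' Simulate a binned chromatin contact table with a planted loop
#'
#' Counts follow an exponential distance decay,
#' C(i,j) = scale * exp(-|i-j| / tau) * lognormal noise, with the
#' bait-bin x promoter-bin entry multiplied by `loop_strength`. The TSS
#' annotation places the target gene's promoter in a bin `tss_offset_bp`
#' from the region start, plus one decoy gene with no loop.
#'
#' @param cfg a [sim_config()].
#' @return list(contacts = [contact_table()], tss = data.frame(gene, chrom,
#'   tss_pos), bait_pos, truth = list(bait_bin, promoter_bin)).
#' @export
simulate_contacts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$loop_strength <= 1) stop("loop_strength must be > 1")
  set.seed(cfg$seed + 2L)
  bait_pos <- snp_positions(cfg)[cfg$causal_index]
  bin0 <- (bait_pos - 1L) %/% cfg$bin_size - 5L   # window starts 5 bins left
  bins <- bin0 + seq_len(cfg$n_bins) - 1L
  bait_bin <- (bait_pos - 1L) %/% cfg$bin_size
  tss_pos <- cfg$region_start + cfg$tss_offset_bp
  promoter_bin <- (tss_pos - 1L) %/% cfg$bin_size
  if (!promoter_bin %in% bins || !bait_bin %in% bins)
    stop("bin window does not cover bait and promoter; increase n_bins")

  pairs <- which(upper.tri(diag(cfg$n_bins), diag = TRUE), arr.ind = TRUE)
  bi <- bins[pairs[, 1]]; bj <- bins[pairs[, 2]]
  d <- abs(bj - bi)
  sdlog <- cfg$contact_noise_sd
  noise <- rlnorm(length(d), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  count <- cfg$contact_scale * exp(-d / cfg$decay_tau) * noise
  is_loop <- (bi == min(bait_bin, promoter_bin)) &
             (bj == max(bait_bin, promoter_bin))
  count[is_loop] <- count[is_loop] * cfg$loop_strength
  contacts <- contact_table(cfg$chrom, cfg$bin_size,
                            data.frame(bin_i = bi, bin_j = bj, count = count))

  decoy_tss <- (max(bins) - 2L) * cfg$bin_size + 1L
  tss <- data.frame(gene = c(cfg$gene, "DECOY1"), chrom = cfg$chrom,
                    tss_pos = c(tss_pos, decoy_tss), stringsAsFactors = FALSE)
  list(contacts = contacts, tss = tss, bait_pos = bait_pos,
       truth = list(bait_bin = bait_bin, promoter_bin = promoter_bin))
}

#' Simulate a clustered cell-by-gene count matrix
#'
#' The target gene is detected (count > 0) with probability `cluster_freq`
#' in the planted cluster and `background_freq` elsewhere; nonzero counts
#' are 1 + NB(mu = 1, dispersion = `nb_dispersion`). Decoy genes are
#' expressed uniformly across clusters.
#'
#' @param cfg a [sim_config()].
#' @return list(counts = sparse genes x cells dgCMatrix, clusters =
#'   data.frame(cell, cluster), planted_cluster).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  props <- cfg$cluster_props / sum(cfg$cluster_props)
  k <- length(props)
  sizes <- floor(props * cfg$n_cells)
  sizes[1] <- sizes[1] + (cfg$n_cells - sum(sizes))
  cl_names <- c("Epithelial", "Stromal-1", "Endothelial", "Myeloid",
                "Lymphoid", "Smooth-muscle", "Stromal-2", "Pericyte")
  if (k > length(cl_names)) cl_names <- c(cl_names, sprintf("C%d", seq_len(k)))
  cl_names <- cl_names[seq_len(k)]
  if (!cfg$planted_cluster %in% cl_names)
    cl_names[k] <- cfg$planted_cluster
  labels <- rep(cl_names, sizes)
  cells <- sprintf("cell%05d", seq_len(cfg$n_cells))

  genes <- c(cfg$gene, sprintf("GENE%03d", seq_len(cfg$n_genes - 1L)))
  size_nb <- 1 / cfg$nb_dispersion
  draw_counts <- function(p_expr) {
    on <- runif(cfg$n_cells) < p_expr
    cnt <- integer(cfg$n_cells)
    cnt[on] <- 1L + rnbinom(sum(on), mu = 1, size = size_nb)
    cnt
  }
  p_target <- ifelse(labels == cfg$planted_cluster,
                     cfg$cluster_freq, cfg$background_freq)
  rows <- list(draw_counts(p_target))
  for (g in 2:length(genes))
    rows[[g]] <- draw_counts(runif(1, 0.05, 0.4))
  mat <- do.call(rbind, rows)
  rownames(mat) <- genes; colnames(mat) <- cells
  counts <- Matrix::Matrix(mat, sparse = TRUE)
  list(counts = counts,
       clusters = data.frame(cell = cells, cluster = labels,
                             stringsAsFactors = FALSE),
       planted_cluster = cfg$planted_cluster)
}

#' Simulate a dual-luciferase reporter plate
#'
#' Four constructs (backbone, promoter_only, non-risk T_haplotype, risk
#' C_haplotype) in two conditions; firefly readings are lognormal, nano
#' readings are firefly x construct mean x lognormal noise with coefficient
#' of variation `reporter_cv`. The risk construct's mean is
#' `reporter_effect` times the non-risk mean.
#'
#' @param cfg a [sim_config()].
#' @return data.frame(construct, condition, replicate_id, nano, firefly).
#' @export
simulate_reporter <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 4L)
  means <- c(backbone = 1, promoter_only = 2,
             T_haplotype = 5, C_haplotype = 5 * cfg$reporter_effect)
  conditions <- c("non_decidualized", "decidualized")
  sdlog <- sqrt(log(1 + cfg$reporter_cv^2))
  rows <- list()
  for (cond in conditions) {
    for (cn in names(means)) {
      for (e in seq_len(cfg$n_experiments)) {
        for (r in seq_len(cfg$n_replicates)) {
          firefly <- rlnorm(1, meanlog = log(1000), sdlog = 0.2)
          noise <- rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
          rows[[length(rows) + 1L]] <- data.frame(
            construct = cn, condition = cond,
            replicate_id = sprintf("e%dr%d", e, r),
            nano = firefly * means[[cn]] * noise, firefly = firefly,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate the complete study
#'
#' Runs every generator off one config and returns all inputs plus the truth
#' record that downstream stages are scored against.
#'
#' @param cfg a [sim_config()].
#' @return list(panel, truth, peaksets, eqtl, motif, sequence, contacts,
#'   tss, bait_pos, counts, clusters, reporter, cfg).
#' @export
simulate_study <- function(cfg = sim_config()) {
  sim <- simulate_panel(cfg)
  ann <- simulate_annotations(cfg, sim)
  hic <- simulate_contacts(cfg)
  sc <- simulate_counts(cfg)
  rep_tab <- simulate_reporter(cfg)
  truth <- sim$truth
  truth$planted_tf <- cfg$planted_tf
  truth$bait_bin <- hic$truth$bait_bin
  truth$promoter_bin <- hic$truth$promoter_bin
  truth$planted_cluster <- sc$planted_cluster
  truth$reporter_effect <- cfg$reporter_effect
  list(panel = sim$panel, truth = truth,
       peaksets = ann$peaksets, eqtl = ann$eqtl, motif = ann$motif,
       sequence = ann$sequence,
       contacts = hic$contacts, tss = hic$tss, bait_pos = hic$bait_pos,
       counts = sc$counts, clusters = sc$clusters,
       reporter = rep_tab, cfg = cfg)
}

#' Write a simulated study to a directory of standard-format files
#'
#' Emits panel.vcf, peaks/*.bed with manifest.tsv, eqtl.tsv, motif files
#' (Cis-BP text and minimal MEME), sequence.fa, contacts.tsv, tss.bed,
#' counts.mtx with genes/cells/clusters TSVs, reporter.tsv and truth.json.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created).
#' @return the study list, invisibly.
#' @export
simulate_to_dir <- function(cfg, dir) {
  study <- simulate_study(cfg)
  dir.create(file.path(dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  write_vcf(study$panel, file.path(dir, "panel.vcf"))

  man <- do.call(rbind, lapply(study$peaksets, function(ps) {
    bed <- file.path("peaks", paste0(ps$dataset_id, ".bed"))
    write_bed(ps$intervals, file.path(dir, bed))
    data.frame(dataset_id = ps$dataset_id, bed_path = bed,
               assay_class = ps$assay_class, factor = ps$factor,
               cell_type = ps$cell_type, stringsAsFactors = FALSE)
  }))
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  write_eqtl(study$eqtl, file.path(dir, "eqtl.tsv"))
  write_motif_cisbp(study$motif, file.path(dir, "motif_cisbp.txt"))
  write_motif_meme(study$motif, file.path(dir, "motif.meme"))
  write_sequence(study$sequence, file.path(dir, "sequence.fa"))

  ct <- study$contacts
  utils::write.table(
    data.frame(chrom = ct$chrom, bin_i = ct$entries$bin_i,
               bin_j = ct$entries$bin_j, count = ct$entries$count),
    file.path(dir, "contacts.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_bed(data.frame(chrom = study$tss$chrom, start = study$tss$tss_pos - 1L,
                       end = study$tss$tss_pos, name = study$tss$gene),
            file.path(dir, "tss.bed"))

  Matrix::writeMM(study$counts, file.path(dir, "counts.mtx"))
  writeLines(rownames(study$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(study$counts), file.path(dir, "cells.tsv"))
  utils::write.table(study$clusters, file.path(dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$reporter, file.path(dir, "reporter.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(study)
}

#' Write / read the region sequence as FASTA
#'
#' The header records the 0-based half-open span, e.g. ">chrX:114999000-115130000".
#'
#' @param sequence list(chrom, start, seq) as produced by
#'   [simulate_annotations()].
#' @param path FASTA path.
#' @return the path ([write_sequence()]) or the sequence list
#'   ([read_sequence()]).
#' @export
write_sequence <- function(sequence, path) {
  con <- file(path, "w"); on.exit(close(con))
  end0 <- sequence$start + nchar(sequence$seq)
  writeLines(sprintf(">%s:%d-%d", sequence$chrom, sequence$start, end0), con)
  body <- substring(sequence$seq,
                    seq(1, nchar(sequence$seq), 70),
                    pmin(seq(1, nchar(sequence$seq), 70) + 69,
                         nchar(sequence$seq)))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_sequence
#' @param path FASTA path.
#' @export
read_sequence <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  m <- regmatches(hdr, regexec("^>([^:]+):([0-9]+)-([0-9]+)$", hdr))[[1]]
  if (length(m) != 4L) stop("FASTA header must be '>chrom:start-end'")
  list(chrom = m[2], start = as.integer(m[3]),
       seq = toupper(paste(lines[-1], collapse = "")))
}
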