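BASES <- c("A", "C", "G", "T")

## ---------------------------------------------------------------------------
## Domain types
## ---------------------------------------------------------------------------

#' Construct a table of biallelic SNP variants
#'
#' Variants are the atomic unit of the pipeline: 1-based positions with a
#' single-base reference and alternate allele. Indels and multiallelic
#' records are rejected at construction.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions (>= 1).
#' @param rsid identifier strings; "." allowed.
#' @param ref,alt single uppercase bases, ref != alt per row.
#' @return a `data.frame` with class `variant_table`.
#' @export
variant_table <- function(chrom, pos, rsid, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  pos <- as.integer(pos)
  if (any(pos < 1L)) stop("variant positions must be >= 1 (1-based)")
  if (any(!ref %in% BASES) || any(!alt %in% BASES))
    stop("alleles must be single bases A/C/G/T (SNPs only)")
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  df <- data.frame(chrom = as.character(chrom), pos = pos,
                   rsid = as.character(rsid), ref = ref, alt = alt,
                   stringsAsFactors = FALSE)
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Construct a phased haplotype panel
#'
#' The panel holds an `n_haplotypes x n_variants` 0/1 allele matrix (0 = ref,
#' 1 = alt), one row per haplotype. On chromosome X a male sample contributes
#' one haplotype row and a female two, following the PLINK hemizygote
#' convention.
#'
#' @param variants a [variant_table()].
#' @param alleles integer matrix of 0/1, rows = haplotypes, cols = variants.
#' @param sample_ids sample identifier per sample.
#' @param hap_sample integer index into `sample_ids` for each haplotype row.
#' @param sexes optional per-sample "M"/"F" labels.
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(variants, alleles, sample_ids,
                            hap_sample = NULL, sexes = NULL) {
  stopifnot(inherits(variants, "variant_table"))
  alleles <- as.matrix(alleles)
  if (!all(alleles %in% c(0L, 1L))) stop("allele matrix entries must be 0 or 1")
  if (ncol(alleles) != nrow(variants))
    stop("allele matrix column count must equal the number of variants")
  storage.mode(alleles) <- "integer"
  if (is.null(hap_sample)) {
    if (nrow(alleles) != 2L * length(sample_ids))
      stop("hap_sample required unless every sample is diploid")
    hap_sample <- rep(seq_along(sample_ids), each = 2L)
  }
  structure(list(variants = variants, alleles = alleles,
                 sample_ids = sample_ids,
                 hap_sample = as.integer(hap_sample), sexes = sexes),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes (%d samples) x %d SNPs on %s\n",
              nrow(x$alleles), length(x$sample_ids), nrow(x$variants),
              paste(unique(x$variants$chrom), collapse = ",")))
  invisible(x)
}

#' Construct a peak set
#'
#' Half-open 0-based genomic intervals from one functional-genomics dataset
#' (TF ChIP-seq, histone mark, or open chromatin).
#'
#' @param intervals data.frame with columns chrom, start (0-based), end
#'   (exclusive), name.
#' @param dataset_id dataset label.
#' @param assay_class one of "tf_chip", "histone", "open_chromatin".
#' @param factor TF name; required (non-empty) iff assay_class is "tf_chip".
#' @param cell_type free-text cell type.
#' @return object of class `peak_set`.
#' @export
peak_set <- function(intervals, dataset_id, assay_class,
                     factor = "", cell_type = "") {
  assay_class <- match.arg(assay_class,
                           c("tf_chip", "histone", "open_chromatin"))
  if (nrow(intervals) > 0) {
    if (any(intervals$start < 0) || any(intervals$start >= intervals$end))
      stop("intervals must satisfy 0 <= start < end (half-open)")
  }
  if ((assay_class == "tf_chip") != nzchar(factor))
    stop("assay_class 'tf_chip' requires a non-empty factor (and vice versa)")
  structure(list(intervals = intervals, dataset_id = dataset_id,
                 assay_class = assay_class, factor = factor,
                 cell_type = cell_type),
            class = "peak_set")
}

#' Position-frequency-matrix motif model
#'
#' @param name motif/TF identifier.
#' @param pfm L x 4 matrix of base probabilities (columns A,C,G,T), rows
#'   renormalized to sum to 1; L >= 2.
#' @param pseudocount smoothing pseudocount (total, split across bases).
#' @param background length-4 base composition, sums to 1.
#' @return object of class `motif_model`.
#' @export
motif_model <- function(name, pfm, pseudocount = 0.1,
                        background = rep(0.25, 4)) {
  pfm <- as.matrix(pfm)
  if (ncol(pfm) != 4L) stop("pfm must have 4 columns (A,C,G,T)")
  if (nrow(pfm) < 2L) stop("motif length must be >= 2")
  if (any(pfm < 0)) stop("pfm entries must be non-negative")
  rs <- rowSums(pfm)
  if (any(rs < 0.9 | rs > 1.1))
    stop("pfm row sums outside [0.9, 1.1]: looks like counts, not frequencies")
  pfm <- pfm / rs
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  colnames(pfm) <- BASES
  structure(list(name = name, pfm = pfm, pseudocount = pseudocount,
                 background = background),
            class = "motif_model")
}

## ---------------------------------------------------------------------------
## VCF
## ---------------------------------------------------------------------------

#' Read a phased haplotype panel from a (minimal) VCF
#'
#' Parses the CHROM/POS/ID/REF/ALT columns and the GT field only. Phased
#' diploid genotypes ("0|1") contribute two haplotype rows; haploid genotypes
#' ("0"/"1", male X) contribute one. With `sexes` supplied, a male sample's
#' homozygous diploid X genotype is collapsed to one haplotype row.
#' Multiallelic and non-SNP records are skipped with a warning. Unphased "/"
#' separators are an error on panels of more than one variant, since
#' haplotype-based LD requires phase.
#'
#' @param path VCF file path (plain text).
#' @param region optional "chrom:start-end" filter (1-based inclusive).
#' @param sexes optional named "M"/"F" vector keyed by sample id.
#' @return a [haplotype_panel()].
#' @export
read_vcf <- function(path, region = NULL, sexes = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop("VCF missing #CHROM header line")
  head_fields <- strsplit(sub("^#", "", lines[hdr]), "\t")[[1]]
  if (length(head_fields) < 10L || head_fields[9] != "FORMAT")
    stop("VCF has no FORMAT/sample columns: GT data required")
  samples <- head_fields[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]

  reg <- NULL
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4L) stop("region must be 'chrom:start-end'")
    reg <- list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
  }

  keep <- list(); hap_rows <- NULL; hap_sample <- NULL
  n_skipped <- 0L
  for (ln in body) {
    f <- strsplit(ln, "\t")[[1]]
    chrom <- f[1]; pos <- as.integer(f[2]); ref <- toupper(f[4]); alt <- toupper(f[5])
    if (!is.null(reg) &&
        (chrom != reg$chrom || pos < reg$start || pos > reg$end)) next
    if (grepl(",", alt) || !ref %in% BASES || !alt %in% BASES) {
      n_skipped <- n_skipped + 1L
      next
    }
    fmt <- strsplit(f[9], ":")[[1]]
    gt_i <- match("GT", fmt)
    if (is.na(gt_i)) stop("VCF FORMAT lacks GT field")
    gts <- vapply(strsplit(f[-(1:9)], ":"),
                  function(x) x[gt_i], character(1))
    keep[[length(keep) + 1L]] <-
      list(chrom = chrom, pos = pos, rsid = f[3], ref = ref, alt = alt,
           gts = gts)
  }
  if (n_skipped > 0L)
    warning(sprintf("skipped %d multiallelic/non-SNP record(s)", n_skipped))
  if (length(keep) == 0L) stop("no biallelic SNP records found in VCF")

  n_var <- length(keep)
  ## haplotype layout from the first record, checked for consistency after
  is_x <- grepl("^(chr)?X$", keep[[1]]$chrom, ignore.case = TRUE)
  per_sample_rows <- integer(length(samples))
  for (s in seq_along(samples)) {
    gt <- keep[[1]]$gts[s]
    sex <- if (!is.null(sexes)) sexes[[samples[s]]] else NA
    haploid <- !grepl("[|/]", gt) ||
      (is_x && identical(sex, "M"))
    per_sample_rows[s] <- if (haploid) 1L else 2L
  }
  n_hap <- sum(per_sample_rows)
  alleles <- matrix(0L, nrow = n_hap, ncol = n_var)
  hap_sample <- rep(seq_along(samples), per_sample_rows)

  for (v in seq_len(n_var)) {
    row <- 1L
    for (s in seq_along(samples)) {
      gt <- keep[[v]]$gts[s]
      if (grepl("/", gt, fixed = TRUE) && n_var > 1L &&
          per_sample_rows[s] == 2L) {
        stop(sprintf(
          "unphased genotype '%s' for sample %s at %s:%d: phased GT required for LD",
          gt, samples[s], keep[[v]]$chrom, keep[[v]]$pos))
      }
      al <- as.integer(strsplit(gt, "[|/]")[[1]])
      if (any(is.na(al)) || any(!al %in% c(0L, 1L)))
        stop(sprintf("unparseable GT '%s' for sample %s", gt, samples[s]))
      if (per_sample_rows[s] == 1L) {
        if (length(al) == 2L) {
          if (al[1] != al[2])
            stop(sprintf(
              "heterozygous X genotype '%s' for male sample %s", gt, samples[s]))
          al <- al[1]
        }
        alleles[row, v] <- al
        row <- row + 1L
      } else {
        if (length(al) != 2L)
          stop(sprintf("ploidy changes across records for sample %s", samples[s]))
        alleles[row, v] <- al[1]
        alleles[row + 1L, v] <- al[2]
        row <- row + 2L
      }
    }
  }

  vt <- variant_table(
    chrom = vapply(keep, `[[`, character(1), "chrom"),
    pos   = vapply(keep, `[[`, integer(1), "pos"),
    rsid  = vapply(keep, `[[`, character(1), "rsid"),
    ref   = vapply(keep, `[[`, character(1), "ref"),
    alt   = vapply(keep, `[[`, character(1), "alt"))
  inferred_sexes <- if (!is.null(sexes)) sexes[samples] else
    ifelse(per_sample_rows == 1L, "M", "F")
  haplotype_panel(vt, alleles, samples, hap_sample, inferred_sexes)
}

#' Write a haplotype panel as a minimal phased VCF
#'
#' @param panel a [haplotype_panel()].
#' @param path output path.
#' @export
write_vcf <- function(panel, path) {
  v <- panel$variants
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", panel$sample_ids), collapse = "\t"), con)
  for (i in seq_len(nrow(v))) {
    gts <- vapply(seq_along(panel$sample_ids), function(s) {
      rows <- which(panel$hap_sample == s)
      paste(panel$alleles[rows, i], collapse = "|")
    }, character(1))
    writeLines(paste(c(v$chrom[i], v$pos[i], v$rsid[i], v$ref[i], v$alt[i],
                       ".", "PASS", ".", "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## BED + manifest
## ---------------------------------------------------------------------------

#' Read a BED3+ file as half-open 0-based intervals
#'
#' @param path BED file path.
#' @return data.frame(chrom, start, end, name); zero rows for an empty file.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t")
  out <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1),
    start = as.integer(vapply(parts, `[`, character(1), 2)),
    end   = as.integer(vapply(parts, `[`, character(1), 3)),
    name  = vapply(parts, function(p) if (length(p) >= 4) p[4] else ".",
                   character(1)),
    stringsAsFactors = FALSE)
  bad <- which(out$start >= out$end)
  if (length(bad) > 0L)
    stop(sprintf("BED line %d of %s: start >= end", bad[1], path))
  out
}

#' Write intervals as BED
#' @param intervals data.frame(chrom, start, end, name).
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  con <- file(path, "w"); on.exit(close(con))
  if (nrow(intervals) > 0L)
    writeLines(paste(intervals$chrom, intervals$start, intervals$end,
                     intervals$name, sep = "\t"), con)
  invisible(path)
}

#' Read a peak-dataset manifest
#'
#' The manifest is a TSV with columns dataset_id, bed_path, assay_class,
#' factor, cell_type; each row's BED file is parsed relative to the
#' manifest's directory (absolute paths honored).
#'
#' @param manifest_path manifest TSV path.
#' @return list of [peak_set()] objects, one per manifest row.
#' @export
read_bed_manifest <- function(manifest_path) {
  man <- utils::read.table(manifest_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           colClasses = "character")
  need <- c("dataset_id", "bed_path", "assay_class", "factor", "cell_type")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$bed_path[i]
    if (!file.exists(p)) p <- file.path(base, man$bed_path[i])
    peak_set(read_bed(p), dataset_id = man$dataset_id[i],
             assay_class = man$assay_class[i], factor = man$factor[i],
             cell_type = man$cell_type[i])
  })
}

## ---------------------------------------------------------------------------
## Motif formats
## ---------------------------------------------------------------------------

#' Read a motif model from Cis-BP PWM text or minimal MEME format
#'
#' The Cis-BP dialect has a "Pos A C G T" header and one probability row per
#' position; minimal MEME has a MOTIF block with a letter-probability matrix.
#' Rows are renormalized to sum to 1; a row sum outside \[0.9, 1.1\] before
#' renormalization is rejected (likely raw counts).
#'
#' @param path motif file path.
#' @param format "cisbp_pwm" or "meme_minimal".
#' @param name motif name; defaults to a name parsed from the file.
#' @param pseudocount,background passed to [motif_model()].
#' @return a [motif_model()].
#' @export
read_motif <- function(path, format = c("cisbp_pwm", "meme_minimal"),
                       name = NULL, pseudocount = 0.1,
                       background = rep(0.25, 4)) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "cisbp_pwm") {
    hdr <- grep("^Pos\\b", lines)
    if (length(hdr) == 0L) stop("Cis-BP PWM file lacks 'Pos A C G T' header")
    body <- lines[(hdr[1] + 1L):length(lines)]
    body <- body[nzchar(trimws(body))]
    rows <- lapply(strsplit(trimws(body), "[ \t]+"), function(p)
      as.numeric(p[2:5]))
    pfm <- do.call(rbind, rows)
    if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  } else {
    mi <- grep("^MOTIF\\b", lines)
    if (length(mi) == 0L) stop("no MOTIF block found in MEME file")
    if (is.null(name)) {
      name <- strsplit(trimws(lines[mi[1]]), "[ \t]+")[[1]][2]
      if (is.na(name)) name <- "motif"
    }
    li <- grep("^letter-probability matrix", lines)
    if (length(li) == 0L) stop("MOTIF block lacks letter-probability matrix")
    body <- lines[(li[1] + 1L):length(lines)]
    num <- grepl("^\\s*[0-9.eE+-]+(\\s+[0-9.eE+-]+){3}\\s*$", body)
    stop_at <- which(!num)
    if (length(stop_at) > 0L) body <- body[seq_len(stop_at[1] - 1L)]
    pfm <- do.call(rbind, lapply(strsplit(trimws(body), "[ \t]+"), as.numeric))
  }
  motif_model(name, pfm, pseudocount = pseudocount, background = background)
}

#' Write a motif in Cis-BP PWM text format
#' @param motif a [motif_model()].
#' @param path output path.
#' @export
write_motif_cisbp <- function(motif, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("Pos\tA\tC\tG\tT", con)
  for (i in seq_len(nrow(motif$pfm)))
    writeLines(paste(c(i, sprintf("%.6f", motif$pfm[i, ])), collapse = "\t"),
               con)
  invisible(path)
}

#' Write a motif in minimal MEME format
#' @param motif a [motif_model()].
#' @param path output path.
#' @export
write_motif_meme <- function(motif, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", BASES, motif$background),
                     collapse = " "), "",
               sprintf("MOTIF %s", motif$name),
               sprintf("letter-probability matrix: alength= 4 w= %d",
                       nrow(motif$pfm))), con)
  for (i in seq_len(nrow(motif$pfm)))
    writeLines(paste(sprintf("%.6f", motif$pfm[i, ]), collapse = " "), con)
  invisible(path)
}

## ---------------------------------------------------------------------------
## eQTL tables (GTEx-style)
## ---------------------------------------------------------------------------

#' Read a GTEx-style eQTL association TSV
#'
#' Expected columns: variant_id (chrom_pos_ref_alt\[_build\]), gene_id,
#' tissue, effect_allele, slope, pval.
#'
#' @param path TSV path.
#' @return data.frame with parsed chrom/pos/ref/alt columns appended.
#' @export
read_eqtl <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  need <- c("variant_id", "gene_id", "tissue", "effect_allele", "slope", "pval")
  if (!all(need %in% names(df)))
    stop("eQTL table must have columns: ", paste(need, collapse = ", "))
  parts <- strsplit(df$variant_id, "_")
  df$chrom <- vapply(parts, `[`, character(1), 1)
  df$pos <- as.integer(vapply(parts, `[`, character(1), 2))
  df$ref <- toupper(vapply(parts, `[`, character(1), 3))
  df$alt <- toupper(vapply(parts, `[`, character(1), 4))
  if (any(!is.finite(df$slope))) stop("eQTL slopes must be finite")
  if (any(df$pval <= 0 | df$pval > 1)) stop("eQTL p-values must lie in (0,1]")
  df
}

#' Write a GTEx-style eQTL TSV
#' @param df data.frame with variant_id, gene_id, tissue, effect_allele,
#'   slope, pval columns.
#' @param path output path.
#' @export
write_eqtl <- function(df, path) {
  need <- c("variant_id", "gene_id", "tissue", "effect_allele", "slope", "pval")
  utils::write.table(df[, need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Coordinate helpers
## ---------------------------------------------------------------------------

#' Does a 1-based SNP position fall in half-open 0-based intervals?
#'
#' A variant at 1-based position p overlaps \[s, e) iff s <= p-1 < e.
#'
#' @param pos 1-based position (scalar).
#' @param start,end equal-length vectors of 0-based half-open bounds.
#' @return logical vector.
#' @export
point_in_intervals <- function(pos, start, end) {
  p0 <- pos - 1L
  start <= p0 & p0 < end
}

#' Normalize chromosome names against an alias map
#'
#' Maps e.g. "X" and "chrX" onto a single spelling so peak files and panels
#' from different sources agree.
#'
#' @param chrom character vector.
#' @param style "chr" (default, UCSC) or "plain".
#' @return normalized character vector.
#' @export
normalize_chrom <- function(chrom, style = c("chr", "plain")) {
  style <- match.arg(style)
  plain <- sub("^chr", "", chrom, ignore.case = TRUE)
  if (style == "chr") paste0("chr", plain) else plain
}
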