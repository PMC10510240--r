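#' Convert methylation beta values to M-values
#'
#' M = log2(beta / (1 - beta)); betas are clamped to [1e-6, 1 - 1e-6] so the
#' transform is finite at the boundaries.
#'
#' @param beta numeric vector or matrix of beta values in [0, 1]
#' @return M-values of the same shape
#' @export
beta_to_m <- function(beta) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]", call. = FALSE)
  b <- clamp(beta, 1e-6, 1 - 1e-6)
  log2(b / (1 - b))
}

#' Convert M-values back to beta values
#' @param m numeric vector or matrix of M-values
#' @return beta values in (0, 1)
#' @export
m_to_beta <- function(m) 2^m / (1 + 2^m)

#' Construct a genotype matrix object
#'
#' A samples x variants dosage matrix (0..2, NA for missing) together with
#' per-variant metadata. The counted (effect) allele is always `alt`;
#' downstream effect sizes are per copy of `alt`.
#'
#' @param dosage numeric matrix, samples in rows, variants in columns
#' @param variants data.frame with columns id, chrom, pos, ref, alt
#' @return an object of class `genotype_matrix`
#' @export
genotype_matrix <- function(dosage, variants) {
  dosage <- as.matrix(dosage)
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants)))
  if (ncol(dosage) != nrow(variants))
    stop("dosage columns and variant rows differ", call. = FALSE)
  if (anyDuplicated(variants$id))
    stop("duplicate variant id: ",
         variants$id[duplicated(variants$id)][1L], call. = FALSE)
  if (any(variants$pos < 1)) stop("variant positions must be >= 1", call. = FALSE)
  bad <- !is.na(variants$ref) & variants$ref == variants$alt
  if (any(bad)) stop("ref and alt alleles identical for variant ",
                     variants$id[bad][1L], call. = FALSE)
  colnames(dosage) <- variants$id
  variants$chrom <- as.character(variants$chrom)
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Construct a methylation matrix object
#'
#' Values are stored on the M-value scale; betas are converted at
#' construction.
#'
#' @param values numeric matrix, samples in rows, CpGs in columns
#' @param probes data.frame with columns id, chrom, pos
#' @param cohort array cohort label (e.g. "450K" or "EPIC")
#' @param value_kind `"m"` or `"beta"`; betas are transformed via
#'   [beta_to_m()]
#' @return an object of class `methylation_matrix` in M-value space
#' @export
methylation_matrix <- function(values, probes, cohort = "450K",
                               value_kind = c("m", "beta")) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  stopifnot(all(c("id", "chrom", "pos") %in% names(probes)))
  if (anyDuplicated(probes$id))
    stop("duplicate probe id", call. = FALSE)
  miss_coord <- is.na(probes$chrom) | is.na(probes$pos)
  if (any(miss_coord)) {
    warning(sum(miss_coord), " probe(s) lack coordinates and were dropped",
            call. = FALSE)
    probes <- probes[!miss_coord, , drop = FALSE]
    values <- values[, !miss_coord, drop = FALSE]
  }
  if (ncol(values) != nrow(probes))
    stop("value columns and probe rows differ", call. = FALSE)
  if (value_kind == "beta") values <- beta_to_m(values)
  colnames(values) <- probes$id
  probes$chrom <- as.character(probes$chrom)
  structure(list(values = values, probes = probes, cohort = cohort),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("methylation_matrix [%s]: %d samples x %d CpGs (M-values)\n",
              x$cohort, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# ---- genotype readers -------------------------------------------------------

parse_vcf_gt <- function(gt) {
  # "0/0", "0|1", "1/1", "./." (possibly with trailing :subfields)
  core <- sub(":.*$", "", gt)
  a1 <- substr(core, 1L, 1L)
  a2 <- substr(core, 3L, 3L)
  d <- suppressWarnings(as.numeric(a1) + as.numeric(a2))
  d[a1 == "." | a2 == "."] <- NA_real_
  d
}

read_vcf_genotypes <- function(path) {
  head_lines <- readLines(path, n = 200L)
  if (!length(head_lines) || !startsWith(head_lines[1L], "##fileformat"))
    stop("malformed VCF header at line 1: missing ##fileformat", call. = FALSE)
  chrom_line <- grep("^#CHROM", head_lines)
  if (!length(chrom_line))
    stop("malformed VCF header: no #CHROM column line in first 200 lines",
         call. = FALSE)
  nfield <- length(strsplit(head_lines[chrom_line[1L]], "\t")[[1L]])
  if (nfield < 9L)
    stop("malformed VCF header at line ", chrom_line[1L],
         ": fewer than 9 columns", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  fmt <- v@gt[, 1L]
  samples <- colnames(v@gt)[-1L]
  if (any(grepl("DS", fmt))) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    dosage <- t(ds)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    dosage <- t(apply(gt, 2L, parse_vcf_gt))
    if (nrow(fix) == 1L) dosage <- matrix(dosage, ncol = 1L)
  }
  rownames(dosage) <- samples
  genotype_matrix(dosage,
                  data.frame(id = ids, chrom = fix[, "CHROM"],
                             pos = as.integer(fix[, "POS"]),
                             ref = fix[, "REF"], alt = fix[, "ALT"],
                             stringsAsFactors = FALSE))
}

read_dosage_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("id", "chrom", "pos", "effect_allele")
  if (!all(need == names(tab)[1:4]))
    stop("malformed dosage TSV header: first four columns must be ",
         paste(need, collapse = "/"), call. = FALSE)
  samples <- names(tab)[-(1:4)]
  dosage <- t(as.matrix(tab[, -(1:4), drop = FALSE]))
  rownames(dosage) <- samples
  genotype_matrix(dosage,
                  data.frame(id = tab$id, chrom = tab$chrom,
                             pos = as.integer(tab$pos),
                             ref = NA_character_, alt = tab$effect_allele,
                             stringsAsFactors = FALSE))
}

#' Read genotypes from VCF or dosage TSV
#'
#' The dosage-TSV dialect has variants as rows; the first four columns are
#' id/chrom/pos/effect_allele and remaining columns are samples, with missing
#' dosages written as `NA`. In VCFs, GT fields are converted to ALT-allele
#' counts (DS is used when present); `./.` becomes a missing dosage.
#'
#' @param path file path
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage"`
#' @return a [genotype_matrix()]
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  if (format == "vcf") read_vcf_genotypes(path) else read_dosage_tsv(path)
}

#' Write a genotype matrix as dosage TSV
#' @param G a [genotype_matrix()]
#' @param path output file path
#' @return invisibly, the path
#' @export
write_dosage_tsv <- function(G, path) {
  tab <- data.frame(id = G$variants$id, chrom = G$variants$chrom,
                    pos = G$variants$pos, effect_allele = G$variants$alt,
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(t(G$dosage), check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- methylation ------------------------------------------------------------

#' Read a methylation matrix from TSV
#'
#' The value TSV has a `sample_id` first column and one column per CpG; the
#' probe sidecar TSV has columns id/chrom/pos.
#'
#' @param path value TSV path
#' @param probes_path probe-annotation sidecar TSV path
#' @param value_kind `"m"` or `"beta"`
#' @param cohort cohort label attached to the result
#' @return a [methylation_matrix()]
#' @export
read_methylation <- function(path, probes_path, value_kind = c("m", "beta"),
                             cohort = "450K") {
  value_kind <- match.arg(value_kind)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1L] != "sample_id")
    stop("methylation TSV must start with a sample_id column", call. = FALSE)
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(vals) <- tab$sample_id
  probes <- utils::read.delim(probes_path, stringsAsFactors = FALSE)
  probes <- probes[match(colnames(vals), probes$id), , drop = FALSE]
  if (anyNA(probes$id))
    stop("probe sidecar is missing entries for some CpG columns", call. = FALSE)
  methylation_matrix(vals, probes, cohort = cohort, value_kind = value_kind)
}

#' Write a methylation matrix (and its probe sidecar) as TSV
#' @param M a [methylation_matrix()]
#' @param path value TSV path
#' @param probes_path probe sidecar TSV path
#' @return invisibly, `path`
#' @export
write_methylation_tsv <- function(M, path, probes_path) {
  tab <- data.frame(sample_id = rownames(M$values), stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(M$values, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(M$probes, probes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- catalog and gene model -------------------------------------------------

#' Read a GWAS-catalog-style association table
#'
#' Expected TSV columns: `variant`, `trait`, `domain` (optional), `p`,
#' `study`. Rows whose p-value does not parse are rejected with a logged line
#' number.
#'
#' @param path TSV path
#' @return data.frame of associations (one per surviving row)
#' @export
read_catalog <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0L) {
    warning("catalog file is empty", call. = FALSE)
    return(data.frame(variant = character(), trait = character(),
                      domain = character(), p = numeric(),
                      study = character(), stringsAsFactors = FALSE))
  }
  need <- c("variant", "trait", "p", "study")
  if (!all(need %in% names(tab)))
    stop("catalog must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"domain" %in% names(tab)) tab$domain <- NA_character_
  p <- suppressWarnings(as.numeric(tab$p))
  bad <- is.na(p) | p <= 0 | p > 1
  if (any(bad)) {
    for (ln in which(bad))
      message(sprintf("[catalog] rejected line %d: unparseable p-value '%s'",
                      ln + 1L, tab$p[ln]))
  }
  out <- data.frame(variant = tab$variant, trait = tab$trait,
                    domain = tab$domain, p = p, study = tab$study,
                    stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a gene model from BED
#'
#' BED intervals (0-based half-open) are converted to the package's 1-based
#' inclusive convention at this boundary.
#'
#' @param path BED file path
#' @return data.frame with columns gene, chrom, start, end (1-based inclusive)
#' @export
read_gene_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- as.data.frame(gr)
  # GRanges is already 1-based inclusive after import's conversion
  out <- data.frame(gene = if ("name" %in% names(df)) df$name else
                      paste0("gene", seq_len(nrow(df))),
                    chrom = as.character(df$seqnames),
                    start = df$start, end = df$end,
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# ---- pipeline configuration -------------------------------------------------

#' Pipeline configuration
#'
#' Collects every analytic threshold the pipeline uses, the cohort labels,
#' the random seed, and the input/output paths. Probability thresholds are
#' validated to lie in (0, 1]; the cis window must be positive.
#'
#' @param candidate_p meta-analysis p-value threshold for candidate CpGs
#' @param fdr FDR level for SNP-CpG pair selection
#' @param clump_r2 LD r-squared above which variants join a clump
#' @param cis_window cis window half-width in bp around each CpG
#' @param iv_p p-value threshold for instrument selection
#' @param gw_p genome-wide threshold selecting top index meQTLs for the
#'   PheWAS-style lookup
#' @param prune_r2 LD-pruning r-squared ceiling for ancestry estimation
#' @param maf_min,miss_max,hwe_p_min genotype QC thresholds
#' @param detection_p_max,snp_bp probe QC thresholds
#' @param knn_k neighbours used in ancestry classification
#' @param target_ancestry ancestry label downstream stages are restricted
#'   to (the study analyses genotype-derived single-ancestry samples);
#'   `NULL` keeps every sample
#' @param alpha family-wise error rate used in Bonferroni-style corrections
#' @param cohorts array cohort labels
#' @param seed integer random seed governing every stochastic step
#' @param paths named list of file paths (as produced by [simulate_bundle()])
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(candidate_p = 1e-4, fdr = 0.05, clump_r2 = 0.1,
                            cis_window = 500000, iv_p = 0.05, gw_p = 5e-8,
                            prune_r2 = 0.02, maf_min = 0.05, miss_max = 0.05,
                            hwe_p_min = 1e-6, detection_p_max = 1e-12,
                            snp_bp = 10, knn_k = 20, target_ancestry = "AFR",
                            alpha = 0.05,
                            cohorts = c("450K", "EPIC"), seed = 1L,
                            paths = list()) {
  probs <- c(candidate_p = candidate_p, fdr = fdr, iv_p = iv_p, gw_p = gw_p,
             hwe_p_min = hwe_p_min, detection_p_max = detection_p_max,
             alpha = alpha)
  if (any(probs <= 0 | probs > 1))
    stop("probability thresholds must lie in (0, 1]: ",
         paste(names(probs)[probs <= 0 | probs > 1], collapse = ", "),
         call. = FALSE)
  if (cis_window <= 0) stop("cis_window must be > 0", call. = FALSE)
  if (clump_r2 < 0 || clump_r2 >= 1 || prune_r2 < 0 || prune_r2 >= 1)
    stop("r-squared thresholds must lie in [0, 1)", call. = FALSE)
  structure(list(candidate_p = candidate_p, fdr = fdr, clump_r2 = clump_r2,
                 cis_window = cis_window, iv_p = iv_p, gw_p = gw_p,
                 prune_r2 = prune_r2, maf_min = maf_min, miss_max = miss_max,
                 hwe_p_min = hwe_p_min, detection_p_max = detection_p_max,
                 snp_bp = snp_bp, knn_k = knn_k,
                 target_ancestry = target_ancestry, alpha = alpha,
                 cohorts = cohorts, seed = as.integer(seed), paths = paths),
            class = "pipeline_config")
}
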