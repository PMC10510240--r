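#' Hardy-Weinberg equilibrium chi-squared test
#'
#' 1-df goodness-of-fit of observed genotype counts against expectations
#' from the estimated allele frequency. Monomorphic variants return p = 1
#' by convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (AA = zero effect alleles)
#' @return two-sided p-value
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("counts must be >= 0", call. = FALSE)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("total count must be > 0", call. = FALSE)
  q <- (2 * n_aa + n_Aa) / (2 * n)  # effect-allele frequency
  if (q == 0 || q == 1) return(1)
  e <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chisq <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
  stats::pchisq(chisq, df = 1, lower.tail = FALSE)
}

#' Genotype quality control
#'
#' Removes variants with minor allele frequency below `maf_min`, missing
#' rate above `miss_max`, or Hardy-Weinberg p below `hwe_p_min` (dosages
#' rounded to genotype calls for the HWE counts). Variants exactly at the
#' MAF threshold are kept.
#'
#' @param G a [genotype_matrix()]
#' @param maf_min,miss_max,hwe_p_min thresholds
#' @return the filtered [genotype_matrix()]
#' @export
genotype_qc <- function(G, maf_min = 0.05, miss_max = 0.05,
                        hwe_p_min = 1e-6) {
  d <- G$dosage
  m <- ncol(d)
  miss <- colMeans(is.na(d))
  af <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- maf >= maf_min
  log_filter(sprintf("MAF >= %g", maf_min), m, sum(keep))
  keep2 <- keep & miss <= miss_max
  log_filter(sprintf("missing rate <= %g", miss_max), sum(keep), sum(keep2))
  hwe_p <- vapply(which(keep2), function(j) {
    g <- round(d[, j])
    hwe_test(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
             sum(g == 2, na.rm = TRUE))
  }, numeric(1L))
  keep3 <- keep2
  keep3[which(keep2)] <- hwe_p >= hwe_p_min
  log_filter(sprintf("HWE p >= %g", hwe_p_min), sum(keep2), sum(keep3))
  genotype_matrix(d[, keep3, drop = FALSE],
                  G$variants[keep3, , drop = FALSE])
}

#' Enumerate cis SNP-CpG pairs
#'
#' Same-chromosome pairs whose positions differ by at most `window` bp
#' (boundary inclusive).
#'
#' @param cpgs data.frame with id, chrom, pos
#' @param variants data.frame with id, chrom, pos
#' @param window half-width of the cis window in bp
#' @return data.frame with columns `variant`, `cpg`, `distance`
#' @export
cis_pairs <- function(cpgs, variants, window = 500000) {
  out <- vector("list", length(unique(cpgs$chrom)))
  i <- 0L
  for (ch in unique(cpgs$chrom)) {
    ci <- cpgs[cpgs$chrom == ch, , drop = FALSE]
    vi <- variants[variants$chrom == ch, , drop = FALSE]
    if (!nrow(vi)) next
    for (r in seq_len(nrow(ci))) {
      dd <- abs(vi$pos - ci$pos[r])
      hit <- dd <= window
      if (any(hit)) {
        i <- i + 1L
        out[[i]] <- data.frame(variant = vi$id[hit], cpg = ci$id[r],
                               distance = dd[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (i == 0L) return(data.frame(variant = character(), cpg = character(),
                                 distance = numeric()))
  res <- do.call(rbind, out[seq_len(i)])
  rownames(res) <- NULL
  res
}

#' Per-pair cis-meQTL regression
#'
#' For each SNP-CpG pair, fits `M = b0 + b1 * X + sum(b_i * C_i)` by OLS
#' (equivalently, via covariate-partialled regression with the full-model
#' residual degrees of freedom) and reports the per-allele effect, SE and
#' two-sided t-test p-value. Missing dosages are mean-imputed here only.
#' Monomorphic-in-sample variants yield a record with p = 1 and a
#' `degenerate` flag.
#'
#' @param M a [methylation_matrix()] (or samples x CpGs matrix)
#' @param G a [genotype_matrix()]
#' @param C data.frame of covariates (or NULL)
#' @param pairs data.frame from [cis_pairs()]
#' @param cohort label recorded in the result
#' @return data.frame: variant, cpg, beta, se, p, cohort, n, degenerate
#' @export
fit_meqtl <- function(M, G, C = NULL, pairs, cohort = "450K") {
  if (!nrow(pairs)) stop("pair list is empty", call. = FALSE)
  V <- if (inherits(M, "methylation_matrix")) M$values else as.matrix(M)
  X <- if (is.null(C)) matrix(1, nrow(V), 1L)
       else stats::model.matrix(~ ., as.data.frame(C))
  n <- nrow(V); p_cov <- ncol(X)
  df <- n - p_cov - 1L
  qx <- qr(X)
  resid_of <- function(A) A - X %*% qr.coef(qx, A)
  ucpg <- unique(pairs$cpg); uvar <- unique(pairs$variant)
  rM <- resid_of(V[, ucpg, drop = FALSE])
  D <- G$dosage[, uvar, drop = FALSE]
  for (j in seq_len(ncol(D))) {
    x <- D[, j]
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    D[, j] <- x
  }
  mono <- apply(D, 2L, stats::var) == 0
  rG <- resid_of(D)
  gi <- match(pairs$variant, uvar)
  mi <- match(pairs$cpg, ucpg)
  beta <- se <- pval <- numeric(nrow(pairs))
  sxx <- colSums(rG^2)
  for (r in seq_len(nrow(pairs))) {
    if (mono[gi[r]] || sxx[gi[r]] == 0) {
      beta[r] <- 0; se[r] <- Inf; pval[r] <- 1
      next
    }
    rg <- rG[, gi[r]]; rm_ <- rM[, mi[r]]
    b <- sum(rg * rm_) / sxx[gi[r]]
    rss <- sum(rm_^2) - b^2 * sxx[gi[r]]
    s <- sqrt(max(rss, 0) / df / sxx[gi[r]])
    beta[r] <- b; se[r] <- s
    pval[r] <- 2 * stats::pt(-abs(b / s), df = df)
  }
  data.frame(variant = pairs$variant, cpg = pairs$cpg, beta = beta, se = se,
             p = pval, cohort = cohort, n = n,
             degenerate = mono[gi] | sxx[gi] == 0,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment (`stats::p.adjust` with method "BH"), original
#' order preserved.
#'
#' @param p_values vector of p-values in (0, 1]
#' @return q-values in the input order
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Greedy LD clumping of meQTL records for one CpG
#'
#' Repeatedly takes the smallest-p unassigned variant as a new clump index
#' (p ties broken by lower genomic position) and assigns to its clump every
#' unassigned variant whose in-sample dosage r-squared with the index
#' exceeds `r2_min`.
#'
#' @param records data.frame of FDR-passing records for one CpG (columns
#'   variant, p at least)
#' @param G a [genotype_matrix()] holding dosages for all record variants
#' @param r2_min clumping r-squared threshold (strict)
#' @return `records` with `clump_id` and `is_index` columns
#' @export
clump <- function(records, G, r2_min = 0.1) {
  if (!nrow(records)) return(cbind(records, clump_id = character(0),
                                   is_index = logical(0)))
  idx <- match(records$variant, G$variants$id)
  if (anyNA(idx)) stop("dosages missing for some record variants",
                       call. = FALSE)
  D <- G$dosage[, idx, drop = FALSE]
  for (j in seq_len(ncol(D))) {
    x <- D[, j]; if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    D[, j] <- x
  }
  pos <- G$variants$pos[idx]
  ord <- order(records$p, pos)
  clump_id <- rep(NA_integer_, nrow(records))
  is_index <- rep(FALSE, nrow(records))
  cl <- 0L
  for (o in ord) {
    if (!is.na(clump_id[o])) next
    cl <- cl + 1L
    clump_id[o] <- cl
    is_index[o] <- TRUE
    free <- which(is.na(clump_id))
    if (length(free)) {
      r <- suppressWarnings(stats::cor(D[, o], D[, free, drop = FALSE]))
      r[is.na(r)] <- 0
      clump_id[free[r^2 > r2_min]] <- cl
    }
  }
  records$clump_id <- clump_id
  records$is_index <- is_index
  records
}

#' Nearest-gene annotation
#'
#' A position inside a gene maps to that gene (region class `genic`, or
#' the class given in an optional `class` column of the gene table);
#' otherwise the minimal-distance gene is kept with class `intergenic`.
#' Distance ties break to the lower-coordinate (start) gene. Positions on
#' chromosomes absent from the gene model get label `NA`.
#'
#' @param positions data.frame with id, chrom, pos
#' @param genes data.frame with gene, chrom, start, end (1-based inclusive),
#'   sorted or not
#' @return data.frame: id, gene, distance, region
#' @export
nearest_gene <- function(positions, genes) {
  out <- data.frame(id = positions$id, gene = NA_character_,
                    distance = NA_real_, region = NA_character_,
                    stringsAsFactors = FALSE)
  for (ch in unique(positions$chrom)) {
    gi <- genes[genes$chrom == ch, , drop = FALSE]
    pi_ <- which(positions$chrom == ch)
    if (!nrow(gi)) next
    gi <- gi[order(gi$start), , drop = FALSE]
    for (r in pi_) {
      pos <- positions$pos[r]
      d <- pmax(gi$start - pos, pos - gi$end, 0)
      best <- which(d == min(d))
      if (length(best) > 1L) best <- best[which.min(gi$start[best])]
      out$gene[r] <- gi$gene[best]
      out$distance[r] <- d[best]
      out$region[r] <- if (d[best] == 0) {
        if ("class" %in% names(gi) && !is.na(gi$class[best]))
          gi$class[best] else "genic"
      } else "intergenic"
    }
  }
  out
}

#' Run the full cis-meQTL mapping stage
#'
#' QC on the pooled genotypes, cis-pair enumeration for the candidate
#' CpGs, per-cohort per-pair regression, fixed-effects meta-analysis,
#' joint BH-FDR over all tested pairs (one family), per-CpG LD clumping
#' of FDR-passing pairs into index meQTLs, and nearest-gene annotation.
#'
#' @param candidates candidate-CpG data.frame (needs cpg, chrom, pos)
#' @param cohort_inputs named list per cohort with `M`, `G`, and covariate
#'   data.frame `C`
#' @param genes gene model from [read_gene_bed()] (or NULL to skip
#'   annotation)
#' @param config a [pipeline_config()]
#' @return list: `pairs` (all tested pairs with meta stats and fdr),
#'   `significant` (fdr < level, with clump assignments), `index`
#'   (index records, annotated), `qc_variants`
#' @export
run_meqtl <- function(candidates, cohort_inputs, genes = NULL,
                      config = pipeline_config()) {
  pooled <- do.call(rbind, lapply(cohort_inputs, function(ci) ci$G$dosage))
  G_pool <- genotype_matrix(pooled, cohort_inputs[[1L]]$G$variants)
  G_qc <- genotype_qc(G_pool, config$maf_min, config$miss_max,
                      config$hwe_p_min)
  cand_pos <- data.frame(id = candidates$cpg, chrom = candidates$chrom,
                         pos = candidates$pos, stringsAsFactors = FALSE)
  pairs <- cis_pairs(cand_pos, G_qc$variants, config$cis_window)
  if (!nrow(pairs)) stop("meqtl: no cis pairs in window", call. = FALSE)
  stage_log("meqtl", sprintf("%d cis pairs for %d candidate CpGs",
                             nrow(pairs), length(unique(pairs$cpg))))
  fits <- lapply(names(cohort_inputs), function(co) {
    ci <- cohort_inputs[[co]]
    keep <- match(G_qc$variants$id, ci$G$variants$id)
    Gc <- genotype_matrix(ci$G$dosage[, keep, drop = FALSE],
                          ci$G$variants[keep, , drop = FALSE])
    fit_meqtl(ci$M, Gc, ci$C, pairs, cohort = co)
  })
  meta <- meta_fixed(fits[[1L]], fits[[2L]])
  meta$fdr <- bh_fdr(meta$p)
  sig <- meta[meta$fdr < config$fdr, , drop = FALSE]
  log_filter(sprintf("meta FDR < %g", config$fdr), nrow(meta), nrow(sig))
  if (!nrow(sig)) stop("meqtl: zero FDR-significant pairs", call. = FALSE)
  sig_clumped <- do.call(rbind, lapply(split(sig, sig$cpg), clump,
                                       G = G_qc, r2_min = config$clump_r2))
  rownames(sig_clumped) <- NULL
  index <- sig_clumped[sig_clumped$is_index, , drop = FALSE]
  if (!is.null(genes)) {
    vpos <- G_qc$variants[match(index$variant, G_qc$variants$id), ]
    ann <- nearest_gene(data.frame(id = vpos$id, chrom = vpos$chrom,
                                   pos = vpos$pos), genes)
    index$nearest_gene <- ann$gene[match(index$variant, ann$id)]
    index$region <- ann$region[match(index$variant, ann$id)]
  }
  stage_log("meqtl", sprintf("%d significant pairs, %d index meQTLs",
                             nrow(sig_clumped), nrow(index)))
  list(pairs = meta, significant = sig_clumped, index = index,
       per_cohort = stats::setNames(fits, names(cohort_inputs)),
       G_qc = G_qc)
}
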