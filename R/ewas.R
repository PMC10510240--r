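#' Probe quality-control filters
#'
#' Drops CpGs with any sample detection p-value above `detection_p_max`,
#' and CpGs with a variant at the probe position or within `snp_bp` base
#' pairs (inclusive). Survivor counts are logged.
#'
#' @param M a [methylation_matrix()]
#' @param detection_p samples x CpGs detection p-value matrix aligned to `M`
#' @param snp_positions data.frame of variants with chrom and pos
#' @param detection_p_max detection p-value ceiling
#' @param snp_bp exclusion radius in bp around each variant
#' @return the filtered [methylation_matrix()]
#' @export
filter_probes <- function(M, detection_p, snp_positions,
                          detection_p_max = 1e-12, snp_bp = 10L) {
  n0 <- ncol(M$values)
  detection_p <- detection_p[, colnames(M$values), drop = FALSE]
  fail_det <- apply(detection_p, 2L, function(p) any(p > detection_p_max))
  keep <- !fail_det
  log_filter(sprintf("detection p <= %g", detection_p_max), n0, sum(keep))
  near_snp <- rep(FALSE, n0)
  if (!is.null(snp_positions) && nrow(snp_positions)) {
    for (ch in unique(M$probes$chrom)) {
      sp <- sort(snp_positions$pos[snp_positions$chrom == ch])
      if (!length(sp)) next
      ci <- which(M$probes$chrom == ch)
      cp <- M$probes$pos[ci]
      lo <- findInterval(cp - snp_bp - 0.5, sp)
      hi <- findInterval(cp + snp_bp + 0.5, sp)
      near_snp[ci] <- hi > lo  # a SNP lies within [pos - snp_bp, pos + snp_bp]
    }
  }
  keep2 <- keep & !near_snp
  log_filter(sprintf("no SNP within %d bp", snp_bp), sum(keep), sum(keep2))
  M$values <- M$values[, keep2, drop = FALSE]
  M$probes <- M$probes[keep2, , drop = FALSE]
  rownames(M$probes) <- NULL
  M
}

pc_sign_fix <- function(scores, loadings) {
  for (j in seq_len(ncol(scores))) {
    lead <- which.max(abs(loadings[, j]))
    if (loadings[lead, j] < 0) {
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  list(scores = scores, loadings = loadings)
}

#' Principal components of control-probe methylation
#'
#' Column-centred PCA of the samples x control-probes matrix; components
#' carry a deterministic sign (the largest-magnitude loading is positive).
#'
#' @param control_matrix samples x control probes
#' @param n_pc components returned (must not exceed the matrix rank)
#' @return samples x n_pc score matrix with an attribute `var_explained`
#' @export
control_probe_pcs <- function(control_matrix, n_pc = 20L) {
  X <- as.matrix(control_matrix)
  if (ncol(X) < n_pc)
    stop("fewer control probes than requested components", call. = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  rk <- qr(Xc)$rank
  if (n_pc > rk)
    stop("n_pc (", n_pc, ") exceeds the control-matrix rank (", rk, ")",
         call. = FALSE)
  sv <- svd(Xc, nu = n_pc, nv = n_pc)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pc)], n_pc)
  fixed <- pc_sign_fix(scores, sv$v)
  scores <- fixed$scores
  dimnames(scores) <- list(rownames(X), paste0("cpPC", seq_len(n_pc)))
  attr(scores, "var_explained") <- sv$d[seq_len(n_pc)]^2 / sum(svd(Xc)$d^2)
  scores
}

#' Reference-based cell-type deconvolution
#'
#' Constrained least squares in the Houseman tradition: per sample,
#' minimize `|| m - P w ||^2` subject to `w >= 0` and `sum(w) <= 1`,
#' where `P` holds the reference methylation profiles (CpGs x cell types).
#' Non-negativity is solved by Lawson-Hanson NNLS; when the unconstrained
#' optimum exceeds total proportion 1, the sum constraint is activated via
#' a heavily weighted penalty row (exactness to ~1e-6).
#'
#' @param M_sample numeric vector over the reference CpGs, or a samples x
#'   reference-CpGs matrix
#' @param cell_profiles reference CpGs x cell types matrix
#' @return samples x cell types proportion matrix
#' @export
estimate_cell_proportions <- function(M_sample, cell_profiles) {
  P <- as.matrix(cell_profiles)
  if (qr(P)$rank < ncol(P))
    stop("singular cell reference: profiles are linearly dependent",
         call. = FALSE)
  if (is.null(dim(M_sample))) M_sample <- matrix(M_sample, nrow = 1L)
  M_sample <- as.matrix(M_sample)
  if (!is.null(colnames(M_sample)) && !is.null(rownames(P)))
    M_sample <- M_sample[, rownames(P), drop = FALSE]
  if (ncol(M_sample) != nrow(P))
    stop("sample vector and reference CpGs do not align", call. = FALSE)
  mu <- 1e6 * max(abs(P))
  W <- matrix(NA_real_, nrow(M_sample), ncol(P),
              dimnames = list(rownames(M_sample), colnames(P)))
  for (i in seq_len(nrow(M_sample))) {
    m <- M_sample[i, ]
    w <- pracma::lsqnonneg(P, m)$x
    if (sum(w) > 1) {
      w <- pracma::lsqnonneg(rbind(P, mu), c(m, mu))$x
    }
    W[i, ] <- w
  }
  W
}

#' Principal components of technical-model residuals
#'
#' Each CpG is regressed (OLS) on the technical covariates; PCA of the
#' samples x CpGs residual matrix captures remaining batch structure. The
#' exposure is deliberately absent from this model so no phenotype signal
#' is removed.
#'
#' @param M a [methylation_matrix()] (or samples x CpGs matrix)
#' @param technical_covariates data.frame of covariates (no missing values)
#' @param n_pc components returned
#' @return samples x n_pc score matrix
#' @export
residual_pcs <- function(M, technical_covariates, n_pc = 5L) {
  V <- if (inherits(M, "methylation_matrix")) M$values else as.matrix(M)
  X <- stats::model.matrix(~ ., data = as.data.frame(technical_covariates))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("collinear covariates: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  resid <- V - X %*% qr.coef(qx, V)
  Rc <- scale(resid, center = TRUE, scale = FALSE)
  sv <- svd(Rc, nu = n_pc, nv = n_pc)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pc)], n_pc)
  scores <- pc_sign_fix(scores, sv$v)$scores
  dimnames(scores) <- list(rownames(V), paste0("resPC", seq_len(n_pc)))
  scores
}

#' Per-CpG exposure association (second-stage linear model)
#'
#' Fits, per CpG, `M = a0 + a1 * Y + sum(a_i * C_i)` by OLS and reports the
#' exposure coefficient, its SE, and a two-sided t-test p-value with the
#' residual degrees of freedom.
#'
#' @param M a [methylation_matrix()] (or samples x CpGs matrix)
#' @param Y 0/1 exposure vector
#' @param C data.frame or matrix of covariates (complete cases only)
#' @param cohort label recorded in the result
#' @return data.frame: cpg, chrom, pos, beta, se, p, cohort, n
#' @export
fit_ewas <- function(M, Y, C = NULL, cohort = "450K") {
  probes <- NULL
  V <- if (inherits(M, "methylation_matrix")) { probes <- M$probes; M$values }
       else as.matrix(M)
  Y <- as.numeric(Y)
  if (stats::var(Y) == 0) stop("exposure has zero variance", call. = FALSE)
  X <- if (is.null(C)) cbind(`(Intercept)` = 1, exposure = Y)
       else cbind(`(Intercept)` = 1, exposure = Y,
                  as.matrix(stats::model.matrix(~ . - 1, as.data.frame(C))))
  cc <- stats::complete.cases(X) & stats::complete.cases(V)
  X <- X[cc, , drop = FALSE]; V <- V[cc, , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1L) stop("too few complete cases for the covariate set",
                        call. = FALSE)
  qx <- qr(X)
  B <- qr.coef(qx, V)
  resid <- V - X %*% B
  rss <- colSums(resid^2)
  sigma2 <- rss / (n - p)
  xtx_inv_22 <- chol2inv(qr.R(qx))[2L, 2L]
  se <- sqrt(sigma2 * xtx_inv_22)
  beta <- B[2L, ]
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  out <- data.frame(cpg = colnames(V), beta = as.numeric(beta),
                    se = as.numeric(se), p = as.numeric(pval),
                    cohort = cohort, n = n, stringsAsFactors = FALSE)
  if (!is.null(probes)) {
    idx <- match(out$cpg, probes$id)
    out$chrom <- probes$chrom[idx]
    out$pos <- probes$pos[idx]
    out <- out[, c("cpg", "chrom", "pos", "beta", "se", "p", "cohort", "n")]
  }
  rownames(out) <- NULL
  out
}

#' Fixed-effects inverse-variance meta-analysis of two cohorts
#'
#' `w_i = 1/se_i^2`; `beta = sum(w b)/sum(w)`; `se = 1/sqrt(sum(w))`;
#' two-sided normal p-value.
#'
#' @param r1,r2 per-CpG result data.frames (from [fit_ewas()] or
#'   [fit_meqtl()]) sharing a `cpg` (and optionally `variant`) key
#' @return meta-analysed data.frame with `cohort = "META"`
#' @export
meta_fixed <- function(r1, r2) {
  key <- intersect(c("variant", "cpg"), intersect(names(r1), names(r2)))
  m <- merge(r1, r2, by = key, suffixes = c("_1", "_2"))
  if (nrow(m) == 0L) stop("no shared records to meta-analyse", call. = FALSE)
  if (nrow(m) < max(nrow(r1), nrow(r2)))
    message(sprintf("[meta] %d records shared by both cohorts",
                    nrow(m)))
  if (any(m$se_1 <= 0 | m$se_2 <= 0))
    stop("standard errors must be positive", call. = FALSE)
  w1 <- 1 / m$se_1^2; w2 <- 1 / m$se_2^2
  beta <- (w1 * m$beta_1 + w2 * m$beta_2) / (w1 + w2)
  se <- 1 / sqrt(w1 + w2)
  p <- 2 * stats::pnorm(-abs(beta / se))
  out <- m[, key, drop = FALSE]
  for (extra in c("chrom", "pos")) {
    col <- paste0(extra, "_1")
    if (col %in% names(m)) out[[extra]] <- m[[col]]
  }
  out$beta <- beta; out$se <- se; out$p <- p
  out$cohort <- "META"
  out$n <- (if ("n_1" %in% names(m)) m$n_1 else 0) +
    (if ("n_2" %in% names(m)) m$n_2 else 0)
  rownames(out) <- NULL
  out
}

#' Select exposure-associated candidate CpGs
#'
#' Keeps META rows with `p < p_threshold` and records the direction of the
#' exposure coefficient (hypomethylated when negative in exposed samples).
#'
#' @param meta META-cohort data.frame from [meta_fixed()]
#' @param p_threshold selection threshold on the meta p-value
#' @return the selected rows with a `direction` column; attributes
#'   `n_hyper` / `n_hypo` carry the direction counts
#' @export
select_candidates <- function(meta, p_threshold = 1e-4) {
  sel <- meta[meta$p < p_threshold, , drop = FALSE]
  sel$direction <- ifelse(sel$beta >= 0, "hyper", "hypo")
  log_filter(sprintf("meta p < %g", p_threshold), nrow(meta), nrow(sel))
  attr(sel, "n_hyper") <- sum(sel$direction == "hyper")
  attr(sel, "n_hypo") <- sum(sel$direction == "hypo")
  rownames(sel) <- NULL
  sel
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, 1)) / 0.4549` (the median of a 1-df
#' chi-squared).
#'
#' @param p_values vector of p-values in (0, 1]
#' @return the inflation factor lambda
#' @export
genomic_lambda <- function(p_values) {
  if (!length(p_values)) stop("need at least one p-value", call. = FALSE)
  if (any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Run the full candidate-CpG selection stage
#'
#' Per cohort: probe QC, cell-proportion estimation from the reference
#' CpGs, control-probe PCs, residual PCs from the phenotype-free technical
#' model, and the second-stage exposure regression; cohorts are then
#' combined by fixed-effects meta-analysis over their shared CpGs and
#' candidates selected at the configured meta p-value.
#'
#' @param cohort_inputs named list (one entry per cohort) of lists with
#'   elements `M` ([methylation_matrix()]), `detection_p`, `controls`,
#'   `covs` (covariate data.frame incl. `exposure`), and `G`
#'   ([genotype_matrix()], used for the SNP-proximity probe filter)
#' @param cell_reference reference CpGs x cell types profile matrix
#' @param config a [pipeline_config()]
#' @return list: `per_cohort` results, `meta`, `candidates`, `lambda`, and
#'   the per-cohort assembled `covariate_sets`
#' @export
run_ewas <- function(cohort_inputs, cell_reference, config = pipeline_config()) {
  per_cohort <- list()
  covariate_sets <- list()
  for (co in names(cohort_inputs)) {
    ci <- cohort_inputs[[co]]
    check_sample_alignment(rownames(ci$M$values), ci$covs$sample_id,
                           rownames(ci$controls), rownames(ci$G$dosage))
    M <- filter_probes(ci$M, ci$detection_p, ci$G$variants,
                       detection_p_max = config$detection_p_max,
                       snp_bp = config$snp_bp)
    ref_cpgs <- intersect(rownames(cell_reference), colnames(ci$M$values))
    cellp <- estimate_cell_proportions(ci$M$values[, ref_cpgs, drop = FALSE],
                                       cell_reference[ref_cpgs, , drop = FALSE])
    cpcs <- control_probe_pcs(ci$controls, n_pc = 20L)
    tech <- data.frame(age = ci$covs$age, tobacco = ci$covs$tobacco,
                       alcohol = ci$covs$alcohol,
                       log10_viral_load = ci$covs$log10_viral_load,
                       adherence = ci$covs$adherence, wbc = ci$covs$wbc)
    tech <- cbind(tech, as.data.frame(cellp[, -ncol(cellp), drop = FALSE]),
                  as.data.frame(cpcs))
    rpcs <- residual_pcs(M, tech, n_pc = 5L)
    C <- cbind(tech, as.data.frame(rpcs))
    covariate_sets[[co]] <- list(technical = tech, full = C)
    stage_log("ewas", sprintf("%s: fitting %d CpGs on %d samples",
                              co, ncol(M$values), nrow(M$values)))
    per_cohort[[co]] <- fit_ewas(M, ci$covs$exposure, C, cohort = co)
  }
  if (length(per_cohort) != 2L)
    stop("run_ewas expects exactly two cohorts", call. = FALSE)
  meta <- meta_fixed(per_cohort[[1L]], per_cohort[[2L]])
  lambda <- genomic_lambda(meta$p)
  stage_log("ewas", sprintf("genomic inflation lambda = %.3f", lambda))
  candidates <- select_candidates(meta, config$candidate_p)
  if (nrow(candidates) == 0L)
    stop("ewas: zero candidates at meta p < ", config$candidate_p,
         call. = FALSE)
  list(per_cohort = per_cohort, meta = meta, candidates = candidates,
       lambda = lambda, covariate_sets = covariate_sets)
}
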