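#' Select instrumental variables among index meQTLs
#'
#' Regresses the 0/1 exposure linearly on each index variant's dosage
#' (mirroring a PLINK-style linear fit on a binary trait) and keeps
#' variants with p below `p_max`. Because clumping is per CpG, several
#' CpGs at one locus can contribute mutually correlated index variants;
#' the retained set is therefore LD-deduplicated by a final greedy clump
#' on the exposure p-values (`r2 > iv_r2` joins a clump; only clump
#' indices are kept), so the instruments are LD-independent.
#'
#' @param meqtls data.frame of index meQTL records (variant at least)
#' @param G a [genotype_matrix()] with the discovery-cohort dosages
#' @param Y 0/1 exposure vector aligned to `G`
#' @param p_max instrument-selection p-value threshold (> 0)
#' @param iv_r2 LD r-squared above which two candidate instruments are
#'   considered redundant
#' @return data.frame: variant, effect_allele, other_allele,
#'   beta_exposure, se_exposure, p_exposure
#' @export
select_ivs <- function(meqtls, G, Y, p_max = 0.05, iv_r2 = 0.1) {
  if (p_max <= 0) stop("p_max must be > 0", call. = FALSE)
  vars <- unique(meqtls$variant)
  idx <- match(vars, G$variants$id)
  if (anyNA(idx)) stop("dosages missing for some meQTL variants",
                       call. = FALSE)
  D <- G$dosage[, idx, drop = FALSE]
  for (j in seq_len(ncol(D))) {
    x <- D[, j]; if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    D[, j] <- x
  }
  st <- marginal_ols(D, as.numeric(Y))
  keep <- st$p < p_max
  log_filter(sprintf("exposure p < %g", p_max), length(vars), sum(keep))
  if (!any(keep)) stop("no instruments: no variant passes p < ", p_max,
                       call. = FALSE)
  out <- data.frame(variant = vars[keep],
                    effect_allele = G$variants$alt[idx][keep],
                    other_allele = G$variants$ref[idx][keep],
                    beta_exposure = st$beta[keep], se_exposure = st$se[keep],
                    p_exposure = st$p[keep], stringsAsFactors = FALSE)
  cl <- clump(data.frame(variant = out$variant, p = out$p_exposure),
              G, r2_min = iv_r2)
  out <- out[cl$is_index, , drop = FALSE]
  log_filter(sprintf("one instrument per LD clump (r2 > %g)", iv_r2),
             nrow(cl), nrow(out))
  rownames(out) <- NULL
  out
}

is_palindromic <- function(a1, a2) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  !is.na(a1) & !is.na(a2) & unname(comp[a1]) == a2
}

#' Harmonize exposure and outcome summary statistics
#'
#' Joins the two tables on variant id; when the outcome's effect allele is
#' the exposure's other allele, the outcome beta sign is flipped and the
#' alleles swapped. Strand-ambiguous (A/T, C/G) variants are dropped with
#' a `palindromic` flag; variants whose alleles cannot be reconciled are
#' dropped with an `allele_mismatch` flag.
#'
#' @param exposure_stats data.frame: variant, effect_allele, other_allele,
#'   beta_exposure, se_exposure
#' @param outcome_stats data.frame: variant, effect_allele, other_allele,
#'   beta, se
#' @return data.frame (MR input): variant, beta_exposure, se_exposure,
#'   beta_outcome, se_outcome, status; dropped variants recorded in
#'   attribute `dropped`
#' @export
harmonize <- function(exposure_stats, outcome_stats) {
  m <- merge(exposure_stats, outcome_stats, by = "variant",
             suffixes = c("_exp", "_out"))
  if (!nrow(m)) stop("zero overlapping variants", call. = FALSE)
  pal <- is_palindromic(m$effect_allele_exp, m$other_allele_exp)
  same <- m$effect_allele_out == m$effect_allele_exp &
    (is.na(m$other_allele_out) | is.na(m$other_allele_exp) |
       m$other_allele_out == m$other_allele_exp)
  flipped <- !same & m$effect_allele_out == m$other_allele_exp &
    (is.na(m$other_allele_out) | m$other_allele_out == m$effect_allele_exp)
  flipped[is.na(flipped)] <- FALSE
  status <- ifelse(pal, "palindromic",
                   ifelse(same, "ok",
                          ifelse(flipped, "flipped", "allele_mismatch")))
  beta_out <- ifelse(status == "flipped", -m$beta, m$beta)
  keep <- status %in% c("ok", "flipped")
  out <- data.frame(variant = m$variant[keep],
                    beta_exposure = m$beta_exposure[keep],
                    se_exposure = m$se_exposure[keep],
                    beta_outcome = beta_out[keep],
                    se_outcome = m$se[keep],
                    status = status[keep], stringsAsFactors = FALSE)
  if (!nrow(out)) stop("zero variants survive harmonization", call. = FALSE)
  attr(out, "dropped") <- data.frame(variant = m$variant[!keep],
                                     status = status[!keep],
                                     stringsAsFactors = FALSE)
  out
}

#' Inverse-variance-weighted MR estimate
#'
#' Fixed-effect weighted regression of outcome effects on exposure effects
#' through the origin, weights `1/se_outcome^2`:
#' `estimate = sum(w bx by) / sum(w bx^2)`, `se = 1/sqrt(sum(w bx^2))`,
#' two-sided normal p.
#'
#' @param input harmonized MR input from [harmonize()]
#' @return one-row data.frame: method, estimate, se, p, n_iv
#' @export
mr_ivw <- function(input) {
  bx <- input$beta_exposure; by <- input$beta_outcome
  if (!length(bx)) stop("need at least one variant", call. = FALSE)
  if (all(bx == 0)) stop("all exposure effects are zero", call. = FALSE)
  w <- 1 / input$se_outcome^2
  est <- sum(w * bx * by) / sum(w * bx^2)
  se <- 1 / sqrt(sum(w * bx^2))
  data.frame(method = "IVW", estimate = est, se = se,
             p = 2 * stats::pnorm(-abs(est / se)), n_iv = length(bx),
             stringsAsFactors = FALSE)
}

weighted_median_est <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]; w <- w[ord]
  q <- (cumsum(w) - 0.5 * w) / sum(w)
  if (q[1L] >= 0.5) return(r[1L])
  j <- max(which(q <= 0.5))
  if (j == length(r) || q[j] == 0.5) return(r[j])
  r[j] + (r[j + 1L] - r[j]) * (0.5 - q[j]) / (q[j + 1L] - q[j])
}

#' Weighted-median MR estimate
#'
#' Per-variant Wald ratios `by/bx` with weights `bx^2/se_outcome^2`; the
#' estimate is the interpolated weighted median (robust to up to 50%
#' invalid instruments by weight). The SE comes from a parametric
#' bootstrap resampling `bx` and `by` from normals.
#'
#' @param input harmonized MR input (>= 3 variants)
#' @param n_boot bootstrap replicates (a warning is issued below 100)
#' @param seed integer seed for the bootstrap
#' @return one-row data.frame: method, estimate, se, p, n_iv
#' @export
mr_weighted_median <- function(input, n_boot = 1000L, seed = 1L) {
  if (nrow(input) < 3L) stop("need >= 3 variants", call. = FALSE)
  if (n_boot < 100L) warning("n_boot < 100: bootstrap SE will be unstable",
                             call. = FALSE)
  bx <- input$beta_exposure; by <- input$beta_outcome
  w <- bx^2 / input$se_outcome^2
  est <- weighted_median_est(by / bx, w)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bxs <- stats::rnorm(length(bx), bx, input$se_exposure)
      bys <- stats::rnorm(length(by), by, input$se_outcome)
      weighted_median_est(bys / bxs, bxs^2 / input$se_outcome^2)
    }, numeric(1L))
  })
  se <- stats::sd(boots)
  data.frame(method = "WM", estimate = est, se = se,
             p = 2 * stats::pnorm(-abs(est / se)), n_iv = nrow(input),
             stringsAsFactors = FALSE)
}

#' Residual-sum-and-outlier pleiotropy test with corrected re-estimation
#'
#' (1) Global test: the observed residual sum of squares is
#' `sum_i w_i (by_i - bx_i theta_(-i))^2` with leave-one-out IVW
#' predictions; its null distribution is simulated by drawing each
#' `by_i` from a normal centred at its leave-one-out prediction with SD
#' `se_outcome_i` and recomputing the same leave-one-out statistic on the
#' simulated draws (so estimator noise is propagated and the test keeps
#' its nominal size). (2) Outlier test: each variant's observed weighted
#' squared residual is compared with its simulated distribution
#' (Bonferroni over variants). (3) The IVW estimate is recomputed after
#' removing flagged outliers. A distortion summary (relative change of the
#' estimate) is reported as informational.
#'
#' @param input harmonized MR input (>= 4 variants)
#' @param n_sim simulated null replicates
#' @param sig significance level for global and outlier tests
#' @param seed integer seed
#' @return list: `result` (corrected one-row data.frame, method
#'   "MR-PRESSO"), `raw` (all-variant IVW), `global_p`, `outliers`,
#'   `outlier_p`, `distortion`
#' @export
mr_presso <- function(input, n_sim = 1000L, sig = 0.05, seed = 1L) {
  n <- nrow(input)
  if (n < 4L) stop("need >= 4 variants", call. = FALSE)
  bx <- input$beta_exposure; by <- input$beta_outcome
  sy <- input$se_outcome
  w <- 1 / sy^2
  A <- sum(w * bx * by); B <- sum(w * bx^2)
  theta_loo <- (A - w * bx * by) / (B - w * bx^2)
  pred <- bx * theta_loo
  obs_res <- w * (by - pred)^2
  rss_obs <- sum(obs_res)
  sims <- with_seed(seed, {
    by_sim <- matrix(stats::rnorm(n_sim * n, mean = rep(pred, each = n_sim),
                                  sd = rep(sy, each = n_sim)), nrow = n_sim)
    # each simulated dataset gets its own leave-one-out predictions
    A_sim <- as.numeric(by_sim %*% (w * bx))
    num <- A_sim - sweep(by_sim, 2L, w * bx, "*")
    theta_sim <- sweep(num, 2L, B - w * bx^2, "/")
    sweep((by_sim - sweep(theta_sim, 2L, bx, "*"))^2, 2L, w, "*")
  })
  rss_sim <- rowSums(sims)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  outlier_p <- vapply(seq_len(n), function(i)
    (1 + sum(sims[, i] >= obs_res[i])) / (n_sim + 1), numeric(1L))
  outliers <- input$variant[outlier_p * n < sig]
  if (length(outliers) == n)
    stop("no instruments remain: every variant flagged as outlier",
         call. = FALSE)
  raw <- mr_ivw(input)
  corrected <- mr_ivw(input[!(input$variant %in% outliers), , drop = FALSE])
  result <- data.frame(method = "MR-PRESSO", estimate = corrected$estimate,
                       se = corrected$se, p = corrected$p,
                       n_iv = corrected$n_iv, stringsAsFactors = FALSE)
  distortion <- if (length(outliers))
    (corrected$estimate - raw$estimate) / abs(raw$estimate) else 0
  list(result = result, raw = raw, global_p = global_p,
       outliers = outliers, outlier_p = outlier_p, distortion = distortion)
}

#' Family-wise correction of MR results
#'
#' Flags results with `p < alpha / (n_pairs * n_methods)` — e.g.
#' 0.05/13/3 = 1.28E-3 for 13 trait-study pairs each tested by 3 methods.
#'
#' @param results data.frame of MR results with a `p` column
#' @param n_pairs number of trait-study pairs tested
#' @param n_methods number of MR methods per pair
#' @param alpha family-wise error rate
#' @return `results` with `cutoff` and `significant` columns
#' @export
correct_mr <- function(results, n_pairs, n_methods = 3L, alpha = 0.05) {
  cutoff <- bonferroni_threshold(alpha, n_pairs, n_methods)
  results$cutoff <- cutoff
  results$significant <- results$p < cutoff
  results
}

#' Run the full Mendelian-randomization stage
#'
#' Selects LD-independent instruments among the index meQTLs, harmonizes
#' them against each outcome study, runs IVW, weighted-median and the
#' outlier-corrected estimator, and applies the family-wise correction
#' over (studies x methods).
#'
#' @param index_meqtls index meQTL data.frame
#' @param G discovery [genotype_matrix()]
#' @param Y 0/1 exposure vector
#' @param outcome_tables named list of outcome summary-stat data.frames
#'   (variant, effect_allele, other_allele, beta, se, trait)
#' @param config a [pipeline_config()]
#' @return list: `results` (long data.frame over study x method),
#'   `instruments`, `presso` details per study
#' @export
run_mr <- function(index_meqtls, G, Y, outcome_tables,
                   config = pipeline_config()) {
  ivs <- select_ivs(index_meqtls, G, Y, p_max = config$iv_p)
  stage_log("mr", sprintf("%d instruments selected", nrow(ivs)))
  all_res <- list()
  presso_details <- list()
  for (sid in names(outcome_tables)) {
    ot <- outcome_tables[[sid]]
    inp <- harmonize(ivs, ot)
    trait <- if ("trait" %in% names(ot)) ot$trait[1L] else NA_character_
    res <- mr_ivw(inp)
    if (nrow(inp) >= 3L)
      res <- rbind(res, mr_weighted_median(inp, seed = config$seed + 11L))
    else stage_log("mr", sprintf("%s: < 3 instruments, weighted median skipped",
                                 sid))
    if (nrow(inp) >= 4L) {
      pr <- tryCatch(mr_presso(inp, seed = config$seed + 13L),
                     error = function(e) {
                       stage_log("mr", sprintf("%s: outlier test failed (%s)",
                                               sid, conditionMessage(e)))
                       NULL
                     })
      if (!is.null(pr)) {
        presso_details[[sid]] <- pr
        res <- rbind(res, pr$result)
      }
    } else stage_log("mr", sprintf("%s: < 4 instruments, outlier test skipped",
                                   sid))
    res$study <- sid
    res$trait <- trait
    res$n_outliers <- length(presso_details[[sid]]$outliers)
    all_res[[sid]] <- res
  }
  results <- do.call(rbind, all_res)
  rownames(results) <- NULL
  results <- correct_mr(results, n_pairs = length(outcome_tables),
                        n_methods = 3L, alpha = config$alpha)
  stage_log("mr", sprintf("%d of %d results significant at cutoff %.3g",
                          sum(results$significant), nrow(results),
                          results$cutoff[1L]))
  list(results = results, instruments = ivs, presso = presso_details)
}
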