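#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so generators are pure
#' functions of (config, seed).
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @export
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  expr
}

rdirichlet_mat <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Simulation configuration
#'
#' Defaults mirror the emulated study design: two array cohorts of 423
#' ("450K", 39% exposed) and 388 ("EPIC", 33% exposed) samples drawn from an
#' admixed population dominated by one of four ancestral groups, with block
#' LD, planted cis effects on methylation, an exposure partially driven by
#' those same variants, external outcome GWAS cohorts carrying a causal
#' effect of the exposure, and a trait catalog enriched for the planted
#' meQTL blocks.
#'
#' @param n_pops number of ancestral populations
#' @param pop_labels ancestral population labels
#' @param fst per-population Balding-Nichols differentiation
#' @param n_ref_per_pop reference-panel samples per population
#' @param n_cohort named per-cohort sample sizes
#' @param prevalence named per-cohort exposure prevalence
#' @param admixed_frac fraction of cohort samples with strongly admixed
#'   ancestry (no dominant population)
#' @param n_snps,n_cpgs marker counts
#' @param ld_block_size variants per LD block
#' @param ld_r target within-block dosage correlation, in `[0, 1)`
#' @param maf_range ancestral allele-frequency range
#' @param missing_rate genotype dropout rate applied to the observed cohort
#'   dosages
#' @param n_true_meqtls planted cis SNP-CpG effects
#' @param meqtl_beta_range absolute per-allele M-value effect range
#' @param n_true_exposure_cpgs CpGs with a planted exposure effect (the
#'   planted meQTL CpGs are drawn from this set so they survive candidate
#'   selection)
#' @param exposure_cpg_effect absolute M-value shift in exposed samples
#' @param n_exposure_snps planted meQTL variants that also shift exposure
#'   odds
#' @param exposure_logor per-allele log-odds effect on the exposure
#' @param causal_gamma causal effect of the exposure on each outcome trait
#' @param n_outcome_traits,outcome_n outcome traits and per-study GWAS size
#' @param n_pleiotropic variants given a direct (horizontally pleiotropic)
#'   outcome effect
#' @param pleiotropy_effect direct per-allele outcome effect
#' @param n_cell_types,cell_alpha cell types and Dirichlet concentration of
#'   per-sample mixing proportions
#' @param n_cell_ref_cpgs leading CpGs used as the deconvolution reference
#' @param n_control_probes technical control probes
#' @param noise_sd,batch_sd residual and per-cohort batch standard deviations
#'   (M-value units)
#' @param n_batch_factors,batch_factor_sd unmeasured within-cohort batch
#'   factors (plate/position effects) and their per-CpG loading SD; this is
#'   the structure the residual-PC adjustment captures
#' @param detection_fail_rate fraction of CpGs given one failing detection
#'   p-value
#' @param n_catalog_traits,n_enriched_traits,n_risk_per_trait,enrichment_factor
#'   catalog structure: total traits, traits enriched for planted meQTL
#'   blocks, risk variants per trait, and the enrichment sampling factor
#' @param seed default integer seed
#' @return a `sim_config` list
#' @export
sim_config <- function(n_pops = 4L,
                       pop_labels = c("AFR", "EUR", "EAS", "SAS"),
                       fst = rep(0.1, 4L),
                       n_ref_per_pop = 150L,
                       n_cohort = c("450K" = 423L, "EPIC" = 388L),
                       prevalence = c("450K" = 0.39, "EPIC" = 0.33),
                       admixed_frac = 0.13,
                       n_snps = 2000L, n_cpgs = 1000L,
                       ld_block_size = 10L, ld_r = 0.8,
                       maf_range = c(0.1, 0.5),
                       missing_rate = 0.01,
                       n_true_meqtls = 50L,
                       meqtl_beta_range = c(0.4, 0.5),
                       n_true_exposure_cpgs = 60L,
                       exposure_cpg_effect = 0.5,
                       n_exposure_snps = 40L,
                       exposure_logor = 0.4,
                       causal_gamma = 0.3,
                       n_outcome_traits = 3L,
                       outcome_n = 5000L,
                       n_pleiotropic = 3L,
                       pleiotropy_effect = 1.0,
                       n_cell_types = 6L,
                       cell_alpha = c(6, 4, 2, 2, 3, 15),
                       n_cell_ref_cpgs = 200L,
                       n_control_probes = 40L,
                       noise_sd = 0.5, batch_sd = 0.3,
                       n_batch_factors = 5L, batch_factor_sd = 0.3,
                       detection_fail_rate = 0.01,
                       n_catalog_traits = 20L,
                       n_enriched_traits = 8L,
                       n_risk_per_trait = 40L,
                       enrichment_factor = 8,
                       seed = 1L) {
  cfg <- list(n_pops = as.integer(n_pops), pop_labels = pop_labels, fst = fst,
              n_ref_per_pop = as.integer(n_ref_per_pop),
              n_cohort = n_cohort, prevalence = prevalence,
              admixed_frac = admixed_frac,
              n_snps = as.integer(n_snps), n_cpgs = as.integer(n_cpgs),
              ld_block_size = as.integer(ld_block_size), ld_r = ld_r,
              maf_range = maf_range, missing_rate = missing_rate,
              n_true_meqtls = as.integer(n_true_meqtls),
              meqtl_beta_range = meqtl_beta_range,
              n_true_exposure_cpgs = as.integer(n_true_exposure_cpgs),
              exposure_cpg_effect = exposure_cpg_effect,
              n_exposure_snps = as.integer(n_exposure_snps),
              exposure_logor = exposure_logor,
              causal_gamma = causal_gamma,
              n_outcome_traits = as.integer(n_outcome_traits),
              outcome_n = as.integer(outcome_n),
              n_pleiotropic = as.integer(n_pleiotropic),
              pleiotropy_effect = pleiotropy_effect,
              n_cell_types = as.integer(n_cell_types),
              cell_alpha = cell_alpha,
              n_cell_ref_cpgs = as.integer(n_cell_ref_cpgs),
              n_control_probes = as.integer(n_control_probes),
              noise_sd = noise_sd, batch_sd = batch_sd,
              n_batch_factors = as.integer(n_batch_factors),
              batch_factor_sd = batch_factor_sd,
              detection_fail_rate = detection_fail_rate,
              n_catalog_traits = as.integer(n_catalog_traits),
              n_enriched_traits = as.integer(n_enriched_traits),
              n_risk_per_trait = as.integer(n_risk_per_trait),
              enrichment_factor = enrichment_factor,
              seed = as.integer(seed))
  counts <- c(cfg$n_pops, cfg$n_ref_per_pop, cfg$n_cohort, cfg$n_snps,
              cfg$n_cpgs, cfg$ld_block_size, cfg$outcome_n)
  if (any(counts < 1)) stop("all counts must be >= 1", call. = FALSE)
  if (length(cfg$fst) != cfg$n_pops)
    stop("fst must have one entry per population", call. = FALSE)
  if (any(cfg$fst <= 0 | cfg$fst > 0.5))
    stop("fst must lie in (0, 0.5]", call. = FALSE)
  if (cfg$ld_r < 0 || cfg$ld_r >= 1)
    stop("ld_r must lie in [0, 1)", call. = FALSE)
  if (cfg$enrichment_factor < 1)
    stop("enrichment_factor must be >= 1", call. = FALSE)
  if (cfg$n_true_meqtls > cfg$n_true_exposure_cpgs)
    stop("planted meQTL CpGs are drawn from the exposure CpGs: ",
         "n_true_meqtls must be <= n_true_exposure_cpgs", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

# Genome layout: one locus per LD block, loci 2 Mb apart across chromosomes,
# SNPs 1 kb apart inside the locus, CpGs scattered within +/-300 kb of a
# random locus so each CpG's cis window covers exactly its own locus.
sim_layout <- function(cfg) {
  n_blocks <- ceiling(cfg$n_snps / cfg$ld_block_size)
  loci_per_chrom <- 50L
  locus <- seq_len(n_blocks)
  chrom <- paste0("chr", (locus - 1L) %/% loci_per_chrom + 1L)
  center <- ((locus - 1L) %% loci_per_chrom) * 2000000L + 1000000L
  snp_block <- rep(locus, each = cfg$ld_block_size)[seq_len(cfg$n_snps)]
  within <- (seq_len(cfg$n_snps) - 1L) %% cfg$ld_block_size
  variants <- data.frame(
    id = sprintf("rs%05d", seq_len(cfg$n_snps)),
    chrom = chrom[snp_block],
    pos = center[snp_block] + within * 1000L,
    ref = "A", alt = "G",
    block = snp_block, stringsAsFactors = FALSE)
  list(n_blocks = n_blocks, block_chrom = chrom, block_center = center,
       variants = variants)
}

sim_probes <- function(cfg, layout, seed) {
  with_seed(seed, {
    locus <- sample.int(layout$n_blocks, cfg$n_cpgs, replace = TRUE)
    data.frame(id = sprintf("cg%07d", seq_len(cfg$n_cpgs)),
               chrom = layout$block_chrom[locus],
               pos = layout$block_center[locus] +
                 as.integer(round(stats::runif(cfg$n_cpgs, -3e5, 3e5))),
               block = locus, stringsAsFactors = FALSE)
  })
}

# Common-cause haplotype draw giving within-block dosage correlation ld_r:
# each haplotype copies a block anchor allele with probability sqrt(ld_r),
# otherwise draws a fresh allele at the same frequency.
draw_block_genotypes <- function(p_sample, block_size, ld_r) {
  n <- length(p_sample)
  theta <- sqrt(ld_r)
  p_hap <- rep(p_sample, each = 2L)
  hap <- function() {
    anchor <- stats::rbinom(2L * n, 1L, p_hap)
    copy <- matrix(stats::rbinom(2L * n * block_size, 1L, theta),
                   nrow = 2L * n)
    fresh <- matrix(stats::rbinom(2L * n * block_size, 1L, p_hap),
                    nrow = 2L * n)
    copy * anchor + (1L - copy) * fresh
  }
  alleles <- hap()
  alleles[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    alleles[seq(2L, 2L * n, by = 2L), , drop = FALSE]
}

#' Simulate a Balding-Nichols reference panel
#'
#' Block-constant ancestral frequencies are drawn uniformly on the
#' configured range; each population's frequency is a Beta draw
#' parameterized by its Fst; genotypes are Binomial(2, p) with block-level
#' LD at the configured correlation.
#'
#' @param cfg a [sim_config()]
#' @param seed integer seed (defaults to `cfg$seed`)
#' @return list with `G` (a [genotype_matrix()]), `labels` (per-sample
#'   population), `freqs` (populations x variants frequency matrix), and
#'   `layout`
#' @export
simulate_reference_panel <- function(cfg, seed = cfg$seed) {
  layout <- sim_layout(cfg)
  with_seed(seed, {
    p0_block <- stats::runif(layout$n_blocks, cfg$maf_range[1], cfg$maf_range[2])
    freqs <- matrix(NA_real_, nrow = cfg$n_pops, ncol = cfg$n_snps,
                    dimnames = list(cfg$pop_labels, layout$variants$id))
    for (k in seq_len(cfg$n_pops)) {
      f <- cfg$fst[k]
      pk_block <- stats::rbeta(layout$n_blocks,
                               p0_block * (1 - f) / f,
                               (1 - p0_block) * (1 - f) / f)
      pk_block <- clamp(pk_block, 0.01, 0.99)
      freqs[k, ] <- pk_block[layout$variants$block]
    }
    n <- cfg$n_ref_per_pop * cfg$n_pops
    labels <- rep(cfg$pop_labels, each = cfg$n_ref_per_pop)
    dosage <- matrix(NA_real_, nrow = n, ncol = cfg$n_snps)
    for (b in seq_len(layout$n_blocks)) {
      cols <- which(layout$variants$block == b)
      p_block <- freqs[, cols[1L]]
      dosage[, cols] <- draw_block_genotypes(rep(p_block, each = cfg$n_ref_per_pop),
                                             length(cols), cfg$ld_r)
    }
    rownames(dosage) <- paste0("ref_", labels, "_",
                               rep(seq_len(cfg$n_ref_per_pop), cfg$n_pops))
    list(G = genotype_matrix(dosage, layout$variants[, 1:5]),
         labels = labels, freqs = freqs, layout = layout,
         p0_block = p0_block)
  })
}

#' Draw admixture proportions for a study cohort
#'
#' Most samples are dominated by the first population (proportion drawn
#' uniformly on `[0.85, 1]`); a configured fraction are strongly admixed
#' (flat Dirichlet, redrawn until no population exceeds 0.7) and carry the
#' truth label `"ADMIXED"`.
#'
#' @param cfg a [sim_config()]
#' @param n number of samples
#' @param seed integer seed
#' @return list with `props` (n x K matrix) and `labels`
#' @export
simulate_admixture_props <- function(cfg, n, seed = cfg$seed) {
  with_seed(seed, {
    admixed <- stats::runif(n) < cfg$admixed_frac
    props <- matrix(0, n, cfg$n_pops, dimnames = list(NULL, cfg$pop_labels))
    n_major <- sum(!admixed)
    if (n_major) {
      q1 <- stats::runif(n_major, 0.85, 1)
      rest <- rdirichlet_mat(n_major, rep(1, cfg$n_pops - 1L)) * (1 - q1)
      props[!admixed, ] <- cbind(q1, rest)
    }
    for (i in which(admixed)) {
      repeat {
        q <- as.numeric(rdirichlet_mat(1L, rep(1.5, cfg$n_pops)))
        if (max(q) <= 0.7) break
      }
      props[i, ] <- q
    }
    labels <- ifelse(admixed, "ADMIXED", cfg$pop_labels[1L])
    list(props = props, labels = labels)
  })
}

#' Simulate an admixed cohort from panel frequencies
#'
#' Each sample's per-variant allele frequency is the admixture-weighted
#' mixture of population frequencies; genotypes are Binomial(2, mixture
#' frequency) with the same block-LD construction as the reference panel.
#'
#' @param freqs populations x variants frequency matrix (from
#'   [simulate_reference_panel()])
#' @param admix_props samples x populations proportion matrix, rows on the
#'   simplex
#' @param cfg a [sim_config()]
#' @param layout genome layout (from the panel); defaults to `sim_layout(cfg)`
#' @param seed integer seed
#' @param sample_prefix prefix for generated sample ids
#' @return a [genotype_matrix()]
#' @export
simulate_admixed_cohort <- function(freqs, admix_props, cfg,
                                    layout = sim_layout(cfg),
                                    seed = cfg$seed,
                                    sample_prefix = "s") {
  admix_props <- as.matrix(admix_props)
  if (any(admix_props < 0) ||
      any(abs(rowSums(admix_props) - 1) > 1e-8))
    stop("admixture proportions must be non-negative and sum to 1 per sample",
         call. = FALSE)
  n <- nrow(admix_props)
  with_seed(seed, {
    dosage <- matrix(NA_real_, nrow = n, ncol = ncol(freqs))
    for (b in seq_len(layout$n_blocks)) {
      cols <- which(layout$variants$block == b)
      p_mix <- as.numeric(admix_props %*% freqs[, cols[1L]])
      dosage[, cols] <- draw_block_genotypes(p_mix, length(cols), cfg$ld_r)
    }
    rownames(dosage) <- sprintf("%s%04d", sample_prefix, seq_len(n))
    genotype_matrix(dosage, layout$variants[, 1:5])
  })
}

#' Build the ground-truth object for a simulation
#'
#' Chooses the planted SNP-CpG cis effects (each planted CpG is paired with
#' a variant from its own LD locus), exposure effects on CpGs and on
#' exposure odds, the causal effect of the exposure on each outcome trait,
#' the pleiotropic variants, cell-type profiles, and covariate effects.
#'
#' @param cfg a [sim_config()]
#' @param layout genome layout
#' @param probes probe table from `sim_probes`
#' @param seed integer seed
#' @return a `synthetic_truth` list
#' @export
simulate_truth <- function(cfg, layout, probes, seed = cfg$seed) {
  with_seed(seed + 101L, {
    exp_cpg_idx <- sample.int(cfg$n_cpgs - cfg$n_cell_ref_cpgs,
                              cfg$n_true_exposure_cpgs) + cfg$n_cell_ref_cpgs
    exp_sign <- sample(c(-1, 1), cfg$n_true_exposure_cpgs, replace = TRUE,
                       prob = c(0.75, 0.25))  # mostly hypomethylated in exposed
    exposure_cpg_effects <- data.frame(
      cpg = probes$id[exp_cpg_idx],
      effect = exp_sign * cfg$exposure_cpg_effect,
      stringsAsFactors = FALSE)

    meqtl_cpg_idx <- exp_cpg_idx[seq_len(cfg$n_true_meqtls)]
    meqtl_variant <- vapply(meqtl_cpg_idx, function(i) {
      in_block <- which(layout$variants$block == probes$block[i])
      layout$variants$id[sample(in_block, 1L)]
    }, character(1))
    meqtl_effects <- data.frame(
      variant = meqtl_variant,
      cpg = probes$id[meqtl_cpg_idx],
      beta = sample(c(-1, 1), cfg$n_true_meqtls, replace = TRUE) *
        stats::runif(cfg$n_true_meqtls, cfg$meqtl_beta_range[1],
                     cfg$meqtl_beta_range[2]),
      stringsAsFactors = FALSE)

    exp_snp <- sample(meqtl_variant, min(cfg$n_exposure_snps,
                                         length(meqtl_variant)))
    exposure_snp_effects <- data.frame(
      variant = exp_snp,
      logor = cfg$exposure_logor * sample(c(-1, 1), length(exp_snp),
                                          replace = TRUE),
      stringsAsFactors = FALSE)

    traits <- sprintf("trait_%02d", seq_len(cfg$n_catalog_traits))
    outcome_traits <- traits[seq_len(cfg$n_outcome_traits)]
    causal_gamma <- stats::setNames(rep(cfg$causal_gamma,
                                        cfg$n_outcome_traits), outcome_traits)
    pleiotropic_variants <- sample(exp_snp, min(cfg$n_pleiotropic,
                                                length(exp_snp)))

    # Cell-type profiles: the leading n_cell_ref_cpgs CpGs discriminate
    # strongly between cell types; remaining CpGs carry mild loadings.
    profiles <- matrix(stats::rnorm(cfg$n_cpgs * cfg$n_cell_types, 0, 0.3),
                       nrow = cfg$n_cpgs,
                       dimnames = list(probes$id,
                                       paste0("cell", seq_len(cfg$n_cell_types))))
    ref_idx <- seq_len(cfg$n_cell_ref_cpgs)
    profiles[ref_idx, ] <- stats::rnorm(cfg$n_cell_ref_cpgs * cfg$n_cell_types,
                                        0, 2)

    baseline <- stats::rnorm(cfg$n_cpgs, 0, 1.5)
    # mild covariate effects on methylation (shared across cohorts)
    age_idx <- sample.int(cfg$n_cpgs, round(0.1 * cfg$n_cpgs))
    age_eff <- numeric(cfg$n_cpgs)
    age_eff[age_idx] <- stats::rnorm(length(age_idx), 0, 0.01)
    tob_idx <- sample.int(cfg$n_cpgs, round(0.05 * cfg$n_cpgs))
    tob_eff <- numeric(cfg$n_cpgs)
    tob_eff[tob_idx] <- stats::rnorm(length(tob_idx), 0, 0.3)
    tech_loading <- stats::rnorm(cfg$n_cpgs, 0, 0.3)

    enriched_traits <- traits[seq_len(cfg$n_enriched_traits)]
    structure(list(meqtl_effects = meqtl_effects,
                   exposure_cpg_effects = exposure_cpg_effects,
                   exposure_snp_effects = exposure_snp_effects,
                   causal_gamma = causal_gamma,
                   pleiotropic_variants = pleiotropic_variants,
                   cell_profiles = profiles,
                   cell_ref_cpgs = probes$id[ref_idx],
                   baseline = baseline, age_eff = age_eff,
                   tob_eff = tob_eff, tech_loading = tech_loading,
                   traits = traits, enriched_traits = enriched_traits,
                   outcome_traits = outcome_traits),
              class = "synthetic_truth")
  })
}

logistic_linpred <- function(G, truth) {
  eff <- truth$exposure_snp_effects
  if (is.null(eff) || nrow(eff) == 0L) return(rep(0, nrow(G$dosage)))
  idx <- match(eff$variant, G$variants$id)
  if (anyNA(idx)) stop("exposure_snp_effects keyed to unknown variants",
                       call. = FALSE)
  d <- G$dosage[, idx, drop = FALSE]
  d[is.na(d)] <- 0
  as.numeric(d %*% eff$logor)
}

#' Simulate a binary exposure from genotypes
#'
#' Logistic model: `logit P(Y=1) = intercept + sum(logor * dosage)`, with
#' the intercept tuned numerically so the expected prevalence matches the
#' target.
#'
#' @param G a [genotype_matrix()]
#' @param truth a [simulate_truth()] object (its `exposure_snp_effects` are
#'   used)
#' @param cfg a [sim_config()]
#' @param prevalence target prevalence
#' @param seed integer seed
#' @return integer 0/1 vector named by sample id
#' @export
simulate_exposure <- function(G, truth, cfg,
                              prevalence = cfg$prevalence[[1L]],
                              seed = cfg$seed) {
  lp <- logistic_linpred(G, truth)
  f <- function(c0) mean(stats::plogis(c0 + lp)) - prevalence
  c0 <- stats::uniroot(f, c(-30, 30))$root
  with_seed(seed + 202L, {
    y <- stats::rbinom(length(lp), 1L, stats::plogis(c0 + lp))
    stats::setNames(as.integer(y), rownames(G$dosage))
  })
}

#' Simulate sample covariates
#'
#' Age, tobacco use, alcohol use, log10 viral load, medication adherence and
#' white blood count; tobacco and alcohol rates are higher among exposed
#' samples, mirroring the emulated cohort.
#'
#' @param Y 0/1 exposure vector named by sample
#' @param cfg a [sim_config()]
#' @param seed integer seed
#' @return data.frame of covariates with a `sample_id` column
#' @export
simulate_covariates <- function(Y, cfg, seed = cfg$seed) {
  n <- length(Y)
  with_seed(seed + 303L, {
    data.frame(sample_id = names(Y),
               exposure = as.integer(Y),
               age = stats::rnorm(n, 49, 7),
               tobacco = stats::rbinom(n, 1L, 0.45 + 0.35 * Y),
               alcohol = stats::rbinom(n, 1L, 0.33 + 0.2 * Y),
               log10_viral_load = stats::rnorm(n, 2.5, 1.4),
               adherence = stats::rbinom(n, 1L, 0.76),
               wbc = stats::rnorm(n, 5.5, 1.5),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a cohort methylome with planted effects
#'
#' M-values are built additively: CpG baseline + planted cis SNP effects +
#' planted exposure effects + covariate effects + cell-mixture term
#' (Dirichlet proportions times cell profiles) + a per-cohort batch shift +
#' a control-probe-correlated technical factor + Gaussian noise.
#'
#' @param G cohort [genotype_matrix()] (complete dosages)
#' @param Y 0/1 exposure vector
#' @param covs covariate data.frame from [simulate_covariates()]
#' @param truth a [simulate_truth()] object
#' @param cfg a [sim_config()]
#' @param probes probe table
#' @param cohort cohort label
#' @param seed integer seed
#' @return list with `M` (a [methylation_matrix()]), `controls` (samples x
#'   control probes), `cell_props` (truth proportions), `detection_p`
#' @export
simulate_methylome <- function(G, Y, covs, truth, cfg, probes,
                               cohort = "450K", seed = cfg$seed) {
  n <- nrow(G$dosage)
  with_seed(seed + 404L, {
    M <- matrix(rep(truth$baseline, each = n), nrow = n)
    dimnames(M) <- list(rownames(G$dosage), probes$id)
    me <- truth$meqtl_effects
    vidx <- match(me$variant, G$variants$id)
    cidx <- match(me$cpg, probes$id)
    for (j in seq_len(nrow(me))) {
      d <- G$dosage[, vidx[j]]
      d[is.na(d)] <- mean(d, na.rm = TRUE)
      M[, cidx[j]] <- M[, cidx[j]] + me$beta[j] * d
    }
    ee <- truth$exposure_cpg_effects
    eidx <- match(ee$cpg, probes$id)
    M[, eidx] <- M[, eidx] + outer(as.numeric(Y), ee$effect)
    M <- M + outer(covs$age - mean(covs$age), truth$age_eff)
    M <- M + outer(as.numeric(covs$tobacco), truth$tob_eff)

    cell_props <- rdirichlet_mat(n, cfg$cell_alpha)
    colnames(cell_props) <- colnames(truth$cell_profiles)
    rownames(cell_props) <- rownames(G$dosage)
    M <- M + cell_props %*% t(truth$cell_profiles)

    batch <- stats::rnorm(cfg$n_cpgs, 0, cfg$batch_sd)
    M <- M + rep(batch, each = n)

    # unmeasured within-cohort batch structure (plate/position effects):
    # the residual-PC adjustment exists to capture exactly this
    U <- matrix(stats::rnorm(n * cfg$n_batch_factors), nrow = n)
    L <- matrix(stats::rnorm(cfg$n_cpgs * cfg$n_batch_factors, 0,
                             cfg$batch_factor_sd), ncol = cfg$n_batch_factors)
    M <- M + U %*% t(L)

    tech <- stats::rnorm(n)
    M <- M + outer(tech, truth$tech_loading)
    control_load <- stats::rnorm(cfg$n_control_probes, 0.5, 0.1)
    controls <- outer(tech, control_load) +
      matrix(stats::rnorm(n * cfg$n_control_probes, 0, 0.1), nrow = n)
    dimnames(controls) <- list(rownames(G$dosage),
                               sprintf("ctrl%03d", seq_len(cfg$n_control_probes)))

    M <- M + matrix(stats::rnorm(n * cfg$n_cpgs, 0, cfg$noise_sd), nrow = n)

    detection_p <- matrix(10^stats::runif(n * cfg$n_cpgs, -30, -14), nrow = n,
                          dimnames = dimnames(M))
    n_fail <- round(cfg$detection_fail_rate * cfg$n_cpgs)
    if (n_fail > 0) {
      fail_cpg <- sample.int(cfg$n_cpgs, n_fail)
      fail_sample <- sample.int(n, n_fail, replace = TRUE)
      detection_p[cbind(fail_sample, fail_cpg)] <- 10^stats::runif(n_fail, -11, -2)
    }
    list(M = methylation_matrix(M, probes[, c("id", "chrom", "pos")],
                                cohort = cohort, value_kind = "m"),
         controls = controls, cell_props = cell_props,
         detection_p = detection_p)
  })
}

#' Simulate an external outcome GWAS
#'
#' A fresh cohort sharing only allele frequencies and LD with the discovery
#' cohort is simulated; the outcome is `gamma * exposure` plus direct
#' effects of the pleiotropic variants plus noise, and each variant's
#' ancestry-adjusted marginal regression slope and SE are reported as
#' summary statistics (published GWAS adjust for genotype principal
#' components; without the adjustment, admixture stratification leaks the
#' pleiotropic effects coherently into every variant's marginal estimate).
#'
#' @param truth a [simulate_truth()] object
#' @param cfg a [sim_config()]
#' @param freqs population frequency matrix
#' @param trait outcome trait label (indexes `truth$causal_gamma`)
#' @param study study identifier written into the table
#' @param layout genome layout
#' @param seed integer seed
#' @return data.frame: variant, effect_allele, other_allele, beta, se, p, n,
#'   trait, study
#' @export
simulate_outcome_gwas <- function(truth, cfg, freqs, trait = NULL,
                                  study = "study_1",
                                  layout = sim_layout(cfg),
                                  seed = cfg$seed) {
  if (is.null(trait)) trait <- names(truth$causal_gamma)[1L]
  gamma <- truth$causal_gamma[[trait]]
  with_seed(seed + 505L, {
    pr <- simulate_admixture_props(cfg, cfg$outcome_n,
                                   seed = seed + 515L)
    G <- simulate_admixed_cohort(freqs, pr$props, cfg, layout,
                                 seed = seed + 525L, sample_prefix = "o")
    Y <- simulate_exposure(G, truth, cfg,
                           prevalence = mean(cfg$prevalence),
                           seed = seed + 535L)
    outcome <- gamma * as.numeric(Y)
    if (length(truth$pleiotropic_variants)) {
      pid <- match(truth$pleiotropic_variants, G$variants$id)
      outcome <- outcome +
        as.numeric(G$dosage[, pid, drop = FALSE] %*%
                     rep(cfg$pleiotropy_effect, length(pid)))
    }
    outcome <- outcome + stats::rnorm(cfg$outcome_n)
    # marginal regressions adjusted for ancestry (admixture proportions),
    # as published GWAS adjust for genotype PCs
    sumstats <- marginal_ols(G$dosage, outcome,
                             covar = pr$props[, -1L, drop = FALSE])
    data.frame(variant = G$variants$id,
               effect_allele = G$variants$alt,
               other_allele = G$variants$ref,
               beta = sumstats$beta, se = sumstats$se, p = sumstats$p,
               n = cfg$outcome_n, trait = trait, study = study,
               stringsAsFactors = FALSE)
  })
}

# Vectorized per-column linear regression of y on each column of X,
# optionally adjusted for a shared covariate matrix (Frisch-Waugh
# partialling with full-model residual degrees of freedom).
marginal_ols <- function(X, y, covar = NULL) {
  n <- length(y)
  if (is.null(covar)) {
    Xc <- scale(X, center = TRUE, scale = FALSE)
    yc <- y - mean(y)
    df <- n - 2L
  } else {
    Z <- cbind(1, as.matrix(covar))
    qz <- qr(Z)
    Xc <- X - Z %*% qr.coef(qz, X)
    yc <- as.numeric(y - Z %*% qr.coef(qz, y))
    df <- n - qz$rank - 1L
  }
  sxx <- colSums(Xc^2)
  sxy <- as.numeric(crossprod(Xc, yc))
  beta <- sxy / sxx
  sse <- sum(yc^2) - beta^2 * sxx
  se <- sqrt(pmax(sse, 0) / df / sxx)
  tt <- beta / se
  p <- 2 * stats::pt(-abs(tt), df = df)
  mono <- sxx == 0
  beta[mono] <- 0; se[mono] <- Inf; p[mono] <- 1
  list(beta = beta, se = se, p = p)
}

#' Simulate a GWAS-catalog-style trait table
#'
#' Enriched traits draw their risk variants preferentially (by
#' `enrichment_factor`) from the LD blocks carrying planted meQTLs and
#' receive genome-wide-significant p-values; null traits draw uniformly
#' from the variant universe with sub-threshold p-values.
#'
#' @param truth a [simulate_truth()] object
#' @param enrichment_factor sampling weight multiplier for planted meQTL
#'   blocks (1 = no enrichment)
#' @param cfg a [sim_config()]
#' @param layout genome layout
#' @param seed integer seed
#' @return data.frame: variant, trait, domain, p, study
#' @export
simulate_catalog <- function(truth, enrichment_factor = cfg$enrichment_factor,
                             cfg, layout = sim_layout(cfg),
                             seed = cfg$seed) {
  variants <- layout$variants
  meqtl_blocks <- unique(variants$block[match(truth$meqtl_effects$variant,
                                              variants$id)])
  in_meqtl_block <- variants$block %in% meqtl_blocks
  domains <- c("immunological", "metabolic", "cardiovascular", "psychiatric",
               "skeletal", "nutritional")
  with_seed(seed + 606L, {
    rows <- lapply(seq_along(truth$traits), function(t_i) {
      trait <- truth$traits[t_i]
      enriched <- trait %in% truth$enriched_traits
      w <- rep(1, nrow(variants))
      if (enriched) w[in_meqtl_block] <- enrichment_factor
      n_risk <- min(cfg$n_risk_per_trait, nrow(variants))
      risk <- sample(variants$id, n_risk, prob = w / sum(w))
      p <- if (enriched) 10^stats::runif(n_risk, -14, -8)
           else 10^stats::runif(n_risk, -4, -1.4)
      data.frame(variant = risk, trait = trait,
                 domain = domains[(t_i - 1L) %% length(domains) + 1L],
                 p = p, study = sprintf("study_%02d", t_i),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate and write a complete synthetic input bundle
#'
#' Runs every generator with seeds derived from `cfg$seed`, writes all
#' on-disk artifacts (dosage TSVs, methylation + probe TSVs, covariate,
#' control-probe, cell-reference, detection-p, outcome summary-stat and
#' catalog TSVs, a gene BED, and a ground-truth JSON) under `dir`, and
#' returns the in-memory objects.
#'
#' @param cfg a [sim_config()]
#' @param dir output directory (created if missing); `NULL` skips writing
#' @return a `synthetic_bundle` list
#' @export
simulate_bundle <- function(cfg = sim_config(), dir = NULL) {
  seed <- cfg$seed
  panel <- simulate_reference_panel(cfg, seed)
  probes <- sim_probes(cfg, panel$layout, seed + 7L)
  truth <- simulate_truth(cfg, panel$layout, probes, seed)

  cohorts <- names(cfg$n_cohort)
  cohort_data <- list()
  offset <- 0L
  for (ci in seq_along(cohorts)) {
    co <- cohorts[ci]
    n <- cfg$n_cohort[[co]]
    pr <- simulate_admixture_props(cfg, n, seed + 1000L * ci)
    G <- simulate_admixed_cohort(panel$freqs, pr$props, cfg, panel$layout,
                                 seed = seed + 1000L * ci + 1L,
                                 sample_prefix = paste0(tolower(gsub("[^A-Za-z0-9]", "", co)), "_"))
    Y <- simulate_exposure(G, truth, cfg, prevalence = cfg$prevalence[[co]],
                           seed = seed + 1000L * ci + 2L)
    covs <- simulate_covariates(Y, cfg, seed + 1000L * ci + 3L)
    meth <- simulate_methylome(G, Y, covs, truth, cfg, probes, cohort = co,
                               seed = seed + 1000L * ci + 4L)
    # observed genotypes: mask a fraction of dosages as missing
    G_obs <- G
    G_obs$dosage <- with_seed(seed + 1000L * ci + 5L, {
      d <- G$dosage
      miss <- stats::runif(length(d)) < cfg$missing_rate
      d[miss] <- NA_real_
      d
    })
    cohort_data[[co]] <- list(G = G_obs, G_complete = G, Y = Y, covs = covs,
                              meth = meth, admix = pr)
    offset <- offset + n
  }

  studies <- list()
  s_i <- 0L
  for (trait in truth$outcome_traits) {
    n_study <- if (trait == truth$outcome_traits[1L]) 2L else 1L
    for (k in seq_len(n_study)) {
      s_i <- s_i + 1L
      sid <- sprintf("gwas_%02d", s_i)
      studies[[sid]] <- simulate_outcome_gwas(truth, cfg, panel$freqs,
                                              trait = trait, study = sid,
                                              layout = panel$layout,
                                              seed = seed + 5000L + 7L * s_i)
    }
  }

  catalog <- simulate_catalog(truth, cfg$enrichment_factor, cfg,
                              panel$layout, seed)
  genes <- with_seed(seed + 808L, {
    n_genes <- 2L * panel$layout$n_blocks
    locus <- rep(seq_len(panel$layout$n_blocks), each = 2L)
    start <- panel$layout$block_center[locus] +
      as.integer(round(stats::runif(n_genes, -8e5, 6e5)))
    data.frame(gene = sprintf("GENE%04d", seq_len(n_genes)),
               chrom = panel$layout$block_chrom[locus],
               start = pmax(start, 1L),
               end = pmax(start, 1L) +
                 as.integer(round(stats::runif(n_genes, 5e3, 2e5))),
               stringsAsFactors = FALSE)
  })

  bundle <- structure(list(cfg = cfg, panel = panel, probes = probes,
                           truth = truth, cohorts = cohort_data,
                           outcome_gwas = studies, catalog = catalog,
                           genes = genes),
                      class = "synthetic_bundle")
  if (!is.null(dir)) bundle$paths <- write_bundle(bundle, dir)
  bundle
}

#' Reconstruct the path list of a written bundle directory
#'
#' @param dir bundle directory (as written by [simulate_bundle()])
#' @param cohorts cohort labels
#' @return named list of file paths as `simulate_bundle()` returns
#' @export
bundle_paths <- function(dir, cohorts = c("450K", "EPIC")) {
  p <- function(...) file.path(dir, paste0(...))
  paths <- list(ref_genotypes = p("reference_genotypes.tsv"),
                ref_labels = p("reference_labels.tsv"),
                gene_bed = p("genes.bed"),
                catalog = p("catalog.tsv"),
                cell_reference = p("cell_reference.tsv"),
                truth = p("truth.json"))
  for (co in cohorts) {
    tag <- tolower(gsub("[^A-Za-z0-9]", "", co))
    for (part in c("genotypes", "methylation", "probes", "covariates",
                   "controls", "detection"))
      paths[[paste0(part, "_", tag)]] <- p(part, "_", tag, ".tsv")
  }
  for (f in sort(list.files(dir, pattern = "^outcome_.*\\.tsv$")))
    paths[[sub("\\.tsv$", "", f)]] <- file.path(dir, f)
  paths
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, paste0(...))
  paths <- list(ref_genotypes = p("reference_genotypes.tsv"),
                ref_labels = p("reference_labels.tsv"),
                gene_bed = p("genes.bed"),
                catalog = p("catalog.tsv"),
                truth = p("truth.json"))
  write_dosage_tsv(bundle$panel$G, paths$ref_genotypes)
  utils::write.table(data.frame(sample_id = rownames(bundle$panel$G$dosage),
                                population = bundle$panel$labels),
                     paths$ref_labels, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bed <- data.frame(chrom = bundle$genes$chrom,
                    start = bundle$genes$start - 1L,  # BED 0-based half-open
                    end = bundle$genes$end,
                    name = bundle$genes$gene)
  utils::write.table(bed, paths$gene_bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(bundle$catalog, paths$catalog, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (co in names(bundle$cohorts)) {
    cd <- bundle$cohorts[[co]]
    tag <- tolower(gsub("[^A-Za-z0-9]", "", co))
    paths[[paste0("genotypes_", tag)]] <- p("genotypes_", tag, ".tsv")
    write_dosage_tsv(cd$G, paths[[paste0("genotypes_", tag)]])
    paths[[paste0("methylation_", tag)]] <- p("methylation_", tag, ".tsv")
    paths[[paste0("probes_", tag)]] <- p("probes_", tag, ".tsv")
    write_methylation_tsv(cd$meth$M, paths[[paste0("methylation_", tag)]],
                          paths[[paste0("probes_", tag)]])
    paths[[paste0("covariates_", tag)]] <- p("covariates_", tag, ".tsv")
    utils::write.table(cd$covs, paths[[paste0("covariates_", tag)]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[paste0("controls_", tag)]] <- p("controls_", tag, ".tsv")
    utils::write.table(cbind(sample_id = rownames(cd$meth$controls),
                             as.data.frame(cd$meth$controls)),
                       paths[[paste0("controls_", tag)]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths[[paste0("detection_", tag)]] <- p("detection_", tag, ".tsv")
    utils::write.table(cbind(sample_id = rownames(cd$meth$detection_p),
                             as.data.frame(cd$meth$detection_p)),
                       paths[[paste0("detection_", tag)]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  # the on-disk reference is the expected M-value of each purified cell
  # type at the reference CpGs (baseline + cell profile), as a published
  # deconvolution reference would be
  ref_idx <- match(bundle$truth$cell_ref_cpgs, bundle$probes$id)
  ref_profiles <- bundle$truth$cell_profiles[bundle$truth$cell_ref_cpgs, ] +
    bundle$truth$baseline[ref_idx]
  paths$cell_reference <- p("cell_reference.tsv")
  utils::write.table(cbind(cpg = rownames(ref_profiles),
                           as.data.frame(ref_profiles)),
                     paths$cell_reference, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (sid in names(bundle$outcome_gwas)) {
    paths[[paste0("outcome_", sid)]] <- p("outcome_", sid, ".tsv")
    utils::write.table(bundle$outcome_gwas[[sid]],
                       paths[[paste0("outcome_", sid)]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  truth_json <- list(
    meqtl_effects = bundle$truth$meqtl_effects,
    exposure_cpg_effects = bundle$truth$exposure_cpg_effects,
    exposure_snp_effects = bundle$truth$exposure_snp_effects,
    causal_gamma = as.list(bundle$truth$causal_gamma),
    pleiotropic_variants = bundle$truth$pleiotropic_variants,
    enriched_traits = bundle$truth$enriched_traits)
  jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                       digits = NA)
  paths
}
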