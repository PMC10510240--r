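test_that("reference panel is a pure function of (config, seed)", {
  cfg <- small_sim_config()
  p1 <- simulate_reference_panel(cfg)
  p2 <- simulate_reference_panel(cfg)
  expect_identical(p1$G$dosage, p2$G$dosage)
  expect_identical(p1$freqs, p2$freqs)
  expect_equal(dim(p1$freqs), c(4L, cfg$n_snps))
  expect_true(all(p1$G$dosage %in% 0:2))
})

test_that("population frequencies approach the ancestral frequency as Fst shrinks", {
  cfg <- sim_config(fst = rep(0.005, 4), n_ref_per_pop = 50L,
                    n_snps = 600L, n_cpgs = 10L, n_true_meqtls = 2L,
                    n_true_exposure_cpgs = 2L, n_exposure_snps = 2L,
                    n_cell_ref_cpgs = 5L, seed = 3L)
  p <- simulate_reference_panel(cfg)
  p0 <- p$p0_block[sim_layout(cfg)$variants$block]
  # Beta(p0(1-F)/F, ...) has SD sqrt(F p0 (1-p0)); at F = 0.005 the spread
  # around p0 is ~0.03
  expect_lt(mean(abs(p$freqs[1, ] - p0)), 0.04)
  expect_lt(mean(abs(p$freqs[3, ] - p0)), 0.04)
})

test_that("top-2 PCs separate four Balding-Nichols populations", {
  cfg <- sim_config(fst = rep(0.1, 4), n_ref_per_pop = 200L, n_snps = 2000L,
                    ld_r = 0, n_cpgs = 10L, n_true_meqtls = 2L,
                    n_true_exposure_cpgs = 2L, n_exposure_snps = 2L,
                    n_cell_ref_cpgs = 5L, seed = 11L)
  p <- simulate_reference_panel(cfg)
  pca <- genotype_pca(p$G, p$G, n_pc = 2L)
  sil <- cluster::silhouette(as.integer(factor(p$labels)),
                             dist(pca$ref_scores))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("admixed cohort frequencies follow the mixture", {
  cfg <- small_sim_config(seed = 21L)
  p <- simulate_reference_panel(cfg)
  n <- 600L
  # degenerate mixture: all ancestry from population 1
  props1 <- matrix(rep(c(1, 0, 0, 0), each = n), nrow = n)
  G1 <- simulate_admixed_cohort(p$freqs, props1, cfg, p$layout, seed = 5L)
  af <- colMeans(G1$dosage) / 2
  se <- sqrt(p$freqs[1, ] * (1 - p$freqs[1, ]) / (2 * n))
  expect_gt(mean(abs(af - p$freqs[1, ]) <= 3 * se), 0.98)

  # 50/50 mixture: expected dosage = p1 + p2
  props2 <- matrix(rep(c(0.5, 0.5, 0, 0), each = n), nrow = n)
  G2 <- simulate_admixed_cohort(p$freqs, props2, cfg, p$layout, seed = 6L)
  expect_lt(mean(abs(colMeans(G2$dosage) -
                       (p$freqs[1, ] + p$freqs[2, ]))), 0.05)

  expect_error(simulate_admixed_cohort(p$freqs, props2 * 2, cfg, p$layout),
               "sum to 1")
})

test_that("within-block dosage correlation matches the configured value", {
  cfg <- small_sim_config(seed = 31L)
  p <- simulate_reference_panel(cfg)
  n <- 500L
  props <- matrix(rep(c(1, 0, 0, 0), each = n), nrow = n)
  G <- simulate_admixed_cohort(p$freqs, props, cfg, p$layout, seed = 9L)
  blocks <- p$layout$variants$block
  cors <- unlist(lapply(unique(blocks)[1:20], function(b) {
    cols <- which(blocks == b)
    cm <- cor(G$dosage[, cols])
    cm[upper.tri(cm)]
  }))
  expect_lt(abs(mean(cors) - cfg$ld_r), 0.1)
})

test_that("exposure prevalence and planted log-odds are recovered", {
  cfg <- small_sim_config(seed = 41L)
  p <- simulate_reference_panel(cfg)
  layout <- p$layout
  probes <- meqtlmr:::sim_probes(cfg, layout, 48L)
  truth <- simulate_truth(cfg, layout, probes, seed = 41L)

  n <- 2000L
  props <- matrix(rep(c(1, 0, 0, 0), each = n), nrow = n)
  G <- simulate_admixed_cohort(p$freqs, props, cfg, layout, seed = 10L)

  # null model: no genetic effects
  truth0 <- truth
  truth0$exposure_snp_effects <- truth$exposure_snp_effects[0, ]
  y0 <- simulate_exposure(G, truth0, cfg, prevalence = 0.39, seed = 12L)
  expect_lt(abs(mean(y0) - 0.39), 3 * sqrt(0.39 * 0.61 / n))

  # single-SNP model recovers its log-odds ratio by logistic refit
  truth1 <- truth0
  truth1$exposure_snp_effects <- data.frame(
    variant = layout$variants$id[1], logor = 0.5)
  y1 <- simulate_exposure(G, truth1, cfg, prevalence = 0.39, seed = 13L)
  fit <- glm(y1 ~ G$dosage[, 1], family = binomial())
  est <- coef(summary(fit))[2, ]
  expect_lt(abs(est["Estimate"] - 0.5), 3 * est["Std. Error"])

  expect_identical(y1, simulate_exposure(G, truth1, cfg, prevalence = 0.39,
                                         seed = 13L))
})

test_that("methylome equals baseline plus cell mixture when effects and noise vanish", {
  cfg <- small_sim_config(seed = 51L, noise_sd = 0, batch_sd = 0,
                          n_batch_factors = 1L, batch_factor_sd = 0,
                          detection_fail_rate = 0)
  p <- simulate_reference_panel(cfg)
  probes <- meqtlmr:::sim_probes(cfg, p$layout, 58L)
  truth <- simulate_truth(cfg, p$layout, probes, seed = 51L)
  truth$meqtl_effects$beta[] <- 0
  truth$exposure_cpg_effects$effect[] <- 0
  truth$age_eff[] <- 0
  truth$tob_eff[] <- 0
  truth$tech_loading[] <- 0

  n <- 50L
  props <- matrix(rep(c(1, 0, 0, 0), each = n), nrow = n)
  G <- simulate_admixed_cohort(p$freqs, props, cfg, p$layout, seed = 15L)
  Y <- simulate_exposure(G, truth, cfg, seed = 16L)
  covs <- simulate_covariates(Y, cfg, seed = 17L)
  meth <- simulate_methylome(G, Y, covs, truth, cfg, probes, seed = 18L)
  expected <- matrix(rep(truth$baseline, each = n), nrow = n) +
    meth$cell_props %*% t(truth$cell_profiles)
  expect_equal(unname(meth$M$values), unname(expected), tolerance = 1e-10)
})

test_that("a planted cis effect is recovered by per-pair OLS refit", {
  cfg <- small_sim_config(seed = 61L)
  p <- simulate_reference_panel(cfg)
  probes <- meqtlmr:::sim_probes(cfg, p$layout, 68L)
  truth <- simulate_truth(cfg, p$layout, probes, seed = 61L)
  truth$meqtl_effects <- truth$meqtl_effects[1, , drop = FALSE]
  truth$meqtl_effects$beta <- 0.4
  truth$exposure_cpg_effects$effect[] <- 0

  n <- 400L
  props <- matrix(rep(c(1, 0, 0, 0), each = n), nrow = n)
  G <- simulate_admixed_cohort(p$freqs, props, cfg, p$layout, seed = 20L)
  Y <- simulate_exposure(G, truth, cfg, seed = 21L)
  covs <- simulate_covariates(Y, cfg, seed = 22L)
  meth <- simulate_methylome(G, Y, covs, truth, cfg, probes, seed = 23L)
  g <- G$dosage[, truth$meqtl_effects$variant]
  m <- meth$M$values[, truth$meqtl_effects$cpg]
  fit <- coef(summary(lm(m ~ g)))[2, ]
  expect_lt(abs(fit["Estimate"] - 0.4), 3 * fit["Std. Error"])
})

test_that("outcome GWAS carries the planted causal effect and a null when gamma = 0", {
  cfg <- small_sim_config(seed = 71L, outcome_n = 4000L)
  p <- simulate_reference_panel(cfg)
  probes <- meqtlmr:::sim_probes(cfg, p$layout, 78L)
  truth <- simulate_truth(cfg, p$layout, probes, seed = 71L)
  truth$pleiotropic_variants <- character(0)

  ivs <- truth$exposure_snp_effects$variant
  exposure_betas <- function(gw) {
    idx <- match(ivs, gw$variant)
    make_mr_input(bx = truth$exposure_snp_effects$logor * 0.2,
                  by = gw$beta[idx], se_y = gw$se[idx])
  }
  # null causal effect
  truth0 <- truth
  truth0$causal_gamma[] <- 0
  gw0 <- simulate_outcome_gwas(truth0, cfg, p$freqs, layout = p$layout,
                               seed = 30L)
  ivw0 <- mr_ivw(exposure_betas(gw0))
  expect_lt(abs(ivw0$estimate), 3 * ivw0$se)

  # bx used above is the scaled log-odds; refit bx in a fresh discovery
  # cohort for the recovery check so both sides are on the observed scale
  n <- 3000L
  props <- matrix(rep(c(1, 0, 0, 0), each = n), nrow = n)
  Gd <- simulate_admixed_cohort(p$freqs, props, cfg, p$layout, seed = 31L)
  Yd <- simulate_exposure(Gd, truth, cfg, seed = 32L)
  st <- meqtlmr:::marginal_ols(Gd$dosage[, ivs, drop = FALSE], as.numeric(Yd))
  gw1 <- simulate_outcome_gwas(truth, cfg, p$freqs, layout = p$layout,
                               seed = 33L)
  idx <- match(ivs, gw1$variant)
  inp <- data.frame(variant = ivs, beta_exposure = st$beta,
                    se_exposure = st$se, beta_outcome = gw1$beta[idx],
                    se_outcome = gw1$se[idx], status = "ok")
  ivw1 <- mr_ivw(inp)
  expect_lt(abs(ivw1$estimate - cfg$causal_gamma), 3 * ivw1$se)
})

test_that("catalog generator respects enrichment structure and determinism", {
  cfg <- small_sim_config(seed = 81L)
  p <- simulate_reference_panel(cfg)
  probes <- meqtlmr:::sim_probes(cfg, p$layout, 88L)
  truth <- simulate_truth(cfg, p$layout, probes, seed = 81L)
  cat1 <- simulate_catalog(truth, enrichment_factor = 8, cfg, p$layout,
                           seed = 81L)
  cat2 <- simulate_catalog(truth, enrichment_factor = 8, cfg, p$layout,
                           seed = 81L)
  expect_identical(cat1, cat2)
  expect_setequal(unique(cat1$trait), truth$traits)
  # enriched traits hit the planted meQTL blocks more often than null traits
  blocks <- p$layout$variants$block
  meqtl_blocks <- blocks[match(truth$meqtl_effects$variant,
                               p$layout$variants$id)]
  rate <- function(traits) {
    v <- cat1$variant[cat1$trait %in% traits]
    mean(blocks[match(v, p$layout$variants$id)] %in% meqtl_blocks)
  }
  expect_gt(rate(truth$enriched_traits),
            rate(setdiff(truth$traits, truth$enriched_traits)))
})
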