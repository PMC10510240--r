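# Small in-code fixtures shared across the suite.

# hand-written genotype matrix: 6 samples x 4 variants on two chromosomes
toy_genotypes <- function() {
  d <- rbind(c(0, 1, 2, 0),
             c(1, 1, 2, 0),
             c(2, 0, 1, 1),
             c(0, 2, 0, 2),
             c(1, NA, 1, 1),
             c(2, 1, 0, 2))
  rownames(d) <- paste0("s", 1:6)
  genotype_matrix(d, data.frame(
    id = c("rs1", "rs2", "rs3", "rs4"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    pos = c(100L, 5000L, 100L, 900L),
    ref = "A", alt = "G", stringsAsFactors = FALSE))
}

# Scaled-down simulation config for pipeline-level tests. Planted effects
# are scaled up as the cohorts are scaled down so per-test power stays
# comparable to the full-size design.
small_sim_config <- function(seed = 7L, ...) {
  args <- list(n_ref_per_pop = 60L,
               n_cohort = c("450K" = 140L, "EPIC" = 130L),
               n_snps = 400L, n_cpgs = 300L,
               n_true_meqtls = 12L, n_true_exposure_cpgs = 15L,
               n_exposure_snps = 12L, exposure_logor = 0.9,
               n_cell_ref_cpgs = 60L, n_control_probes = 25L,
               outcome_n = 1500L,
               n_catalog_traits = 10L, n_enriched_traits = 4L,
               seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# draw a random correlated genotype block for LD-based operations
random_dosage <- function(n, m, maf = 0.3, seed = 1) {
  withr::with_seed(seed, {
    matrix(rbinom(n * m, 2L, maf), nrow = n,
           dimnames = list(paste0("s", seq_len(n)), paste0("v", seq_len(m))))
  })
}

make_gm <- function(dosage, chrom = "chr1", pos = NULL) {
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  genotype_matrix(dosage, data.frame(
    id = colnames(dosage) %||% paste0("v", seq_len(m)),
    chrom = chrom, pos = pos, ref = "A", alt = "G",
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# harmonized MR input with known structure
make_mr_input <- function(bx, by, se_x = 0.02, se_y = 0.05) {
  data.frame(variant = paste0("iv", seq_along(bx)),
             beta_exposure = bx, se_exposure = se_x,
             beta_outcome = by, se_outcome = se_y,
             status = "ok", stringsAsFactors = FALSE)
}

# summary-level MR simulation: n_iv instruments, causal effect gamma,
# optional direct (pleiotropic) outcome effects
simulate_mr_summary <- function(n_iv = 30L, gamma = 0.3, se_x = 0.02,
                                se_y = 0.03, direct = numeric(n_iv),
                                seed = 1) {
  withr::with_seed(seed, {
    bx_true <- runif(n_iv, 0.05, 0.2) * sample(c(-1, 1), n_iv, TRUE)
    bx <- rnorm(n_iv, bx_true, se_x)
    by <- rnorm(n_iv, gamma * bx_true + direct, se_y)
    make_mr_input(bx, by, se_x, se_y)
  })
}
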