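#!/usr/bin/env Rscript

# Stage 1 — generate the synthetic study.
#
# Emulates the cohort design the pipeline targets: two methylation-array
# cohorts ("450K" N=423, ~39% exposed; "EPIC" N=388, ~33% exposed) drawn
# from an admixed population with a 4-population reference panel, planted
# cis SNP effects on CpG M-values, planted exposure effects, external
# outcome GWAS cohorts with a causal exposure effect (gamma = 0.3) plus a
# few horizontally pleiotropic variants, and a trait catalog enriched for
# the planted meQTL LD blocks. Ground truth is written alongside the data.

suppressMessages({ library(optparse); library(meqtlmr) })
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--dir", type = "character", default = "results/bundle"))))

cfg <- sim_config(seed = opts$seed)
bundle <- simulate_bundle(cfg, dir = opts$dir)

message(sprintf("cohorts: %s",
                paste(sprintf("%s n=%d", names(cfg$n_cohort), cfg$n_cohort),
                      collapse = ", ")))
message(sprintf("planted: %d cis meQTL effects (|beta| %.2f-%.2f), %d exposure CpGs, %d exposure SNPs",
                nrow(bundle$truth$meqtl_effects), cfg$meqtl_beta_range[1],
                cfg$meqtl_beta_range[2],
                nrow(bundle$truth$exposure_cpg_effects),
                nrow(bundle$truth$exposure_snp_effects)))
message(sprintf("outcome GWAS: %d studies over %d traits, causal gamma = %.2f, %d pleiotropic variants",
                length(bundle$outcome_gwas), cfg$n_outcome_traits,
                cfg$causal_gamma, length(bundle$truth$pleiotropic_variants)))
message("bundle written under ", opts$dir)
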