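#!/usr/bin/env Rscript

# Stage 6 — Mendelian randomization of the exposure on the overlap traits.
#
# Instruments are index meQTLs associated with the exposure (linear fit,
# p < 0.05; one per LD clump). Per outcome study: allele harmonization
# (palindromic variants dropped), IVW, weighted median, and the
# pleiotropy-residual outlier test with outlier-corrected re-estimation;
# Bonferroni family alpha / (studies x 3 methods), the scheme that gives
# 1.28E-3 for 13 pairs x 3 methods.

suppressMessages({ library(optparse); library(meqtlmr) })
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--dir", type = "character", default = "results/bundle"),
  make_option("--outdir", type = "character", default = "results"))))

config <- pipeline_config(seed = opts$seed, paths = bundle_paths(opts$dir))
cohort_inputs <- read_cohort_inputs(config$paths, config$cohorts)
ancestry <- read.delim(file.path(opts$outdir, "ancestry.tsv"))
cohort_inputs <- restrict_to_ancestry(cohort_inputs, ancestry,
                                      config$target_ancestry)
G_all <- genotype_matrix(do.call(rbind, lapply(cohort_inputs,
                                               function(ci) ci$G$dosage)),
                         cohort_inputs[[1]]$G$variants)
Y_all <- unlist(lapply(cohort_inputs, function(ci) ci$covs$exposure),
                use.names = FALSE)

index <- read.delim(file.path(opts$outdir, "index_meqtls.tsv"))
overlap <- read.delim(file.path(opts$outdir, "overlap_traits.tsv"))$trait

outcome_keys <- grep("^outcome_", names(config$paths), value = TRUE)
outcome_tables <- lapply(config$paths[outcome_keys], read.delim)
names(outcome_tables) <- sub("^outcome_", "", outcome_keys)
keep <- vapply(outcome_tables,
               function(ot) tolower(trimws(ot$trait[1])) %in% overlap,
               logical(1))
if (any(keep)) outcome_tables <- outcome_tables[keep]

mr <- run_mr(index, G_all, Y_all, outcome_tables, config)

write.table(mr$results, file.path(opts$outdir, "mr_results.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("%d instruments; %d study x method results; %d significant at p < %.3g",
                nrow(mr$instruments), nrow(mr$results),
                sum(mr$results$significant), mr$results$cutoff[1]))
print(mr$results[, c("study", "trait", "method", "estimate", "se", "p",
                     "significant")], digits = 3)
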