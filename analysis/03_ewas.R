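#!/usr/bin/env Rscript

# Stage 3 — exposure-associated candidate CpGs.
#
# Per cohort: probe QC (detection p <= 1e-12; no SNP within 10 bp),
# reference-based cell-type deconvolution, 20 control-probe PCs, 5
# residual PCs from the phenotype-free technical model, then the
# second-stage regression of M-values on the exposure. Cohorts are
# combined by fixed-effects inverse-variance meta-analysis and candidates
# kept at meta p < 1e-4.

suppressMessages({ library(optparse); library(meqtlmr) })
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--dir", type = "character", default = "results/bundle"),
  make_option("--outdir", type = "character", default = "results"))))

config <- pipeline_config(seed = opts$seed,
                          paths = bundle_paths(opts$dir))
cohort_inputs <- read_cohort_inputs(config$paths, config$cohorts)
ancestry <- read.delim(file.path(opts$outdir, "ancestry.tsv"))
cohort_inputs <- restrict_to_ancestry(cohort_inputs, ancestry,
                                      config$target_ancestry)

ref_tab <- read.delim(config$paths$cell_reference, check.names = FALSE)
cell_reference <- as.matrix(ref_tab[, -1]); rownames(cell_reference) <- ref_tab$cpg

ewas <- run_ewas(cohort_inputs, cell_reference, config)

write.table(ewas$meta, file.path(opts$outdir, "ewas_meta.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ewas$candidates, file.path(opts$outdir, "candidates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
for (co in names(ewas$covariate_sets))  # stage-4 covariates (no residual PCs)
  write.table(cbind(sample_id = cohort_inputs[[co]]$covs$sample_id,
                    ewas$covariate_sets[[co]]$technical),
              file.path(opts$outdir, paste0("covariates_technical_",
                                            tolower(gsub("[^A-Za-z0-9]", "", co)),
                                            ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("genomic inflation lambda = %.3f", ewas$lambda))
message(sprintf("%d candidate CpGs at meta p < %g (%d hypo, %d hyper)",
                nrow(ewas$candidates), config$candidate_p,
                attr(ewas$candidates, "n_hypo"),
                attr(ewas$candidates, "n_hyper")))
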