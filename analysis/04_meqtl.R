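#!/usr/bin/env Rscript

# Stage 4 — cis-meQTL mapping for the candidate CpGs.
#
# Genotype QC (MAF >= 0.05, missing <= 0.05, HWE p >= 1e-6) on the pooled
# cohorts, cis pairs within +/-500 kb, per-cohort per-pair regression with
# the stage-3 technical covariates, fixed-effects meta-analysis, a single
# BH-FDR family over all tested pairs (FDR < 0.05), greedy LD clumping
# (r2 > 0.1) into index meQTLs, and nearest-gene annotation.

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

candidates <- read.delim(file.path(opts$outdir, "candidates.tsv"))
meqtl_inputs <- lapply(names(cohort_inputs), function(co) {
  tag <- tolower(gsub("[^A-Za-z0-9]", "", co))
  C <- read.delim(file.path(opts$outdir,
                            paste0("covariates_technical_", tag, ".tsv")),
                  check.names = FALSE)
  list(M = cohort_inputs[[co]]$M, G = cohort_inputs[[co]]$G, C = C[, -1])
})
names(meqtl_inputs) <- names(cohort_inputs)

genes <- read_gene_bed(config$paths$gene_bed)
meqtl <- run_meqtl(candidates, meqtl_inputs, genes, config)

write.table(meqtl$pairs, file.path(opts$outdir, "meqtl_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(meqtl$significant, file.path(opts$outdir, "meqtl_significant.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(meqtl$index, file.path(opts$outdir, "index_meqtls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(variant = meqtl$G_qc$variants$id),
            file.path(opts$outdir, "tested_variants.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("%d pairs tested; %d at FDR < %g; %d index meQTLs over %d CpGs",
                nrow(meqtl$pairs), nrow(meqtl$significant), config$fdr,
                nrow(meqtl$index), length(unique(meqtl$index$cpg))))
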