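#!/usr/bin/env Rscript

# Stage 2 — genotype-based global ancestry.
#
# LD-prunes the reference panel (r2 <= 0.02), projects all cohort samples
# onto the reference PCA, estimates supervised admixture proportions
# (K = 4), flags admixed samples by PC1-PC3 centroid distance, and
# classifies everyone by KNN (k = 20) over 10 PCs + 4 proportions with an
# admixed training group. Downstream stages keep only the AFR-labelled
# samples, mirroring a single-ancestry study design.

suppressMessages({ library(optparse); library(meqtlmr) })
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--dir", type = "character", default = "results/bundle"),
  make_option("--outdir", type = "character", default = "results"))))

paths <- list(ref_genotypes = file.path(opts$dir, "reference_genotypes.tsv"),
              ref_labels = file.path(opts$dir, "reference_labels.tsv"))
config <- pipeline_config(seed = opts$seed)

G_ref <- read_genotypes(paths$ref_genotypes, format = "dosage")
ref_labels <- read.delim(paths$ref_labels)$population
tags <- c("450k", "epic")
G_list <- lapply(tags, function(tg)
  read_genotypes(file.path(opts$dir, paste0("genotypes_", tg, ".tsv")),
                 format = "dosage"))
G_all <- genotype_matrix(do.call(rbind, lapply(G_list, function(g) g$dosage)),
                         G_list[[1]]$variants)

ancestry <- run_ancestry(G_ref, ref_labels, G_all, config)
dir.create(opts$outdir, showWarnings = FALSE, recursive = TRUE)
write.table(ancestry, file.path(opts$outdir, "ancestry.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("label counts:")
print(table(ancestry$label))
message(sprintf("%d samples flagged admixed by centroid distance",
                sum(ancestry$admixed)))
message("wrote ", file.path(opts$outdir, "ancestry.tsv"))
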