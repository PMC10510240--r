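#!/usr/bin/env Rscript

# Stage 5 — pleiotropy screening of the index meQTLs.
#
# (a) PheWAS-style lookup: index meQTLs at meta p < 5e-8 are screened
# against the catalog; associations survive at p below the recomputed
# Bonferroni family (alpha / n_variants / n_studies, the scheme that gives
# 1.70E-07 for 62 variants x 4,756 studies). (b) Trait enrichment: a
# one-sided Fisher exact test on the 2x2 table over the tested-variant
# universe. Traits significant in both screens feed the MR stage.

suppressMessages({ library(optparse); library(meqtlmr) })
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--dir", type = "character", default = "results/bundle"),
  make_option("--outdir", type = "character", default = "results"))))

config <- pipeline_config(seed = opts$seed, paths = bundle_paths(opts$dir))
index <- read.delim(file.path(opts$outdir, "index_meqtls.tsv"))
sig <- read.delim(file.path(opts$outdir, "meqtl_significant.tsv"))
universe <- read.delim(file.path(opts$outdir, "tested_variants.tsv"))$variant
catalog <- read_catalog(config$paths$catalog)

pleio <- run_pleiotropy(index, unique(sig$variant), catalog, universe, config)

write.table(pleio$phewas$hits, file.path(opts$outdir, "phewas_hits.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(pleio$enrichment, file.path(opts$outdir, "enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(trait = pleio$overlap_traits),
            file.path(opts$outdir, "overlap_traits.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("PheWAS: %d significant traits at p < %.3g",
                length(unique(pleio$phewas$hits$trait)),
                pleio$phewas$threshold))
message(sprintf("enrichment: %d traits at Fisher p < %g",
                length(pleio$enriched_traits), config$alpha))
message(sprintf("overlap feeding MR: %s",
                paste(pleio$overlap_traits, collapse = ", ")))
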