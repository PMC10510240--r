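#' Read one cohort's pipeline inputs from a bundle
#'
#' Loads methylation, covariates, control probes, detection p-values and
#' genotypes for each cohort from the paths written by
#' [simulate_bundle()], verifying sample alignment.
#'
#' @param paths named path list (`bundle$paths` or `config$paths`)
#' @param cohorts cohort labels
#' @return named list per cohort with `M`, `covs`, `controls`,
#'   `detection_p`, `G`
#' @export
read_cohort_inputs <- function(paths, cohorts) {
  out <- list()
  for (co in cohorts) {
    tag <- tolower(gsub("[^A-Za-z0-9]", "", co))
    g <- function(name) paths[[paste0(name, "_", tag)]]
    M <- read_methylation(g("methylation"), g("probes"), value_kind = "m",
                          cohort = co)
    covs <- utils::read.delim(g("covariates"), stringsAsFactors = FALSE)
    ctrl_tab <- utils::read.delim(g("controls"), check.names = FALSE,
                                  stringsAsFactors = FALSE)
    controls <- as.matrix(ctrl_tab[, -1L, drop = FALSE])
    rownames(controls) <- ctrl_tab$sample_id
    det_tab <- utils::read.delim(g("detection"), check.names = FALSE,
                                 stringsAsFactors = FALSE)
    detection <- as.matrix(det_tab[, -1L, drop = FALSE])
    rownames(detection) <- det_tab$sample_id
    G <- read_genotypes(g("genotypes"), format = "dosage")
    check_sample_alignment(rownames(M$values), covs$sample_id,
                           rownames(controls), rownames(detection),
                           rownames(G$dosage))
    out[[co]] <- list(M = M, covs = covs, controls = controls,
                      detection_p = detection, G = G)
  }
  out
}

#' Restrict cohort inputs to one estimated ancestry group
#'
#' Subsets every per-cohort table to the samples the ancestry stage
#' labelled with `label` (the study design analyses genotype-derived
#' single-ancestry samples).
#'
#' @param cohort_inputs list from [read_cohort_inputs()]
#' @param ancestry data.frame from [run_ancestry()]
#' @param label ancestry label to keep
#' @return the subset cohort input list
#' @export
restrict_to_ancestry <- function(cohort_inputs, ancestry, label = "AFR") {
  keep_ids <- ancestry$sample_id[ancestry$label == label]
  n_dropped <- 0L
  for (co in names(cohort_inputs)) {
    ci <- cohort_inputs[[co]]
    keep <- ci$covs$sample_id %in% keep_ids
    n_dropped <- n_dropped + sum(!keep)
    ci$M$values <- ci$M$values[keep, , drop = FALSE]
    ci$covs <- ci$covs[keep, , drop = FALSE]
    ci$controls <- ci$controls[keep, , drop = FALSE]
    ci$detection_p <- ci$detection_p[keep, , drop = FALSE]
    ci$G$dosage <- ci$G$dosage[keep, , drop = FALSE]
    cohort_inputs[[co]] <- ci
  }
  stage_log("ancestry", sprintf("restricting to %s ancestry: %d samples dropped",
                                label, n_dropped))
  if (!any(vapply(cohort_inputs, function(ci) nrow(ci$covs) > 0, logical(1))))
    stop("ancestry: zero samples with target ancestry", call. = FALSE)
  cohort_inputs
}

write_stage_tsv <- function(x, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  stage_log("pipeline", sprintf("wrote %s (%d rows)", basename(path),
                                nrow(x)))
  path
}

#' Run the full pipeline on an input bundle
#'
#' Executes ancestry -> candidate-CpG selection -> cis-meQTL mapping ->
#' pleiotropy screening -> Mendelian randomization in order, reading every
#' input from `config$paths` (as written by [simulate_bundle()]) and
#' writing one TSV per stage into `outdir`. Deterministic given
#' `config$seed`; a stage with zero surviving records stops the pipeline
#' with a stage-named error.
#'
#' @param config a [pipeline_config()] whose `paths` point at a bundle
#' @param outdir output directory for stage TSVs
#' @return invisibly, a list of all stage results (ancestry, ewas, meqtl,
#'   pleiotropy, mr) plus the output paths
#' @export
run_pipeline <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- config$paths

  # --- stage 1: ancestry ----------------------------------------------------
  G_ref <- read_genotypes(paths$ref_genotypes, format = "dosage")
  ref_labels <- utils::read.delim(paths$ref_labels,
                                  stringsAsFactors = FALSE)$population
  cohort_inputs <- read_cohort_inputs(paths, config$cohorts)
  G_all <- genotype_matrix(do.call(rbind, lapply(cohort_inputs,
                                                 function(ci) ci$G$dosage)),
                           cohort_inputs[[1L]]$G$variants)
  ancestry <- run_ancestry(G_ref, ref_labels, G_all, config)
  if (!nrow(ancestry)) stop("ancestry: zero samples labelled", call. = FALSE)
  write_stage_tsv(ancestry, outdir, "ancestry")

  # downstream analyses are restricted to the target-ancestry samples
  if (!is.null(config$target_ancestry)) {
    cohort_inputs <- restrict_to_ancestry(cohort_inputs, ancestry,
                                          config$target_ancestry)
    G_all <- genotype_matrix(do.call(rbind, lapply(cohort_inputs,
                                                   function(ci) ci$G$dosage)),
                             cohort_inputs[[1L]]$G$variants)
  }

  # --- stage 2: candidate CpGs ----------------------------------------------
  cell_ref_tab <- utils::read.delim(paths$cell_reference, check.names = FALSE,
                                    stringsAsFactors = FALSE)
  cell_reference <- as.matrix(cell_ref_tab[, -1L, drop = FALSE])
  rownames(cell_reference) <- cell_ref_tab$cpg
  ewas <- run_ewas(cohort_inputs, cell_reference, config)
  write_stage_tsv(ewas$meta, outdir, "ewas_meta")
  write_stage_tsv(ewas$candidates, outdir, "candidates")

  # --- stage 3: cis-meQTLs --------------------------------------------------
  meqtl_inputs <- lapply(names(cohort_inputs), function(co) {
    ci <- cohort_inputs[[co]]
    list(M = ci$M, G = ci$G, C = ewas$covariate_sets[[co]]$technical)
  })
  names(meqtl_inputs) <- names(cohort_inputs)
  genes <- if (!is.null(paths$gene_bed)) read_gene_bed(paths$gene_bed)
           else NULL
  meqtl <- run_meqtl(ewas$candidates, meqtl_inputs, genes, config)
  write_stage_tsv(meqtl$pairs, outdir, "meqtl_pairs")
  write_stage_tsv(meqtl$index, outdir, "index_meqtls")

  # --- stage 4: pleiotropy --------------------------------------------------
  catalog <- read_catalog(paths$catalog)
  pleio <- run_pleiotropy(meqtl$index,
                          unique(meqtl$significant$variant), catalog,
                          universe = meqtl$G_qc$variants$id, config)
  if (!nrow(pleio$phewas$hits))
    stop("pleiotropy: zero PheWAS hits", call. = FALSE)
  write_stage_tsv(pleio$phewas$hits, outdir, "phewas_hits")
  write_stage_tsv(pleio$enrichment, outdir, "enrichment")
  write_stage_tsv(data.frame(trait = pleio$overlap_traits), outdir,
                  "overlap_traits")

  # --- stage 5: Mendelian randomization -------------------------------------
  outcome_keys <- grep("^outcome_", names(paths), value = TRUE)
  outcome_tables <- lapply(paths[outcome_keys], utils::read.delim,
                           stringsAsFactors = FALSE)
  names(outcome_tables) <- sub("^outcome_", "", outcome_keys)
  # restrict to studies whose trait survived both screens
  keep <- vapply(outcome_tables, function(ot)
    tolower(trimws(ot$trait[1L])) %in% pleio$overlap_traits, logical(1L))
  if (any(keep)) outcome_tables <- outcome_tables[keep]
  Y_all <- unlist(lapply(cohort_inputs, function(ci) ci$covs$exposure),
                  use.names = FALSE)
  mr <- run_mr(meqtl$index, G_all, Y_all, outcome_tables, config)
  if (!nrow(mr$results)) stop("mr: zero results", call. = FALSE)
  write_stage_tsv(mr$results, outdir, "mr_results")

  invisible(list(ancestry = ancestry, ewas = ewas, meqtl = meqtl,
                 pleiotropy = pleio, mr = mr, outdir = outdir))
}
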