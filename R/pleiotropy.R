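#' Bonferroni-style per-test threshold over a variant x study family
#'
#' `alpha / (n_variants * n_studies)` — e.g. 0.05/62/4756 = 1.70E-07 for a
#' 62-variant lookup against a 4,756-study catalog, or 0.05/13/3 = 1.28E-3
#' for 13 trait-study pairs each tested by 3 MR methods.
#'
#' @param alpha family-wise error rate
#' @param n_variants,n_studies family dimensions (>= 1)
#' @return the per-test threshold
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_variants, n_studies) {
  if (n_variants < 1 || n_studies < 1)
    stop("family sizes must be >= 1", call. = FALSE)
  alpha / (n_variants * n_studies)
}

#' PheWAS-style catalog lookup for top index meQTLs
#'
#' Restricts to index meQTLs with meta p below the genome-wide threshold,
#' collects every catalog association with p < 0.05 for those variants,
#' and keeps associations below the Bonferroni threshold
#' `alpha / (n selected variants x n studies in the catalog)`.
#'
#' @param index_meqtls data.frame of index records (variant, p)
#' @param catalog association table from [read_catalog()]
#' @param gw_threshold genome-wide meta p threshold selecting variants
#' @param alpha family-wise error rate
#' @param screen_p the per-variant collection screen
#' @return list: `hits` (significant variant-trait rows), `screened`
#'   (all collected rows), `threshold`, `n_selected`, `n_studies`
#' @export
phewas_lookup <- function(index_meqtls, catalog, gw_threshold = 5e-8,
                          alpha = 0.05, screen_p = 0.05) {
  sel <- unique(index_meqtls$variant[index_meqtls$p < gw_threshold])
  n_studies <- length(unique(catalog$study))
  if (!length(sel)) {
    warning("no index meQTL passes the genome-wide threshold", call. = FALSE)
    return(list(hits = catalog[0, ], screened = catalog[0, ],
                threshold = NA_real_, n_selected = 0L,
                n_studies = n_studies))
  }
  screened <- catalog[catalog$variant %in% sel & catalog$p < screen_p, ,
                      drop = FALSE]
  thr <- bonferroni_threshold(alpha, length(sel), n_studies)
  hits <- screened[screened$p < thr, , drop = FALSE]
  log_filter(sprintf("PheWAS p < %.3g (0.05/%d/%d)", thr, length(sel),
                     n_studies), nrow(screened), nrow(hits))
  rownames(hits) <- rownames(screened) <- NULL
  list(hits = hits, screened = screened, threshold = thr,
       n_selected = length(sel), n_studies = n_studies)
}

#' MeQTL trait-enrichment test
#'
#' For each trait D, builds the 2x2 table over the tested-variant universe
#' T with margins M (meQTL variants) and R (the trait's risk variants) and
#' overlap MR, and tests enrichment with a one-sided (greater) Fisher
#' exact test. The odds ratio is the cross-product `ad/bc` (infinite when
#' bc = 0). Traits whose risk set does not intersect the universe are
#' emitted with a `no_overlap` flag.
#'
#' @param meqtl_variants character vector of meQTL variant ids (subset of
#'   `universe`)
#' @param catalog association table (variant, trait at least)
#' @param universe all variants tested in the meQTL stage
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`
#' @return data.frame per trait: trait, T, M, R, MR, odds_ratio, p,
#'   no_overlap
#' @export
trait_enrichment <- function(meqtl_variants, catalog, universe,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  meqtl_variants <- unique(meqtl_variants)
  if (!all(meqtl_variants %in% universe))
    stop("meqtl_variants must be a subset of the universe", call. = FALSE)
  T_ <- length(unique(universe))
  M <- length(meqtl_variants)
  traits <- unique(catalog$trait)
  rows <- lapply(traits, function(tr) {
    risk_all <- unique(catalog$variant[catalog$trait == tr])
    risk <- intersect(risk_all, universe)
    if (length(risk) < length(risk_all))
      message(sprintf("[enrichment] %s: %d/%d risk variants in universe",
                      tr, length(risk), length(risk_all)))
    R <- length(risk)
    MR <- length(intersect(risk, meqtl_variants))
    a <- MR; b <- R - MR; c_ <- M - MR; d <- T_ - R - c_
    if (R == 0L) {
      return(data.frame(trait = tr, T = T_, M = M, R = 0L, MR = 0L,
                        odds_ratio = NA_real_, p = 1, no_overlap = TRUE,
                        stringsAsFactors = FALSE))
    }
    or <- if (b * c_ == 0) {
      if (a * d == 0) NA_real_ else Inf
    } else (a * d) / (b * c_)
    pv <- stats::fisher.test(matrix(c(a, c_, b, d), nrow = 2L),
                             alternative = alternative)$p.value
    data.frame(trait = tr, T = T_, M = M, R = R, MR = MR,
               odds_ratio = or, p = pv, no_overlap = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Intersect PheWAS and enrichment trait lists
#'
#' Case-normalized (lowercase, trimmed) exact-label intersection; the
#' result feeds the Mendelian-randomization outcome list.
#'
#' @param phewas_traits,enrichment_traits character vectors of trait labels
#' @return the normalized overlapping labels
#' @export
intersect_findings <- function(phewas_traits, enrichment_traits) {
  norm <- function(x) tolower(trimws(x))
  intersect(unique(norm(phewas_traits)), unique(norm(enrichment_traits)))
}

#' Run the full pleiotropy-screening stage
#'
#' @param index_meqtls index-meQTL data.frame (variant, p)
#' @param meqtl_variants all FDR-significant meQTL variants
#' @param catalog association table from [read_catalog()]
#' @param universe all variants tested in the meQTL stage
#' @param config a [pipeline_config()]
#' @return list: `phewas`, `enrichment`, `enriched_traits` (enrichment
#'   p < alpha), `overlap_traits`
#' @export
run_pleiotropy <- function(index_meqtls, meqtl_variants, catalog, universe,
                           config = pipeline_config()) {
  ph <- phewas_lookup(index_meqtls, catalog, gw_threshold = config$gw_p,
                      alpha = config$alpha)
  enr <- trait_enrichment(meqtl_variants, catalog, universe)
  enriched <- enr$trait[!enr$no_overlap & enr$p < config$alpha]
  overlap <- intersect_findings(ph$hits$trait, enriched)
  stage_log("pleiotropy",
            sprintf("%d PheWAS traits, %d enriched traits, %d overlap",
                    length(unique(ph$hits$trait)), length(enriched),
                    length(overlap)))
  list(phewas = ph, enrichment = enr, enriched_traits = enriched,
       overlap_traits = overlap)
}
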