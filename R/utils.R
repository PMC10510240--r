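#' @keywords internal
"_PACKAGE"

# Clamp values into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Log a filtering step
#'
#' Every filter in the pipeline reports how many records went in, how many
#' survived, and under which rule, so that stage survivor counts are auditable.
#'
#' @param rule short label of the filtering rule applied
#' @param n_in,n_out record counts before and after
#' @return invisibly, a one-row data.frame with the logged counts
#' @export
log_filter <- function(rule, n_in, n_out) {
  message(sprintf("[filter] %s: %d -> %d", rule, n_in, n_out))
  invisible(data.frame(rule = rule, n_in = n_in, n_out = n_out))
}

stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Verify that datasets share one ordered sample id list
#'
#' Genotype, methylation and covariate tables must be row-aligned; any
#' mismatch is an error, never a silent reindexing.
#'
#' @param ... two or more character vectors of sample ids
#' @return invisibly TRUE
#' @export
check_sample_alignment <- function(...) {
  ids <- list(...)
  if (length(ids) < 2L) return(invisible(TRUE))
  ref <- ids[[1L]]
  for (i in seq_along(ids)[-1L]) {
    if (!identical(as.character(ref), as.character(ids[[i]]))) {
      stop("sample ids are not identical and identically ordered across inputs (input ",
           i, " differs)", call. = FALSE)
    }
  }
  invisible(TRUE)
}
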