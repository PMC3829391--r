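#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a reporter-assay comparison
#'
#' @param x A [reporter_stats()] object.
#' @param ... Unused.
#' @return Per-group tibble with `condition`, `n`, `mean_ratio`, `sem`.
#' @export
tidy.reporter_stats <- function(x, ...) x$groups

#' @rdname tidy.reporter_stats
#' @return `glance()`: one row with `mean_difference`, `fold_change`,
#'   `p_value`, `test`.
#' @export
glance.reporter_stats <- function(x, ...) {
  tibble::tibble(
    group_a = x$group_a, group_b = x$group_b,
    mean_difference = x$mean_difference, fold_change = x$fold_change,
    p_value = x$p_value, test = x$test
  )
}

#' Tidy the three-set overlap structure
#'
#' @param x A [venn3()] result.
#' @param ... Unused.
#' @return One row per region: `region`, `size`, `kind`
#'   (`exclusive`/`pairwise_total`/`union`).
#' @export
tidy.wnt_venn <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(region = names(x$exclusive), size = unname(x$exclusive),
                   kind = "exclusive"),
    tibble::tibble(region = names(x$pairwise), size = unname(x$pairwise),
                   kind = "pairwise_total"),
    tibble::tibble(region = "union", size = x$union_size, kind = "union")
  )
}

#' Tidy / glance a pipeline run report
#'
#' @param x A [run_pipeline()] report.
#' @param ... Unused.
#' @return `tidy()`: the candidate table. `glance()`: one row of headline
#'   counts.
#' @export
tidy.wnt_run_report <- function(x, ...) x$candidates

#' @rdname tidy.wnt_run_report
#' @export
glance.wnt_run_report <- function(x, ...) {
  tibble::tibble(
    n_pools_screened = x$n_pools_screened,
    n_pool_hits = x$n_pool_hits,
    n_gene_hits = x$n_gene_hits,
    n_candidates = x$n_candidates,
    n_apms_retained = x$n_apms_retained,
    triple_overlap = paste(x$venn$triple_symbols, collapse = ";")
  )
}
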