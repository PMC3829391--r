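#' Hit-calling thresholds
#'
#' The screen's hit criterion: a pool is a hit when its normalized reporter
#' effect changes by at least `fold_threshold`-fold in either direction
#' (percent of control at or above `100 * fold_threshold`, or at or below
#' `100 / fold_threshold`) AND its p-value is below `alpha`. Defaults are the
#' published rule: at least 2.0-fold with p < 0.01.
#'
#' @param fold_threshold Fold-change cutoff, >= 1 (default 2). The boundary is
#'   inclusive ("at least" 2-fold).
#' @param alpha p-value cutoff in (0, 1) (default 0.01), strict (`p < alpha`).
#' @param require_direction_consensus If `TRUE`, a gene is only a consensus
#'   hit when all its pool hits agree in direction (default `FALSE`: the rule
#'   is on magnitude and significance only; mixed-direction genes are still
#'   flagged in `direction_mix`).
#' @return A list of class `hit_thresholds`.
#' @export
hit_thresholds <- function(fold_threshold = 2, alpha = 0.01,
                           require_direction_consensus = FALSE) {
  stopifnot(is.numeric(fold_threshold), length(fold_threshold) == 1,
            fold_threshold >= 1,
            is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1,
            is.logical(require_direction_consensus))
  structure(list(fold_threshold = fold_threshold, alpha = alpha,
                 require_direction_consensus = require_direction_consensus),
            class = "hit_thresholds")
}

#' Classify each siRNA pool as hit_up / hit_down / non_hit
#'
#' @param summaries Pool summaries from [summarize_pools()] (needs
#'   `percent_of_control` and `p_value`).
#' @param thresholds A [hit_thresholds()] object.
#' @param adjust `"none"` (default; the published rule uses raw p < 0.01) or
#'   `"BH"` for Benjamini-Hochberg adjustment across pools before
#'   thresholding.
#' @return The input tibble with added columns `p_used` (possibly adjusted)
#'   and `pool_call` (`hit_up`, `hit_down`, `non_hit`). Pools with `NA`
#'   p-values are `non_hit` with a warning.
#' @export
classify_pools <- function(summaries, thresholds = hit_thresholds(),
                           adjust = c("none", "BH")) {
  adjust <- rlang::arg_match(adjust)
  stopifnot(inherits(thresholds, "hit_thresholds"))
  abort_missing_cols(summaries, c("pool_id", "percent_of_control", "p_value"),
                     "pool summaries")
  if (anyNA(summaries$p_value)) {
    rlang::warn(sprintf("%d pool(s) have NA p-values and are classified non_hit",
                        sum(is.na(summaries$p_value))))
  }
  f <- thresholds$fold_threshold
  summaries |>
    dplyr::mutate(
      p_used = if (adjust == "BH") stats::p.adjust(.data$p_value, "BH") else .data$p_value,
      pool_call = dplyr::case_when(
        is.na(.data$p_used) | is.na(.data$percent_of_control) ~ "non_hit",
        .data$p_used < thresholds$alpha &
          .data$percent_of_control >= 100 * f ~ "hit_up",
        .data$p_used < thresholds$alpha &
          .data$percent_of_control <= 100 / f ~ "hit_down",
        TRUE ~ "non_hit"
      )
    )
}

#' Gene-level consensus hit calls
#'
#' A gene is a consensus hit only when every siRNA pool targeting it is
#' independently a hit — the redundancy requirement that suppresses
#' single-pool off-target artifacts. The direction makeup across a gene's
#' pools is always recorded (`all_up`, `all_down`, `mixed`, or `na` when no
#' pool is a hit).
#'
#' @param pool_calls Output of [classify_pools()]; must carry `gene_symbol`.
#' @param thresholds The [hit_thresholds()] used (controls
#'   `require_direction_consensus`).
#' @return A tibble of class `wnt_gene_calls`: `gene_symbol`, `n_pools`,
#'   `n_pool_hits`, `is_hit`, `direction_mix`, sorted by gene symbol.
#' @export
call_genes <- function(pool_calls, thresholds = hit_thresholds()) {
  stopifnot(inherits(thresholds, "hit_thresholds"))
  abort_missing_cols(pool_calls, c("gene_symbol", "pool_call"), "pool calls")
  if (nrow(pool_calls) == 0) rlang::abort("no pool calls supplied")
  out <- pool_calls |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::summarise(
      n_pools = dplyr::n(),
      n_pool_hits = sum(.data$pool_call != "non_hit"),
      n_up = sum(.data$pool_call == "hit_up"),
      n_down = sum(.data$pool_call == "hit_down"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      direction_mix = dplyr::case_when(
        .data$n_pool_hits == 0 ~ "na",
        .data$n_up == .data$n_pool_hits ~ "all_up",
        .data$n_down == .data$n_pool_hits ~ "all_down",
        TRUE ~ "mixed"
      ),
      is_hit = .data$n_pool_hits == .data$n_pools &
        (!thresholds$require_direction_consensus |
           .data$direction_mix %in% c("all_up", "all_down"))
    ) |>
    dplyr::select("gene_symbol", "n_pools", "n_pool_hits", "is_hit", "direction_mix") |>
    dplyr::arrange(.data$gene_symbol)
  class(out) <- c("wnt_gene_calls", class(out))
  out
}
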