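#' Reporter-assay group statistics
#'
#' Summarizes a dual-luciferase validation assay: per-replicate
#' firefly/Renilla ratios, per-group mean and SEM, and an unpaired
#' two-tailed t-test between two conditions (Student by default; Welch or an
#' exact/Monte-Carlo permutation test via `test`).
#'
#' @param records Tibble with columns `firefly`, `renilla` (> 0) and the
#'   grouping column named by `group_col` (default `"condition"`).
#' @param group_a,group_b The two condition values to compare; each needs at
#'   least 2 replicates.
#' @param group_col Name of the grouping column.
#' @param test `"student"` (default), `"welch"` or `"permutation"`.
#' @return An object of class `reporter_stats`; use [generics::tidy()] for
#'   per-group summaries and [generics::glance()] for the test result.
#' @export
reporter_stats <- function(records, group_a, group_b, group_col = "condition",
                           test = c("student", "welch", "permutation")) {
  test <- rlang::arg_match(test)
  abort_missing_cols(records, c("firefly", "renilla", group_col), "reporter records")
  d <- records |>
    dplyr::filter(.data[[group_col]] %in% c(group_a, group_b)) |>
    dplyr::mutate(ratio = normalize_ratio(.data$firefly, .data$renilla))
  counts <- table(factor(d[[group_col]], levels = c(group_a, group_b)))
  if (any(counts < 2)) {
    rlang::abort("each group needs at least 2 replicates for reporter_stats")
  }
  groups <- d |>
    dplyr::group_by(condition = .data[[group_col]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_ratio = mean(.data$ratio),
      sem = stats::sd(.data$ratio) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$condition, c(group_a, group_b)))
  ra <- d$ratio[d[[group_col]] == group_a]
  rb <- d$ratio[d[[group_col]] == group_b]
  structure(list(
    groups = groups,
    group_a = group_a, group_b = group_b,
    mean_difference = mean(ra) - mean(rb),
    fold_change = mean(ra) / mean(rb),
    p_value = two_group_p(ra, rb, method = test),
    test = test
  ), class = "reporter_stats")
}

#' @export
print.reporter_stats <- function(x, ...) {
  cat(sprintf("<reporter_stats: %s vs %s, %s test>\n", x$group_a, x$group_b, x$test))
  print(x$groups)
  cat(sprintf("  mean difference %.4g (fold %.3g), p = %.4g\n",
              x$mean_difference, x$fold_change, x$p_value))
  invisible(x)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Standard qPCR relative quantification: per sample,
#' `delta_ct = target_ct - reference_ct` (reference gene, e.g. beta-actin);
#' `delta_delta_ct = delta_ct - mean(delta_ct of the calibrator condition)`;
#' relative quantity `rq = efficiency^(-delta_delta_ct)`. With the default
#' perfect amplification efficiency of 2, one cycle equals one doubling.
#'
#' @param records Tibble with `sample`, `condition`, `target_ct`,
#'   `reference_ct` (Ct values in cycles). Rows with a missing reference Ct
#'   are excluded with a warning.
#' @param calibrator The condition whose mean delta-Ct anchors `rq = 1`.
#' @param efficiency Assumed amplification efficiency per cycle (default 2;
#'   exposed because uncalibrated SYBR assays assume perfect doubling).
#' @return Per-sample tibble with `delta_ct`, `delta_delta_ct`, `rq`;
#'   summarize per condition with dplyr as needed.
#' @export
relative_expression <- function(records, calibrator, efficiency = 2) {
  abort_missing_cols(records, c("sample", "condition", "target_ct", "reference_ct"),
                     "qPCR records")
  stopifnot(efficiency > 1)
  drop <- is.na(records$reference_ct) | is.na(records$target_ct)
  if (any(drop)) {
    rlang::warn(sprintf("%d qPCR row(s) excluded (missing Ct)", sum(drop)))
    records <- records[!drop, ]
  }
  if (!calibrator %in% records$condition) {
    rlang::abort(sprintf("calibrator condition '%s' not present", calibrator))
  }
  if (any(records$target_ct <= 0 | records$target_ct >= 45 |
          records$reference_ct <= 0 | records$reference_ct >= 45)) {
    rlang::abort("Ct values must lie in (0, 45) cycles")
  }
  d <- dplyr::mutate(records, delta_ct = .data$target_ct - .data$reference_ct)
  cal_mean <- mean(d$delta_ct[d$condition == calibrator])
  dplyr::mutate(d,
    delta_delta_ct = .data$delta_ct - cal_mean,
    rq = efficiency^(-.data$delta_delta_ct)
  )
}

#' Percent TUNEL-positive nuclei per condition
#'
#' Apoptosis quantification from microscopy field counts: TUNEL-positive
#' nuclei as a percent of DAPI-positive nuclei, with counts summed across
#' fields *before* dividing (robust to unequal field cellularity; a mean of
#' per-field percentages would weight sparse fields equally).
#'
#' @param fields Tibble with `condition`, `field_index`, `dapi_count`,
#'   `tunel_count` (`tunel_count <= dapi_count` per field).
#' @return Tibble per condition: `n_fields`, `total_dapi`, `total_tunel`,
#'   `percent_positive` in `[0, 100]`.
#' @export
tunel_percent <- function(fields) {
  abort_missing_cols(fields, c("condition", "dapi_count", "tunel_count"),
                     "TUNEL field counts")
  if (any(fields$tunel_count > fields$dapi_count)) {
    rlang::abort("tunel_count cannot exceed dapi_count in any field")
  }
  if (any(fields$tunel_count < 0 | fields$dapi_count < 0)) {
    rlang::abort("field counts must be non-negative")
  }
  out <- fields |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n_fields = dplyr::n(),
      total_dapi = sum(.data$dapi_count),
      total_tunel = sum(.data$tunel_count),
      .groups = "drop"
    )
  if (any(out$total_dapi == 0)) {
    rlang::abort("a condition has zero DAPI-positive nuclei across all fields")
  }
  dplyr::mutate(out, percent_positive = 100 * .data$total_tunel / .data$total_dapi)
}

#' Densitometry as percent of the maximum condition
#'
#' Immunoblot quantification: each condition's cleaved-caspase-3 band
#' density is normalized to its loading control (total ERK1/2) and expressed
#' as a percent of the largest normalized value, so the strongest condition
#' reads exactly 100.
#'
#' @param records Tibble with `condition`, `cc3_density`, `loading_density`
#'   (> 0).
#' @return Tibble per condition with `normalized` (cc3/loading) and
#'   `percent_of_max` in `(0, 100]`.
#' @export
caspase_relative <- function(records) {
  abort_missing_cols(records, c("condition", "cc3_density", "loading_density"),
                     "densitometry records")
  if (nrow(records) == 0) rlang::abort("no densitometry records")
  if (any(records$loading_density <= 0)) {
    rlang::abort("loading_density must be positive")
  }
  if (all(records$cc3_density == 0)) {
    rlang::abort("all cleaved-caspase-3 densities are zero; nothing to normalize")
  }
  records |>
    dplyr::mutate(normalized = .data$cc3_density / .data$loading_density) |>
    dplyr::mutate(percent_of_max = 100 * .data$normalized / max(.data$normalized))
}
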