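#' Normalize firefly signal by the constitutive Renilla channel
#'
#' The dual-luciferase readout divides the pathway-responsive firefly
#' luminescence by the constitutively expressed Renilla luminescence from the
#' same well. Because shared multiplicative effects (cell number,
#' transfection efficiency) hit both channels, the ratio cancels them.
#'
#' @param firefly,renilla Non-negative luminescence counts (RLU); `renilla`
#'   must be strictly positive — callers must exclude zero-Renilla wells
#'   before normalizing.
#' @return `firefly / renilla`, unitless. Vectorized.
#' @export
normalize_ratio <- function(firefly, renilla) {
  if (any(!is.finite(renilla)) || any(renilla <= 0)) {
    rlang::abort("renilla must be positive; exclude zero-Renilla wells before normalizing")
  }
  if (any(!is.finite(firefly)) || any(firefly < 0)) {
    rlang::abort("firefly must be a non-negative luminescence count")
  }
  firefly / renilla
}

#' Per-plate negative-control summary
#'
#' Summarizes the negative-control wells of each plate: the median
#' firefly/Renilla ratio that anchors percent-of-control for that plate, and
#' the spread of control log2 ratios. Plate effects dominate HTS noise, so
#' every pool well is referenced to the controls of its own plate.
#'
#' @param wells A well table (see [read_well_table()]); excluded wells are
#'   ignored.
#' @return A tibble with `plate_id`, `n_neg_controls`, `control_median_ratio`,
#'   `control_log2_sd`.
#' @export
plate_control_summary <- function(wells) {
  ctrl <- dplyr::filter(wells, .data$sample_kind == "negative_control", !.data$excluded)
  if (nrow(ctrl) == 0) {
    rlang::abort("no usable negative-control wells found")
  }
  ctrl |>
    dplyr::mutate(ratio = normalize_ratio(.data$firefly, .data$renilla)) |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(
      n_neg_controls = dplyr::n(),
      control_median_ratio = stats::median(.data$ratio),
      control_log2_sd = stats::sd(log2(.data$ratio)),
      .groups = "drop"
    ) |>
    dplyr::mutate(control_log2_sd = dplyr::coalesce(.data$control_log2_sd, 0)) |>
    dplyr::arrange(.data$plate_id)
}

#' Summarize every siRNA pool against its plate controls
#'
#' For each pool, the firefly/Renilla ratio of every usable replicate well is
#' referenced to the negative-control median of the same plate. The pool's
#' effect is the median of those plate-normalized ratios expressed as a
#' percent of control; its significance is a two-group test of the pool's
#' log2 plate-normalized ratios against the plate-normalized control log2
#' ratios of the plates it sits on.
#'
#' Pools with no usable wells get `p_value = NA` and `direction = "none"`
#' and are flagged via the `n_replicates = 0` row (with a warning), never
#' dropped.
#'
#' @param wells A well table (see [read_well_table()]).
#' @param annotations Optional pool annotation tibble (`pool_id`,
#'   `gene_symbol`, `gene_id`); when supplied, gene symbols are attached.
#' @param test p-value method passed to [two_group_p()]: `"student"`
#'   (default, an unpaired two-tailed t-test), `"welch"`, or `"permutation"`.
#' @param min_neg_controls Minimum usable negative-control wells a plate
#'   must have to support p-value computation (default 2).
#' @return A tibble of class `wnt_pool_summary` with one row per pool:
#'   `pool_id`, `gene_symbol`, `n_replicates`, `median_ratio`,
#'   `percent_of_control`, `log2_effect`, `p_value`, `direction`.
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_genes = 20, seed = 1))
#' summarize_pools(sim$wells, sim$annotations)
#' @export
summarize_pools <- function(wells, annotations = NULL,
                            test = c("student", "welch", "permutation"),
                            min_neg_controls = 2) {
  test <- rlang::arg_match(test)
  if (!"excluded" %in% names(wells)) wells <- validate_well_table(wells)
  controls <- plate_control_summary(wells)
  low <- controls$plate_id[controls$n_neg_controls < min_neg_controls]

  usable <- wells |>
    dplyr::filter(!.data$excluded) |>
    dplyr::inner_join(controls, by = "plate_id") |>
    dplyr::mutate(
      norm_ratio = normalize_ratio(.data$firefly, .data$renilla) / .data$control_median_ratio
    )

  # plate-normalized control log2 values, reused by every pool on the plate
  ctrl_vals <- usable |>
    dplyr::filter(.data$sample_kind == "negative_control") |>
    dplyr::mutate(log2_norm = log2(.data$norm_ratio)) |>
    dplyr::select("plate_id", "log2_norm")

  pool_wells <- dplyr::filter(usable, .data$sample_kind == "pool")
  all_pool_ids <- sort(unique(wells$pool_id[wells$sample_kind == "pool"]))

  summaries <- pool_wells |>
    dplyr::group_by(.data$pool_id) |>
    dplyr::group_map(function(d, key) {
      plates <- unique(d$plate_id)
      if (any(plates %in% low)) {
        rlang::abort(sprintf(
          "plate(s) %s have fewer than %d usable negative controls",
          paste(intersect(plates, low), collapse = ", "), min_neg_controls
        ))
      }
      ctrl_log2 <- ctrl_vals$log2_norm[ctrl_vals$plate_id %in% plates]
      med <- stats::median(d$norm_ratio)
      tibble::tibble(
        pool_id = key$pool_id,
        n_replicates = nrow(d),
        median_ratio = stats::median(normalize_ratio(d$firefly, d$renilla)),
        percent_of_control = 100 * med,
        log2_effect = log2(med),
        p_value = two_group_p(log2(d$norm_ratio), ctrl_log2, method = test)
      )
    }) |>
    dplyr::bind_rows()

  empty <- setdiff(all_pool_ids, summaries$pool_id)
  if (length(empty) > 0) {
    rlang::warn(sprintf("%d pool(s) had no usable wells and carry NA summaries",
                        length(empty)))
    summaries <- dplyr::bind_rows(summaries, tibble::tibble(
      pool_id = empty, n_replicates = 0L, median_ratio = NA_real_,
      percent_of_control = NA_real_, log2_effect = NA_real_, p_value = NA_real_
    ))
  }

  summaries <- summaries |>
    dplyr::mutate(direction = dplyr::case_when(
      is.na(.data$percent_of_control) ~ "none",
      .data$percent_of_control > 100 ~ "up",
      .data$percent_of_control < 100 ~ "down",
      TRUE ~ "none"
    )) |>
    dplyr::arrange(.data$pool_id)

  if (!is.null(annotations)) {
    abort_missing_cols(annotations, c("pool_id", "gene_symbol"), "pool annotation")
    summaries <- summaries |>
      dplyr::left_join(dplyr::select(annotations, "pool_id", "gene_symbol"),
                       by = "pool_id") |>
      dplyr::relocate("gene_symbol", .after = "pool_id")
  }
  class(summaries) <- c("wnt_pool_summary", class(summaries))
  attr(summaries, "test") <- test
  summaries
}

#' Build the volcano table from pool summaries
#'
#' One row per siRNA pool with its percent-of-control effect and p-value,
#' sorted by ascending p-value with ties broken by `pool_id` — the tabular
#' equivalent of the screen's volcano plot.
#'
#' @param summaries Output of [summarize_pools()].
#' @return A tibble of class `wnt_volcano` with columns `pool_id`,
#'   `gene_symbol` (if present), `percent_of_control`, `p_value`.
#' @export
build_volcano_table <- function(summaries) {
  if (nrow(summaries) == 0) rlang::abort("no pool summaries to tabulate")
  keep <- intersect(c("pool_id", "gene_symbol", "percent_of_control", "p_value"),
                    names(summaries))
  out <- summaries |>
    dplyr::select(dplyr::all_of(keep)) |>
    dplyr::arrange(.data$p_value, .data$pool_id)
  class(out) <- c("wnt_volcano", setdiff(class(out), "wnt_pool_summary"))
  out
}
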