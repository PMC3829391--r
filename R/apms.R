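#' Read an AP-MS spectral-count table
#'
#' @param path TSV with columns `bait` (bait protein of the affinity
#'   purification), `prey` (protein identified in the pulldown) and
#'   `spectral_counts` (total peptide-spectrum matches for that prey, >= 1).
#' @return A tibble with one row per (bait, prey).
#' @export
read_spectral_counts <- function(path) {
  run <- readr::read_tsv(path, col_types = readr::cols(
    bait = readr::col_character(),
    prey = readr::col_character(),
    spectral_counts = readr::col_integer()
  ), progress = FALSE, show_col_types = FALSE)
  abort_missing_cols(run, c("bait", "prey", "spectral_counts"),
                     sprintf("spectral-count table '%s'", path))
  if (any(run$spectral_counts < 1)) rlang::abort("spectral_counts must be >= 1")
  if (anyDuplicated(run[c("bait", "prey")])) {
    rlang::abort("duplicate (bait, prey) rows in spectral-count table")
  }
  run
}

#' Background-subtract an AP-MS run
#'
#' Removes preys that are purification background rather than genuine
#' interactors: anything also co-purified by the control purification
#' (`control_preys`) or found on a common-contaminant list. Subtraction is
#' label-based presence/absence — no spectral-count ratio filtering — and
#' every input row is kept in the output with its `removal_reason`, so
#' nothing is silently dropped. The bait recovered as its own prey is always
#' retained and tagged (`is_bait_self`): bait recovery is a positive control
#' for the purification.
#'
#' @param run Spectral-count tibble (`bait`, `prey`, `spectral_counts`).
#' @param control_preys Character vector of preys seen in control
#'   purifications (matched case-insensitively).
#' @param contaminants Character vector of common contaminant labels.
#' @param min_count Minimum spectral counts to retain a prey (default 1,
#'   i.e. no count filtering).
#' @return A tibble of interaction edges: input columns plus `is_bait_self`,
#'   `retained` and `removal_reason` (`none`, `in_control`, `contaminant`,
#'   `low_count`); `retained` is `TRUE` iff `removal_reason == "none"`.
#' @export
subtract_background <- function(run, control_preys = character(),
                                contaminants = character(), min_count = 1) {
  abort_missing_cols(run, c("bait", "prey", "spectral_counts"), "AP-MS run")
  if (nrow(run) == 0) rlang::abort("AP-MS run is empty")
  ctrl <- toupper(trimws(control_preys))
  crap <- toupper(trimws(contaminants))
  run |>
    dplyr::mutate(
      is_bait_self = toupper(.data$prey) == toupper(.data$bait),
      removal_reason = dplyr::case_when(
        .data$is_bait_self ~ "none",
        toupper(.data$prey) %in% ctrl ~ "in_control",
        toupper(.data$prey) %in% crap ~ "contaminant",
        .data$spectral_counts < min_count ~ "low_count",
        TRUE ~ "none"
      ),
      retained = .data$removal_reason == "none"
    )
}

#' Export retained interaction edges as a network file
#'
#' @param edges Output of [subtract_background()].
#' @param path Output file path.
#' @param format `"sif"` (simple interaction format, one
#'   `bait interacts prey` line per retained edge) or `"tsv"` (bait, prey,
#'   spectral_counts). Edges are written in lexicographic (bait, prey) order
#'   so output is deterministic.
#' @return `path`, invisibly.
#' @export
export_network <- function(edges, path, format = c("sif", "tsv")) {
  format <- rlang::arg_match(format)
  abort_missing_cols(edges, c("bait", "prey", "retained"), "interaction edges")
  kept <- edges |>
    dplyr::filter(.data$retained) |>
    dplyr::arrange(.data$bait, .data$prey)
  if (format == "sif") {
    writeLines(sprintf("%s interacts %s", kept$bait, kept$prey), path)
  } else {
    readr::write_tsv(dplyr::select(kept, "bait", "prey", "spectral_counts"), path)
  }
  invisible(path)
}
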