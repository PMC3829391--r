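#' Read a well-level dual-luciferase screen table
#'
#' Parses a delimited table of raw per-well readings: one row per well with
#' its plate, layout annotation (siRNA pool, negative/positive control or
#' empty), and the firefly (pathway-responsive) and Renilla (constitutive)
#' luminescence counts. Wells with non-positive Renilla signal cannot be
#' ratio-normalized; they are kept in the returned table but flagged
#' `excluded = TRUE` (with the number excluded reported via a message and the
#' `n_excluded` attribute) so they are never silently divided.
#'
#' @param path Path to a TSV/CSV file with columns `plate_id`, `well_id`,
#'   `sample_kind` (one of `pool`, `negative_control`, `positive_control`,
#'   `empty`), `pool_id`, `firefly`, `renilla`, `replicate`. Column order is
#'   irrelevant.
#' @param delim Field delimiter; defaults to tab, with `","` inferred from a
#'   `.csv` extension.
#' @return A tibble of well measurements with an added logical `excluded`
#'   column and attribute `n_excluded`.
#' @examples
#' path <- system.file("extdata", "example_wells.tsv", package = "wntscreen")
#' read_well_table(path)
#' @export
read_well_table <- function(path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"), progress = FALSE, show_col_types = FALSE
  )
  abort_missing_cols(
    raw, c("plate_id", "well_id", "sample_kind", "pool_id", "firefly", "renilla", "replicate"),
    sprintf("well table '%s'", path)
  )
  validate_well_table(raw, path = path)
}

# shared validation so in-memory tables (e.g. simulated) go through the same
# checks as parsed files; `path` only decorates error messages
validate_well_table <- function(raw, path = "<in-memory well table>") {
  raw <- tibble::as_tibble(raw)
  parse_num <- function(col) {
    v <- raw[[col]]
    if (is.numeric(v)) return(as.numeric(v))
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad) > 0) {
      rlang::abort(sprintf(
        "non-numeric %s value%s in %s at data row%s %s (e.g. '%s')",
        col, if (length(bad) > 1) "s" else "", path,
        if (length(bad) > 1) "s" else "",
        paste(utils::head(bad, 5), collapse = ", "), v[bad[1]]
      ))
    }
    out
  }
  wells <- tibble::tibble(
    plate_id = as.character(raw$plate_id),
    well_id = as.character(raw$well_id),
    sample_kind = as.character(raw$sample_kind),
    pool_id = as.character(raw$pool_id),
    firefly = parse_num("firefly"),
    renilla = parse_num("renilla"),
    replicate = as.integer(parse_num("replicate"))
  )
  bad_kind <- setdiff(unique(wells$sample_kind),
                      c("pool", "negative_control", "positive_control", "empty"))
  if (length(bad_kind) > 0) {
    rlang::abort(sprintf("unknown sample_kind value(s) in %s: %s",
                         path, paste(bad_kind, collapse = ", ")))
  }
  orphan <- wells$sample_kind == "pool" & (is.na(wells$pool_id) | wells$pool_id == "")
  if (any(orphan)) {
    rlang::abort(sprintf("%d pool well(s) in %s lack a pool_id", sum(orphan), path))
  }
  wells$excluded <- is.na(wells$renilla) | wells$renilla <= 0 | is.na(wells$firefly)
  n_excl <- sum(wells$excluded)
  if (n_excl > 0) {
    rlang::inform(sprintf(
      "%d well(s) excluded from analysis (non-positive or missing Renilla/firefly signal)",
      n_excl
    ))
  }
  attr(wells, "n_excluded") <- n_excl
  wells
}

#' Read a pool-to-gene annotation table
#'
#' @param path TSV with columns `pool_id`, `gene_symbol`, `gene_id`. A gene
#'   may be targeted by several pools; `pool_id` must be unique.
#' @return A tibble with one row per siRNA pool.
#' @export
read_pool_annotations <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(
    pool_id = readr::col_character(),
    gene_symbol = readr::col_character(),
    gene_id = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE)
  abort_missing_cols(ann, c("pool_id", "gene_symbol", "gene_id"),
                     sprintf("pool annotation '%s'", path))
  if (anyDuplicated(ann$pool_id)) {
    rlang::abort(sprintf("duplicated pool_id values in %s", path))
  }
  ann
}

#' Write / read a volcano table as TSV
#'
#' The volcano table is the tabular form of the screen's volcano plot: one
#' row per siRNA pool with its median percent-of-control effect and p-value,
#' sorted by ascending p (ties broken by `pool_id`).
#'
#' @param volcano A tibble from [build_volcano_table()].
#' @param path Output / input TSV path.
#' @return `write_volcano()` returns `path` invisibly; `read_volcano()`
#'   returns the tibble.
#' @export
write_volcano <- function(volcano, path) {
  readr::write_tsv(volcano, path)
  invisible(path)
}

#' @rdname write_volcano
#' @export
read_volcano <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    pool_id = readr::col_character(),
    gene_symbol = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE, show_col_types = FALSE)
}
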