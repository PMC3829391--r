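#' Harmonize a raw gene-symbol list into an evidence set
#'
#' Evidence lists from different sources (screen hits, phosphoproteomic
#' hits, disease-associated genes) use inconsistent casing, stray whitespace
#' and aliases. Harmonization trims, uppercases, resolves aliases through the
#' supplied map and deduplicates; symbols absent from the alias map are kept
#' verbatim (uppercased) and counted in the provenance note.
#'
#' @param raw_symbols Character vector of gene symbols.
#' @param alias_map Named character vector mapping alias -> canonical symbol
#'   (matched case-insensitively); may be `NULL` or empty.
#' @param name Label for the set (e.g. `"screen"`).
#' @param provenance Free-text origin note.
#' @return An `evidence_set`: a list with `name`, `symbols` (sorted unique
#'   uppercase character vector) and `provenance`.
#' @examples
#' harmonize(c("fam129b", "FAM129B ", "MEG-3"),
#'           alias_map = c("MEG-3" = "FAM129B"), name = "demo")
#' @export
harmonize <- function(raw_symbols, alias_map = NULL, name = "evidence",
                      provenance = "") {
  symbols <- toupper(trimws(as.character(raw_symbols)))
  symbols <- symbols[!is.na(symbols) & symbols != ""]
  n_resolved <- 0L
  if (length(alias_map) > 0) {
    stopifnot(!is.null(names(alias_map)))
    map <- stats::setNames(toupper(alias_map), toupper(names(alias_map)))
    idx <- match(symbols, names(map))
    n_resolved <- sum(!is.na(idx))
    symbols[!is.na(idx)] <- unname(map[idx[!is.na(idx)]])
  }
  structure(
    list(name = name, symbols = sort(unique(symbols)),
         provenance = paste0(provenance,
                             sprintf(" [%d aliases resolved]", n_resolved))),
    class = "evidence_set"
  )
}

#' @export
print.evidence_set <- function(x, ...) {
  cat(sprintf("<evidence_set '%s': %d symbols>%s\n", x$name, length(x$symbols),
              if (nzchar(x$provenance)) paste0(" ", x$provenance) else ""))
  invisible(x)
}

as_symbol_set <- function(x) {
  if (inherits(x, "evidence_set")) x$symbols else sort(unique(toupper(trimws(x))))
}

#' Read / write a gene-record dump (JSON lines)
#'
#' An offline snapshot of gene-database records, one JSON object per line
#' with fields `gene_id`, `gene_symbol`, `aliases` (array), `description`,
#' `summary`. Querying a serialized dump keeps the disease-gene keyword
#' search reproducible: live database content drifts, so published match
#' counts are tied to a snapshot date.
#'
#' @param path JSON-lines file path.
#' @param dump Tibble of records (as returned by `read_gene_dump()` or
#'   [simulate_evidence()]).
#' @param source_label,snapshot_date Metadata stored as attributes.
#' @return `read_gene_dump()`: a tibble of records with attributes
#'   `source_label` and `snapshot_date`.
#' @export
read_gene_dump <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- purrr::map(lines, function(l) {
    r <- jsonlite::fromJSON(l)
    tibble::tibble(
      gene_id = as.character(r$gene_id),
      gene_symbol = as.character(r$gene_symbol),
      aliases = list(as.character(r$aliases %||% character(0))),
      description = as.character(r$description %||% ""),
      summary = as.character(r$summary %||% "")
    )
  })
  dump <- dplyr::bind_rows(recs)
  if (anyDuplicated(dump$gene_id)) rlang::abort("duplicate gene_id in dump")
  dump
}

#' @rdname read_gene_dump
#' @export
write_gene_dump <- function(dump, path, source_label = "synthetic",
                            snapshot_date = "1970-01-01") {
  lines <- purrr::pmap_chr(dump, function(gene_id, gene_symbol, aliases,
                                          description, summary, ...) {
    jsonlite::toJSON(list(
      gene_id = gene_id, gene_symbol = gene_symbol,
      aliases = as.character(aliases),
      description = description, summary = summary
    ), auto_unbox = TRUE)
  })
  writeLines(lines, path)
  invisible(path)
}

#' Keyword query over an offline gene-record dump
#'
#' Reproduces a "disease-associated genes" database query offline: a record
#' matches when its description or summary contains the keyword,
#' case-insensitively. Whole-word matching is the default (so "melanoma"
#' does not match "melanomagenesis"); set `whole_word = FALSE` for substring
#' semantics.
#'
#' @param dump Gene-record tibble (see [read_gene_dump()]).
#' @param keyword Non-empty search term.
#' @param whole_word Match at word boundaries (default `TRUE`).
#' @param name Label for the resulting evidence set.
#' @return An `evidence_set` of matching gene symbols; provenance records how
#'   many matched by description vs summary.
#' @export
query_disease_genes <- function(dump, keyword, whole_word = TRUE,
                                name = "disease") {
  if (!is.character(keyword) || length(keyword) != 1 || !nzchar(trimws(keyword))) {
    rlang::abort("keyword must be a non-empty string")
  }
  if (nrow(dump) == 0) rlang::abort("gene-record dump is empty")
  pat <- stringr::fixed(keyword, ignore_case = TRUE)
  if (whole_word) {
    pat <- stringr::regex(paste0("\\b", escape_regex(keyword), "\\b"),
                          ignore_case = TRUE)
  }
  in_desc <- stringr::str_detect(dump$description, pat)
  in_summ <- stringr::str_detect(dump$summary, pat)
  hit <- in_desc | in_summ
  harmonize(
    dump$gene_symbol[hit], name = name,
    provenance = sprintf("keyword '%s' (%s): %d by description, %d by summary",
                         keyword, if (whole_word) "whole word" else "substring",
                         sum(in_desc), sum(in_summ))
  )
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Three-set overlap structure (Venn counts)
#'
#' Computes the full three-set overlap structure of harmonized gene lists:
#' the seven exclusive regions, the three pairwise intersection totals (each
#' pairwise total = its exclusive pair region + the triple region), the
#' union size, and the triple-overlap symbols themselves.
#'
#' @param a,b,c `evidence_set`s (or plain character vectors).
#' @return A list of class `wnt_venn` with elements `sets` (names and
#'   sizes), `exclusive` (named 7-vector: `a_only`, `b_only`, `c_only`,
#'   `ab_only`, `ac_only`, `bc_only`, `abc`), `pairwise` (named 3-vector:
#'   `ab`, `ac`, `bc`), `union_size`, `triple_symbols`.
#' @export
venn3 <- function(a, b, c) {
  nm <- c(
    if (inherits(a, "evidence_set")) a$name else "A",
    if (inherits(b, "evidence_set")) b$name else "B",
    if (inherits(c, "evidence_set")) c$name else "C"
  )
  A <- as_symbol_set(a); B <- as_symbol_set(b); C <- as_symbol_set(c)
  u <- sort(unique(c(A, B, C)))
  inA <- u %in% A; inB <- u %in% B; inC <- u %in% C
  exclusive <- c(
    a_only = sum(inA & !inB & !inC),
    b_only = sum(!inA & inB & !inC),
    c_only = sum(!inA & !inB & inC),
    ab_only = sum(inA & inB & !inC),
    ac_only = sum(inA & !inB & inC),
    bc_only = sum(!inA & inB & inC),
    abc = sum(inA & inB & inC)
  )
  structure(list(
    sets = tibble::tibble(set = c("a", "b", "c"), name = nm,
                          size = c(length(A), length(B), length(C))),
    exclusive = exclusive,
    pairwise = c(ab = sum(inA & inB), ac = sum(inA & inC), bc = sum(inB & inC)),
    union_size = length(u),
    triple_symbols = u[inA & inB & inC]
  ), class = "wnt_venn")
}

#' @export
print.wnt_venn <- function(x, ...) {
  cat(sprintf("<3-set overlap of %s (sizes %s)>\n",
              paste(x$sets$name, collapse = "/"),
              paste(x$sets$size, collapse = "/")))
  cat("  pairwise:", paste(sprintf("%s=%d", names(x$pairwise), x$pairwise),
                           collapse = ", "), "\n")
  cat(sprintf("  triple (%d): %s\n", x$exclusive[["abc"]],
              paste(utils::head(x$triple_symbols, 10), collapse = ", ")))
  invisible(x)
}

#' Nominate candidate genes by multi-evidence support
#'
#' Genes supported by at least two of the three evidence sets, ranked by the
#' number of supporting sets (triple-overlap genes first) and then
#' alphabetically — the integration step that elevates a single
#' all-three-sets gene above hundreds of pairwise overlaps.
#'
#' @param screen,phospho,disease `evidence_set`s (or character vectors) of
#'   screen hits, phosphoproteomic hits and disease-associated genes.
#' @return A tibble: `gene_symbol`, `in_screen`, `in_phospho`, `in_disease`,
#'   `rank_key` (2 or 3), sorted by descending `rank_key` then symbol.
#' @export
nominate <- function(screen, phospho, disease) {
  S <- as_symbol_set(screen); P <- as_symbol_set(phospho); D <- as_symbol_set(disease)
  u <- sort(unique(c(S, P, D)))
  out <- tibble::tibble(
    gene_symbol = u,
    in_screen = u %in% S,
    in_phospho = u %in% P,
    in_disease = u %in% D
  ) |>
    dplyr::mutate(rank_key = .data$in_screen + .data$in_phospho + .data$in_disease) |>
    dplyr::filter(.data$rank_key >= 2) |>
    dplyr::arrange(dplyr::desc(.data$rank_key), .data$gene_symbol)
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
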