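#' Synthetic stand-in for the published integration inputs
#'
#' A deterministic, fully synthetic set of inputs whose overlap structure
#' mirrors the published FAM129B discovery: a screen-hit list, a
#' phosphoproteomic hit list and a melanoma-associated gene list with
#' pairwise intersections of exactly 17 (screen/phospho), 1
#' (phospho/melanoma) and 119 (screen/melanoma), FAM129B as the single
#' triple-overlap gene, plus an AP-MS spectral-count table with 18 prey
#' proteins including KEAP1. All symbols other than FAM129B and KEAP1 are
#' synthetic placeholders — these are NOT the original supplementary data,
#' which are only available as a download; the object exists so the
#' integration and AP-MS code paths can be exercised offline against the
#' published overlap structure.
#'
#' List sizes are scaled down (600 screen hits, 60 phospho hits, 300
#' disease genes) while the published intersection counts are preserved
#' exactly.
#'
#' @return A list with `screen_hits`, `phospho_hits`, `disease_genes`
#'   (character vectors), `gene_dump` (a gene-record tibble whose
#'   "melanoma" whole-word matches are exactly the disease genes; one decoy
#'   record mentions only "melanomagenesis"), and `apms_run` (bait
#'   FAM129B, 18 preys including KEAP1).
#' @examples
#' ex <- synthetic_fam129b_example()
#' venn3(harmonize(ex$screen_hits, name = "screen"),
#'       harmonize(ex$phospho_hits, name = "phospho"),
#'       harmonize(ex$disease_genes, name = "melanoma"))
#' @export
synthetic_fam129b_example <- function() {
  triple <- "FAM129B"
  sp_only <- sprintf("SPHIT%03d", 1:16)    # screen & phospho only
  sm_only <- sprintf("SMEL%03d", 1:118)    # screen & melanoma only
  s_only <- sprintf("SCRN%03d", 1:465)
  p_only <- sprintf("PHOS%03d", 1:43)
  m_only <- sprintf("MELG%03d", 1:181)

  screen_hits <- c(s_only, sp_only, sm_only, triple)
  phospho_hits <- c(p_only, sp_only, triple)
  disease_genes <- c(m_only, sm_only, triple)

  decoys <- tibble::tibble(
    gene_id = c("900001", "900002"),
    gene_symbol = c("DECOY01", "DECOY02"),
    aliases = list(character(0), character(0)),
    description = c(
      "Putative driver of melanomagenesis in model systems",
      "Ubiquitous cytoskeletal component"
    ),
    summary = c("Substring-only decoy record.", "No disease association.")
  )
  gene_dump <- dplyr::bind_rows(
    tibble::tibble(
      gene_id = as.character(seq_along(disease_genes)),
      gene_symbol = disease_genes,
      aliases = purrr::map(disease_genes, ~ character(0)),
      description = "Gene associated with melanoma progression",
      summary = "Recurrently reported in melanoma cohorts."
    ),
    decoys
  )

  preys <- c("KEAP1", sprintf("PREYP%02d", 1:17))
  apms_run <- tibble::tibble(
    bait = "FAM129B",
    prey = preys,
    spectral_counts = as.integer(c(24, 2 + ((1:17 * 7) %% 30)))
  )

  list(screen_hits = screen_hits, phospho_hits = phospho_hits,
       disease_genes = disease_genes, gene_dump = gene_dump,
       apms_run = apms_run)
}
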