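#' Configuration for an end-to-end screen-integration run
#'
#' Bundles the per-stage inputs: either paths to real tables or simulation
#' configs. All randomness flows from `seed`, with a fixed per-stage offset
#' so one stage's draws never perturb another's.
#'
#' @param screen Either a [screen_sim_config()] or a list
#'   `list(wells = <path>, annotations = <path>)` of TSV paths.
#' @param thresholds A [hit_thresholds()].
#' @param test p-value method for [summarize_pools()].
#' @param evidence `NULL` (simulate evidence around the screen truth), or a
#'   list `list(phospho = <path>, dump = <path>)` with a one-symbol-per-line
#'   phospho list and a JSON-lines gene-record dump.
#' @param keyword Disease keyword for the dump query.
#' @param apms `NULL` (simulate), a list
#'   `list(run = <path>, control = <path or NULL>, contaminants = <path or NULL>)`,
#'   or a list `list(run = <tibble>, control_preys = ..., contaminants = ...)`.
#' @param seed Integer master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(screen = screen_sim_config(),
                            thresholds = hit_thresholds(),
                            test = c("student", "welch", "permutation"),
                            evidence = NULL, keyword = "melanoma",
                            apms = NULL, seed = 1) {
  test <- rlang::arg_match(test)
  stopifnot(inherits(thresholds, "hit_thresholds"))
  structure(list(screen = screen, thresholds = thresholds, test = test,
                 evidence = evidence, keyword = keyword, apms = apms,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# stage seeds derived from the master seed; offsets fixed so stages are
# isolated; kept far below .Machine$integer.max
stage_seed <- function(seed, stage) {
  seed + c(screen = 0L, evidence = 10007L, apms = 20011L)[[stage]]
}

#' Run the full screen-to-candidates pipeline
#'
#' Orchestrates simulate/load -> normalize & summarize -> hit call ->
#' evidence integration -> AP-MS subtraction, writes every stage's tabular
#' output plus a machine-readable `report.json` under `outdir`, and returns
#' the run report.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if missing).
#' @return An object of class `wnt_run_report`: stage outputs
#'   (`pool_summaries`, `volcano`, `gene_calls`, `venn`, `candidates`,
#'   `apms_edges`, `truth` when simulated) and headline counts
#'   (`n_pools_screened`, `n_pool_hits`, `n_gene_hits`). Use
#'   [generics::glance()] for the one-row count summary.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(screen = screen_sim_config(n_genes = 50, seed = 3))
#' rep <- run_pipeline(cfg, outdir = tempfile())
#' generics::glance(rep)
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("wntscreen_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  ## stage 1: screen data ----------------------------------------------------
  truth <- NULL
  if (inherits(config$screen, "screen_sim_config")) {
    scfg <- config$screen
    scfg$seed <- stage_seed(config$seed, "screen")
    sim <- simulate_screen(scfg)
    wells <- sim$wells
    annotations <- sim$annotations
    truth <- sim$truth
    readr::write_tsv(dplyr::select(wells, -"excluded"),
                     file.path(outdir, "wells.tsv"))
    readr::write_tsv(annotations, file.path(outdir, "pool_annotations.tsv"))
  } else {
    wells <- read_well_table(config$screen$wells)
    annotations <- read_pool_annotations(config$screen$annotations)
  }

  ## stage 2: summarize + volcano -------------------------------------------
  summaries <- summarize_pools(wells, annotations, test = config$test)
  volcano <- build_volcano_table(summaries)
  write_volcano(volcano, file.path(outdir, "volcano.tsv"))

  ## stage 3: hit calling -----------------------------------------------------
  pool_calls <- classify_pools(summaries, config$thresholds)
  gene_calls <- call_genes(pool_calls, config$thresholds)
  readr::write_tsv(gene_calls, file.path(outdir, "gene_calls.tsv"))
  screen_set <- harmonize(gene_calls$gene_symbol[gene_calls$is_hit],
                          name = "screen", provenance = "consensus gene hits")

  ## stage 4: evidence integration -------------------------------------------
  if (is.null(config$evidence)) {
    if (is.null(truth)) {
      rlang::abort("evidence paths are required when the screen is not simulated")
    }
    ev <- simulate_evidence(truth, seed = stage_seed(config$seed, "evidence"))
    truth <- ev$truth
    phospho_raw <- ev$phospho
    dump <- ev$dump
    writeLines(phospho_raw, file.path(outdir, "phospho_hits.txt"))
    write_gene_dump(dump, file.path(outdir, "gene_records.jsonl"))
  } else {
    phospho_raw <- readLines(config$evidence$phospho, warn = FALSE)
    dump <- read_gene_dump(config$evidence$dump)
  }
  phospho_set <- harmonize(phospho_raw, name = "phospho",
                           provenance = "phosphoproteomic hit list")
  disease_set <- query_disease_genes(dump, config$keyword)
  venn <- venn3(screen_set, phospho_set, disease_set)
  candidates <- nominate(screen_set, phospho_set, disease_set)
  readr::write_tsv(candidates, file.path(outdir, "candidates.tsv"))

  ## stage 5: AP-MS -----------------------------------------------------------
  if (is.null(config$apms)) {
    ap <- simulate_apms(seed = stage_seed(config$seed, "apms"))
    run <- ap$run; ctrl <- ap$control_preys; crap <- ap$contaminants
  } else if (!is.null(config$apms$run) && is.character(config$apms$run)) {
    run <- read_spectral_counts(config$apms$run)
    ctrl <- if (is.null(config$apms$control)) character() else
      readLines(config$apms$control, warn = FALSE)
    crap <- if (is.null(config$apms$contaminants)) character() else
      readLines(config$apms$contaminants, warn = FALSE)
  } else {
    run <- config$apms$run
    ctrl <- config$apms$control_preys %||% character()
    crap <- config$apms$contaminants %||% character()
  }
  edges <- subtract_background(run, control_preys = ctrl, contaminants = crap)
  export_network(edges, file.path(outdir, "network.sif"), format = "sif")

  ## report -------------------------------------------------------------------
  report <- structure(list(
    n_pools_screened = nrow(summaries),
    n_pool_hits = sum(pool_calls$pool_call != "non_hit"),
    n_gene_hits = sum(gene_calls$is_hit),
    n_candidates = nrow(candidates),
    n_apms_retained = sum(edges$retained & !edges$is_bait_self),
    venn = venn,
    candidates = candidates,
    pool_summaries = summaries,
    volcano = volcano,
    gene_calls = gene_calls,
    apms_edges = edges,
    truth = truth,
    config = config,
    outdir = outdir
  ), class = "wnt_run_report")
  jsonlite::write_json(report_json(report), file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

# serializable summary of a run report (stable field order => byte-stable)
report_json <- function(report) {
  v <- report$venn
  list(
    n_pools_screened = report$n_pools_screened,
    n_pool_hits = report$n_pool_hits,
    n_gene_hits = report$n_gene_hits,
    n_candidates = report$n_candidates,
    n_apms_retained = report$n_apms_retained,
    venn = list(
      sets = as.list(stats::setNames(v$sets$size, v$sets$name)),
      exclusive = as.list(v$exclusive),
      pairwise = as.list(v$pairwise),
      union_size = v$union_size,
      triple_symbols = as.list(v$triple_symbols)
    ),
    top_candidates = utils::head(report$candidates$gene_symbol, 25),
    config = list(
      test = report$config$test,
      fold_threshold = report$config$thresholds$fold_threshold,
      alpha = report$config$thresholds$alpha,
      keyword = report$config$keyword,
      seed = report$config$seed
    ),
    package_version = as.character(utils::packageVersion("wntscreen"))
  )
}

#' @export
print.wnt_run_report <- function(x, ...) {
  cat("<wntscreen run report>\n")
  cat(sprintf("  pools screened : %d\n", x$n_pools_screened))
  cat(sprintf("  pool hits      : %d\n", x$n_pool_hits))
  cat(sprintf("  gene hits      : %d\n", x$n_gene_hits))
  cat(sprintf("  candidates     : %d (triple overlap: %s)\n", x$n_candidates,
              paste(x$venn$triple_symbols, collapse = ", ")))
  cat(sprintf("  AP-MS retained : %d preys\n", x$n_apms_retained))
  cat(sprintf("  outputs under  : %s\n", x$outdir))
  invisible(x)
}

#' Compare recovered hits against a planted truth table
#'
#' Sensitivity and false-discovery rate of gene-level consensus hit calls
#' against the simulator's truth table.
#'
#' @param gene_calls Output of [call_genes()].
#' @param truth Truth tibble with `gene_symbol` and `is_regulator`.
#' @return One-row tibble: `n_true`, `n_called`, `tp`, `fp`, `fn`,
#'   `sensitivity`, `fdr`.
#' @export
recovery_stats <- function(gene_calls, truth) {
  abort_missing_cols(truth, c("gene_symbol", "is_regulator"), "truth table")
  called <- gene_calls$gene_symbol[gene_calls$is_hit]
  pos <- truth$gene_symbol[truth$is_regulator]
  tp <- length(intersect(called, pos))
  fp <- length(setdiff(called, pos))
  tibble::tibble(
    n_true = length(pos), n_called = length(called),
    tp = tp, fp = fp, fn = length(pos) - tp,
    sensitivity = if (length(pos) == 0) NA_real_ else tp / length(pos),
    fdr = if (length(called) == 0) 0 else fp / length(called)
  )
}
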