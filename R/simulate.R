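#' Configuration for a simulated dual-luciferase siRNA screen
#'
#' The generator emulates a plate-based reporter screen: each siRNA pool
#' occupies one well per replicate plate, each plate carries its own
#' negative-control wells, and a planted fraction of genes are true
#' regulators with a log2 effect on the firefly channel only. Well noise is
#' log-normal and multiplicative on each luminescence channel; an additional
#' log-normal "cell number" factor is shared between the two channels of a
#' well, which is exactly the nuisance the firefly/Renilla ratio is designed
#' to cancel.
#'
#' Defaults are desk-scale: 500 genes on 384-well plates with 16 negative
#' controls per plate, 10% true regulators with log2 effects uniform in
#' +/-[1, 3], and 0.2 coefficients of variation for both channel and cell
#' noise. `wells_per_plate = 1536` reproduces the screening-scale plate
#' format.
#'
#' @param n_genes Number of genes targeted.
#' @param pools_per_gene siRNA pools per gene (>= 1).
#' @param replicates_per_pool Replicate wells per pool, one per replicate
#'   plate copy.
#' @param wells_per_plate Physical wells per plate.
#' @param n_neg_controls_per_plate Negative-control wells on every plate
#'   (>= 2).
#' @param fraction_true_regulators Fraction of genes with a real effect.
#' @param effect_log2_range Range of |log2 effect| for regulators (sign
#'   random); a degenerate range like `c(2, 2)` plants a fixed magnitude.
#' @param well_noise_cv Coefficient of variation of the per-channel
#'   log-normal noise.
#' @param cell_number_cv CV of the shared per-well log-normal factor.
#' @param baseline_firefly,baseline_renilla Baseline RLU per channel.
#' @param seed Integer seed; generators are pure functions of (config, seed).
#' @return A validated list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_genes = 500, pools_per_gene = 1,
                              replicates_per_pool = 3, wells_per_plate = 384,
                              n_neg_controls_per_plate = 16,
                              fraction_true_regulators = 0.1,
                              effect_log2_range = c(1, 3),
                              well_noise_cv = 0.2, cell_number_cv = 0.2,
                              baseline_firefly = 1000, baseline_renilla = 1000,
                              seed = 1) {
  cfg <- list(
    n_genes = as.integer(n_genes), pools_per_gene = as.integer(pools_per_gene),
    replicates_per_pool = as.integer(replicates_per_pool),
    wells_per_plate = as.integer(wells_per_plate),
    n_neg_controls_per_plate = as.integer(n_neg_controls_per_plate),
    fraction_true_regulators = fraction_true_regulators,
    effect_log2_range = sort(abs(effect_log2_range)),
    well_noise_cv = well_noise_cv, cell_number_cv = cell_number_cv,
    baseline_firefly = baseline_firefly, baseline_renilla = baseline_renilla,
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      n_genes >= 1, pools_per_gene >= 1, replicates_per_pool >= 1,
      n_neg_controls_per_plate >= 2,
      wells_per_plate > n_neg_controls_per_plate,
      fraction_true_regulators >= 0, fraction_true_regulators <= 1,
      length(effect_log2_range) == 2,
      well_noise_cv >= 0, cell_number_cv >= 0,
      baseline_firefly > 0, baseline_renilla > 0
    )
  })
  structure(cfg, class = "screen_sim_config")
}

#' Simulate a dual-luciferase siRNA screen with planted ground truth
#'
#' @param cfg A [screen_sim_config()].
#' @return A list with `wells` (well-measurement tibble in the
#'   [read_well_table()] schema, plus `excluded`), `annotations`
#'   (pool -> gene), and `truth` (per gene: `is_regulator`,
#'   `true_log2_effect`, and placeholder `in_phospho_truth` /
#'   `in_disease_truth` columns filled by [simulate_evidence()]).
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_genes = 30, seed = 42))
#' dplyr::count(sim$wells, sample_kind)
#' @export
simulate_screen <- function(cfg = screen_sim_config()) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  withr::with_seed(cfg$seed, {
    n_pools <- cfg$n_genes * cfg$pools_per_gene
    genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
    pools <- sprintf("POOL%05d", seq_len(n_pools))
    annotations <- tibble::tibble(
      pool_id = pools,
      gene_symbol = rep(genes, each = cfg$pools_per_gene),
      gene_id = as.character(rep(seq_len(cfg$n_genes), each = cfg$pools_per_gene))
    )

    n_reg <- round(cfg$fraction_true_regulators * cfg$n_genes)
    reg_idx <- sample.int(cfg$n_genes, n_reg)
    eff <- numeric(cfg$n_genes)
    if (n_reg > 0) {
      mag <- stats::runif(n_reg, cfg$effect_log2_range[1], cfg$effect_log2_range[2])
      eff[reg_idx] <- mag * sample(c(-1, 1), n_reg, replace = TRUE)
    }
    truth <- tibble::tibble(
      gene_symbol = genes,
      is_regulator = seq_len(cfg$n_genes) %in% reg_idx,
      true_log2_effect = eff,
      in_phospho_truth = FALSE,
      in_disease_truth = FALSE
    )

    # plate layout: pools fill the non-control wells of as many plates as
    # needed; each replicate is a fresh copy of that layout on its own
    # plates (own controls, own noise)
    pool_wells_per_plate <- cfg$wells_per_plate - cfg$n_neg_controls_per_plate
    n_plates <- ceiling(n_pools / pool_wells_per_plate)
    plate_of_pool <- rep(seq_len(n_plates), each = pool_wells_per_plate)[seq_len(n_pools)]
    ncol_plate <- if (cfg$wells_per_plate %% 24 == 0) 24 else
      ceiling(sqrt(cfg$wells_per_plate / 1.5))
    labels <- well_labels(cfg$wells_per_plate, ncol = ncol_plate)

    layout <- purrr::map(seq_len(n_plates), function(p) {
      on_plate <- pools[plate_of_pool == p]
      n_on <- length(on_plate)
      tibble::tibble(
        plate_base = sprintf("P%03d", p),
        well_id = labels[seq_len(n_on + cfg$n_neg_controls_per_plate)],
        sample_kind = c(rep("pool", n_on),
                        rep("negative_control", cfg$n_neg_controls_per_plate)),
        pool_id = c(on_plate, rep(NA_character_, cfg$n_neg_controls_per_plate))
      )
    }) |> dplyr::bind_rows()

    gene_eff <- stats::setNames(truth$true_log2_effect, truth$gene_symbol)
    pool_eff <- stats::setNames(
      gene_eff[annotations$gene_symbol], annotations$pool_id
    )

    wells <- purrr::map(seq_len(cfg$replicates_per_pool), function(r) {
      n <- nrow(layout)
      cell <- rlnorm_cv(n, cfg$cell_number_cv)
      chF <- rlnorm_cv(n, cfg$well_noise_cv)
      chR <- rlnorm_cv(n, cfg$well_noise_cv)
      e <- ifelse(layout$sample_kind == "pool",
                  unname(pool_eff[layout$pool_id]), 0)
      tibble::tibble(
        plate_id = paste0(layout$plate_base, sprintf("_R%d", r)),
        well_id = layout$well_id,
        sample_kind = layout$sample_kind,
        pool_id = layout$pool_id,
        firefly = cfg$baseline_firefly * 2^e * cell * chF,
        renilla = cfg$baseline_renilla * cell * chR,
        replicate = r
      )
    }) |> dplyr::bind_rows()
    wells$excluded <- FALSE
    list(wells = wells, annotations = annotations, truth = truth)
  })
}

#' Simulate phosphoproteomic and disease-gene evidence around a screen truth
#'
#' Draws which genes enter the phosphoproteomic hit list and which carry the
#' disease keyword in a synthetic gene-record dump, with membership
#' probabilities that differ between true regulators and the rest — that is
#' what creates (configurable) enrichment of the triple overlap.
#'
#' @param truth Truth tibble from [simulate_screen()].
#' @param phospho_frac,disease_frac Length-2 named numeric vectors
#'   `c(regulator = ..., other = ...)`: probability that a regulator /
#'   non-regulator gene enters the respective evidence set.
#' @param keyword Disease keyword embedded in matching record descriptions.
#' @param seed Integer seed.
#' @return A list with `phospho` (character vector of symbols), `dump`
#'   (gene-record tibble covering every gene; matching records mention the
#'   keyword), and `truth` with `in_phospho_truth` / `in_disease_truth`
#'   realized.
#' @export
simulate_evidence <- function(truth,
                              phospho_frac = c(regulator = 0.3, other = 0.02),
                              disease_frac = c(regulator = 0.3, other = 0.05),
                              keyword = "melanoma", seed = 1) {
  stopifnot(all(c("gene_symbol", "is_regulator") %in% names(truth)),
            all(phospho_frac >= 0 & phospho_frac <= 1),
            all(disease_frac >= 0 & disease_frac <= 1))
  withr::with_seed(seed, {
    p_ph <- ifelse(truth$is_regulator, phospho_frac[["regulator"]],
                   phospho_frac[["other"]])
    p_di <- ifelse(truth$is_regulator, disease_frac[["regulator"]],
                   disease_frac[["other"]])
    truth$in_phospho_truth <- stats::runif(nrow(truth)) < p_ph
    truth$in_disease_truth <- stats::runif(nrow(truth)) < p_di
    dump <- tibble::tibble(
      gene_id = as.character(seq_len(nrow(truth))),
      gene_symbol = truth$gene_symbol,
      aliases = purrr::map(truth$gene_symbol, ~ character(0)),
      description = ifelse(
        truth$in_disease_truth,
        sprintf("Gene associated with %s progression", keyword),
        "Housekeeping gene with no disease association"
      ),
      summary = ifelse(
        truth$in_disease_truth,
        sprintf("Reported in %s cohorts.", keyword),
        "No notable phenotype reported."
      )
    )
    list(phospho = truth$gene_symbol[truth$in_phospho_truth],
         dump = dump, truth = truth)
  })
}

#' Simulate an AP-MS run with known background
#'
#' Prey spectral counts are drawn from a shifted Poisson (always >= 1); a
#' configurable fraction of preys are purification background and are
#' duplicated into the control-prey list, so the post-subtraction truth is
#' known by construction.
#'
#' @param n_prey Number of prey proteins recovered with the bait.
#' @param background_rate Fraction of preys that are background.
#' @param contaminant_preys Labels to place on the contaminant list (a
#'   subset may overlap the background).
#' @param bait Bait protein label.
#' @param mean_counts Mean of the Poisson component of spectral counts.
#' @param seed Integer seed.
#' @return A list with `run` (spectral-count tibble), `control_preys`,
#'   `contaminants` and `truth_retained` (prey labels that should survive
#'   [subtract_background()]).
#' @export
simulate_apms <- function(n_prey = 50, background_rate = 0.4,
                          contaminant_preys = character(), bait = "BAIT1",
                          mean_counts = 5, seed = 1) {
  stopifnot(n_prey >= 1, background_rate >= 0, background_rate <= 1)
  withr::with_seed(seed, {
    prey <- sprintf("PREY%03d", seq_len(n_prey))
    run <- tibble::tibble(
      bait = bait, prey = prey,
      spectral_counts = 1L + stats::rpois(n_prey, mean_counts)
    )
    n_bg <- round(background_rate * n_prey)
    control_preys <- sort(sample(prey, n_bg))
    truth <- setdiff(prey, union(control_preys, toupper(contaminant_preys)))
    list(run = run, control_preys = control_preys,
         contaminants = contaminant_preys, truth_retained = sort(truth))
  })
}

#' Effect specification for simulated validation assays
#'
#' @param reporter_fold True firefly fold-activation of the treated
#'   condition over control (default 5, a typical reporter activation).
#' @param reporter_cv CV of the log-normal noise on each reporter channel.
#' @param qpcr_fold True fold-induction of the qPCR target in the treated
#'   condition (default 4).
#' @param ct_sd Additive SD on every measured Ct, in cycles (default 0.15,
#'   typical technical scatter).
#' @param n_replicates Replicates per condition for reporter and qPCR
#'   (default 6).
#' @param tunel_rates Named per-condition true TUNEL-positive rates.
#' @param tunel_fields Microscopy fields per condition (default 5 per slide).
#' @param dapi_per_field Mean DAPI-positive nuclei per field (default 200).
#' @param caspase_levels Named per-condition true cleaved-caspase-3 levels
#'   relative to the strongest condition.
#' @param densitometry_cv CV of log-normal noise on band densities.
#' @return A list of class `assay_sim_spec`.
#' @export
assay_sim_spec <- function(reporter_fold = 5, reporter_cv = 0.2,
                           qpcr_fold = 4, ct_sd = 0.15, n_replicates = 6,
                           tunel_rates = c(control = 0.02, treated = 0.20),
                           tunel_fields = 5, dapi_per_field = 200,
                           caspase_levels = c(control = 1, knockdown = 0.3),
                           densitometry_cv = 0.1) {
  stopifnot(reporter_fold > 0, qpcr_fold > 0, n_replicates >= 2,
            all(tunel_rates >= 0 & tunel_rates <= 1), tunel_fields >= 1,
            dapi_per_field > 0, all(caspase_levels > 0))
  structure(as.list(environment()), class = "assay_sim_spec")
}

#' Simulate validation-assay tables with planted effects
#'
#' @param spec An [assay_sim_spec()].
#' @param seed Integer seed.
#' @return A list of tibbles: `reporter` (conditions `control`/`treated`),
#'   `qpcr` (`control` is the calibrator), `tunel`, `densitometry`, plus the
#'   `spec` echo.
#' @export
simulate_assays <- function(spec = assay_sim_spec(), seed = 1) {
  stopifnot(inherits(spec, "assay_sim_spec"))
  withr::with_seed(seed, {
    n <- spec$n_replicates
    reporter <- tibble::tibble(
      cell_line = "SIMLINE",
      sirna = "control",
      condition = rep(c("control", "treated"), each = n),
      replicate = rep(seq_len(n), 2),
      firefly = 1000 * rep(c(1, spec$reporter_fold), each = n) *
        rlnorm_cv(2 * n, spec$reporter_cv),
      renilla = 1000 * rlnorm_cv(2 * n, spec$reporter_cv)
    )
    # induction lowers the target Ct by log2(fold) cycles at efficiency 2
    qpcr <- tibble::tibble(
      sample = sprintf("S%02d", seq_len(2 * n)),
      condition = rep(c("control", "treated"), each = n),
      target_ct = rep(c(26, 26 - log2(spec$qpcr_fold)), each = n) +
        stats::rnorm(2 * n, 0, spec$ct_sd),
      reference_ct = 18 + stats::rnorm(2 * n, 0, spec$ct_sd)
    )
    tunel <- purrr::imap(spec$tunel_rates, function(rate, cond) {
      dapi <- stats::rpois(spec$tunel_fields, spec$dapi_per_field)
      dapi <- pmax(dapi, 1L)
      tibble::tibble(
        condition = cond,
        field_index = seq_len(spec$tunel_fields),
        dapi_count = dapi,
        tunel_count = stats::rbinom(spec$tunel_fields, dapi, rate)
      )
    }) |> dplyr::bind_rows()
    densitometry <- tibble::tibble(
      condition = names(spec$caspase_levels),
      cc3_density = 5000 * unname(spec$caspase_levels) *
        rlnorm_cv(length(spec$caspase_levels), spec$densitometry_cv),
      loading_density = 8000 * rlnorm_cv(length(spec$caspase_levels),
                                         spec$densitometry_cv)
    )
    list(reporter = reporter, qpcr = qpcr, tunel = tunel,
         densitometry = densitometry, spec = spec)
  })
}
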