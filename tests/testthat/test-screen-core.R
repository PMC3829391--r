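test_that("well tables parse with validation, exclusion flags and column-order invariance", {
  wells <- make_plate(c(0.8, 1.0, 1.2, 2.0), c(1.9, 2.0, 2.1))
  path <- write_well_tsv(wells)
  parsed <- read_well_table(path)
  expect_equal(nrow(parsed), 7)
  expect_equal(attr(parsed, "n_excluded"), 0)

  # zero-Renilla wells are flagged, never dropped
  bad <- wells
  bad$renilla[2] <- 0
  expect_message(parsed_bad <- read_well_table(write_well_tsv(bad)), "1 well")
  expect_equal(nrow(parsed_bad), 7)
  expect_equal(sum(parsed_bad$excluded), 1)
  expect_true(parsed_bad$excluded[2])

  # shuffled column order parses identically
  shuffled <- wells[, c("renilla", "pool_id", "plate_id", "replicate",
                        "firefly", "well_id", "sample_kind")]
  expect_equal(read_well_table(write_well_tsv(shuffled)), parsed)

  # missing column is a hard error naming the column
  expect_error(read_well_table(write_well_tsv(wells[, -5])), "firefly")

  # non-numeric RLU is a row-level error carrying the row number
  corrupt <- wells
  corrupt$firefly <- as.character(corrupt$firefly)
  corrupt$firefly[3] <- "oops"
  expect_error(read_well_table(write_well_tsv(corrupt)), "row.* 3")
})

test_that("ratio normalization is exact and scale invariant", {
  expect_identical(normalize_ratio(1000, 1000), 1)
  expect_identical(normalize_ratio(500, 1000), 0.5)
  f <- c(312, 7.5, 9100)
  r <- c(1020, 88, 455)
  for (const in c(0.25, 3, 1e4)) {
    expect_equal(normalize_ratio(f * const, r * const), normalize_ratio(f, r))
  }
  expect_error(normalize_ratio(100, 0), "renilla")
})

test_that("pool summaries implement plate-matched percent of control", {
  wells <- make_plate(c(0.8, 1.0, 1.2), c(1.9, 2.0, 2.0, 2.1))
  s <- summarize_pools(wells)
  expect_equal(s$percent_of_control, 50)
  expect_equal(s$log2_effect, -1)
  expect_equal(s$direction, "down")
  expect_equal(s$n_replicates, 3)
  expect_equal(s$median_ratio, 1.0)

  # degenerate case: pool indistinguishable from controls
  flat <- make_plate(c(1, 1, 1), c(1, 1, 1, 1))
  s_flat <- summarize_pools(flat)
  expect_equal(s_flat$percent_of_control, 100)
  expect_equal(s_flat$p_value, 1)
  expect_equal(s_flat$direction, "none")

  # a pool that copies the control wells sits at exactly 100% of control
  ctrl_vals <- c(1.8, 2.0, 2.2, 2.4)
  mirror <- make_plate(ctrl_vals, ctrl_vals)
  expect_equal(summarize_pools(mirror)$percent_of_control, 100)
})

test_that("configured tests agree with the exact permutation oracle on small n", {
  set.seed(11)
  ctrl <- rnorm(8, 0, 0.2)
  pool <- c(1.1, 0.9, 1.0)
  for (method in c("student", "welch")) {
    p <- two_group_p(pool, ctrl, method = method)
    expect_lte(abs(p - oracle_perm_p(pool, ctrl)), 0.02)
  }
  # across screen-like effect sizes the t approximations stay within the
  # oracle's granularity floor (2/choose(11,3) ~ 0.012 at 3 vs 8)
  for (i in 1:8) {
    set.seed(100 + i)
    x <- rnorm(3, 1, 0.2)
    y <- rnorm(8, 0, 0.2)
    expect_lte(abs(two_group_p(x, y) - oracle_perm_p(x, y)), 0.02)
  }
  # the package's own permutation mode must match the oracle exactly
  for (i in 1:5) {
    set.seed(400 + i)
    x <- rnorm(4, 0.3, 0.5); y <- rnorm(6, 0, 0.5)
    expect_equal(two_group_p(x, y, method = "permutation"), oracle_perm_p(x, y))
  }
})

test_that("zero-variance conventions avoid NaN p-values", {
  expect_equal(two_group_p(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_equal(two_group_p(c(1, 1, 1), c(2, 2, 2)), .Machine$double.xmin)
})

test_that("plate-wide rescaling changes neither effects nor p-values", {
  sim <- simulate_screen(screen_sim_config(n_genes = 12, wells_per_plate = 48,
                                           n_neg_controls_per_plate = 8, seed = 3))
  s0 <- summarize_pools(sim$wells, sim$annotations)
  scaled <- sim$wells |>
    dplyr::group_by(plate_id) |>
    dplyr::mutate(const = 10^(dplyr::cur_group_id()),
                  firefly = firefly * const, renilla = renilla * const) |>
    dplyr::ungroup() |>
    dplyr::select(-const)
  s1 <- summarize_pools(scaled, sim$annotations)
  expect_equal(s1$percent_of_control, s0$percent_of_control, tolerance = 1e-10)
  expect_equal(s1$p_value, s0$p_value, tolerance = 1e-8)
})

test_that("pools with no usable wells are flagged, not dropped", {
  wells <- make_plate(c(0.8, 1.0), c(1, 1.1, 0.9))
  dead <- make_plate(c(1, 1), c(1, 1.1, 0.9), pool_id = "POOLDEAD")
  dead$renilla[dead$sample_kind == "pool"] <- 0
  dead$well_id <- paste0("Z", dead$well_id)
  both <- wntscreen:::validate_well_table(dplyr::bind_rows(wells, dead)) |>
    suppressMessages()
  expect_warning(s <- summarize_pools(both), "no usable wells")
  row <- s[s$pool_id == "POOLDEAD", ]
  expect_true(is.na(row$p_value))
  expect_equal(row$direction, "none")
  expect_equal(row$n_replicates, 0)
  expect_equal(nrow(s), 2)
})

test_that("volcano table sorts by p with stable pool_id tie-break and round-trips", {
  s <- tibble::tibble(
    pool_id = c("POOLC", "POOLA", "POOLB", "POOLD"),
    gene_symbol = c("G3", "G1", "G2", "G4"),
    percent_of_control = c(210.123456, 48.7654321, 100.5, 99.9),
    p_value = c(0.02, 0.005, 0.02, 1e-7)
  )
  v <- build_volcano_table(s)
  expect_equal(v$pool_id, c("POOLD", "POOLA", "POOLB", "POOLC"))

  path <- tempfile(fileext = ".tsv")
  write_volcano(v, path)
  v2 <- read_volcano(path)
  expect_equal(signif(v2$percent_of_control, 6), signif(v$percent_of_control, 6))
  expect_equal(signif(v2$p_value, 6), signif(v$p_value, 6))
  expect_equal(v2$pool_id, v$pool_id)
})
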