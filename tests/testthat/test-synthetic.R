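test_that("generators are pure functions of (config, seed)", {
  cfg <- screen_sim_config(n_genes = 40, seed = 77)
  a <- simulate_screen(cfg)
  b <- simulate_screen(cfg)
  expect_identical(a, b)
  # a different seed actually changes the draws
  c <- simulate_screen(screen_sim_config(n_genes = 40, seed = 78))
  expect_false(identical(a$wells$firefly, c$wells$firefly))
  # and the global RNG stream is left untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_screen(cfg)); after <- runif(1)
  expect_identical(before, after)

  ev1 <- simulate_evidence(a$truth, seed = 5)
  ev2 <- simulate_evidence(a$truth, seed = 5)
  expect_identical(ev1, ev2)
  ap1 <- simulate_apms(seed = 3)
  expect_identical(ap1, simulate_apms(seed = 3))
  as1 <- simulate_assays(seed = 3)
  expect_identical(as1, simulate_assays(seed = 3))
})

test_that("simulated wells respect the stated noise structure", {
  cfg <- screen_sim_config(n_genes = 100, fraction_true_regulators = 0,
                          cell_number_cv = 0.5, well_noise_cv = 0.1, seed = 12)
  sim <- simulate_screen(cfg)
  s <- summarize_pools(sim$wells, sim$annotations)

  # cell-number noise is shared between channels, so the ratio's log spread
  # reflects only the two channel draws, not the (much larger) cell CV
  ratio_sd <- sd(log(sim$wells$firefly / sim$wells$renilla))
  expect_lt(ratio_sd, 0.2)  # ~sqrt(2)*0.1; cell CV 0.5 would give ~0.5+

  # null genes sit symmetrically about the control median (sign test)
  signs <- sum(s$log2_effect > 0)
  expect_gt(binom.test(signs, nrow(s))$p.value, 0.01)
})

test_that("a regulator-free screen produces hits at no more than the alpha rate", {
  cfg <- screen_sim_config(n_genes = 300, fraction_true_regulators = 0, seed = 19)
  sim <- simulate_screen(cfg)
  s <- summarize_pools(sim$wells, sim$annotations)
  n_hits <- sum(classify_pools(s)$pool_call != "non_hit")
  # the fold filter makes the joint null rate far below alpha = 0.01; allow
  # the full binomial(n, alpha) envelope to keep this a pure null check
  expect_lte(n_hits, qbinom(0.999, 300, 0.01))
})

test_that("evidence simulation realizes its truth flags exactly", {
  sim <- simulate_screen(screen_sim_config(n_genes = 150, seed = 8))
  ev <- simulate_evidence(sim$truth, phospho_frac = c(regulator = 0.5, other = 0.05),
                          disease_frac = c(regulator = 0.5, other = 0.1), seed = 8)
  # phospho list is exactly the flagged genes
  expect_setequal(ev$phospho, ev$truth$gene_symbol[ev$truth$in_phospho_truth])
  # the dump's whole-word keyword matches are exactly the disease-flagged genes
  hit <- query_disease_genes(ev$dump, "melanoma")
  expect_setequal(hit$symbols, ev$truth$gene_symbol[ev$truth$in_disease_truth])
  # brute-force recount of the realized triple overlap from the truth table
  screen_names <- ev$truth$gene_symbol[ev$truth$is_regulator]
  v <- venn3(screen_names, ev$phospho, hit$symbols)
  brute_triple <- sum(ev$truth$is_regulator & ev$truth$in_phospho_truth &
                        ev$truth$in_disease_truth)
  expect_equal(unname(v$exclusive["abc"]), brute_triple)
})

test_that("zero overlap fractions give empty pairwise overlaps", {
  sim <- simulate_screen(screen_sim_config(n_genes = 60, seed = 2))
  ev <- simulate_evidence(sim$truth, phospho_frac = c(regulator = 0, other = 0),
                          disease_frac = c(regulator = 0, other = 0), seed = 2)
  expect_length(ev$phospho, 0)
  expect_error(query_disease_genes(ev$dump, "melanoma"), NA)
  v <- venn3(sim$truth$gene_symbol[sim$truth$is_regulator], ev$phospho,
             query_disease_genes(ev$dump, "melanoma")$symbols)
  expect_equal(unname(v$pairwise), c(0, 0, 0))
})

test_that("apms simulation boundary behavior matches its construction", {
  clean <- simulate_apms(n_prey = 30, background_rate = 0, seed = 1)
  edges <- subtract_background(clean$run, clean$control_preys)
  expect_equal(sum(edges$retained), 30)
  dirty <- simulate_apms(n_prey = 30, background_rate = 1, seed = 1)
  edges2 <- subtract_background(dirty$run, dirty$control_preys)
  expect_equal(sum(edges2$retained), 0)
  expect_true(all(simulate_apms(seed = 5)$run$spectral_counts >= 1))
})

test_that("null reporter simulations give roughly uniform p-values", {
  spec <- assay_sim_spec(reporter_fold = 1, n_replicates = 4)
  ps <- vapply(1:200, function(i) {
    sim <- simulate_assays(spec, seed = 1000 + i)
    reporter_stats(sim$reporter, "control", "treated")$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("planted assay effects are recovered in the right order", {
  sim <- simulate_assays(assay_sim_spec(
    tunel_rates = c(control = 0.02, treated = 0.20)
  ), seed = 14)
  tp <- tunel_percent(sim$tunel)
  expect_gt(tp$percent_positive[tp$condition == "treated"],
            tp$percent_positive[tp$condition == "control"])
})
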