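mk_reporter <- function(a, b, conds = c("L_CM", "WNT3A_CM")) {
  tibble::tibble(
    condition = rep(conds, c(length(a), length(b))),
    firefly = c(a, b) * 1000,
    renilla = 1000,
    replicate = c(seq_along(a), seq_along(b))
  )
}

test_that("reporter statistics match their definitions and the permutation oracle", {
  # identical groups: no difference, p = 1
  same <- mk_reporter(c(1, 1.2, 0.8), c(1, 1.2, 0.8))
  rs <- reporter_stats(same, "L_CM", "WNT3A_CM")
  expect_equal(rs$mean_difference, 0)
  expect_equal(rs$p_value, 1)

  # zero variance with unequal means: machine-minimum convention
  flat <- mk_reporter(c(1, 1, 1), c(2, 2, 2))
  expect_equal(reporter_stats(flat, "L_CM", "WNT3A_CM")$p_value,
               .Machine$double.xmin)

  # the permutation mode reproduces the exact 20-split oracle; note the
  # oracle's granularity floor at 3v3 is 2/20 = 0.1, so it can only be
  # compared against the configured permutation test, not a t-test
  d <- mk_reporter(c(0.9, 1.0, 1.1), c(1.8, 2.1, 2.0))
  p_oracle <- oracle_perm_p(c(0.9, 1.0, 1.1), c(1.8, 2.1, 2.0))
  expect_equal(p_oracle, 0.1)
  rs_perm <- reporter_stats(d, "L_CM", "WNT3A_CM", test = "permutation")
  expect_lte(abs(rs_perm$p_value - p_oracle), 0.05)
  expect_equal(rs_perm$p_value, p_oracle)
  # the default Student test detects the same near-2-fold difference
  rs2 <- reporter_stats(d, "L_CM", "WNT3A_CM")
  expect_lt(rs2$p_value, 0.05)
  expect_equal(rs2$fold_change, 1 / 1.966666667, tolerance = 1e-8)

  # tidy/glance accessors expose means, SEMs and the test
  td <- generics::tidy(rs2)
  expect_equal(td$mean_ratio, c(1.0, 59/30), tolerance = 1e-9)
  expect_equal(td$sem, c(sd(c(0.9, 1, 1.1)) / sqrt(3),
                         sd(c(1.8, 2.1, 2)) / sqrt(3)), tolerance = 1e-9)
  expect_equal(generics::glance(rs2)$p_value, rs2$p_value)

  expect_error(reporter_stats(mk_reporter(1, c(1, 2)), "L_CM", "WNT3A_CM"),
               "at least 2 replicates")
})

test_that("delta-delta-Ct relative quantification follows the stated formula", {
  recs <- tibble::tibble(
    sample = c("c1", "c2", "t1"),
    condition = c("cal", "cal", "trt"),
    target_ct = c(26, 26, 24),
    reference_ct = c(20, 20, 20)
  )
  rq <- relative_expression(recs, calibrator = "cal")
  expect_equal(rq$rq[rq$condition == "cal"], c(1, 1))     # calibrator anchors 1
  expect_equal(rq$delta_delta_ct[rq$sample == "t1"], -2)
  expect_equal(rq$rq[rq$sample == "t1"], 4)

  # shifting every Ct by a constant leaves all RQ unchanged
  shifted <- dplyr::mutate(recs, target_ct = target_ct + 3.7,
                           reference_ct = reference_ct + 3.7)
  expect_equal(relative_expression(shifted, "cal")$rq, rq$rq)

  # amplification efficiency rescales the exponent base
  expect_equal(relative_expression(recs, "cal", efficiency = 1.9)$rq[3], 1.9^2)

  # rows with missing reference Ct are excluded with a warning
  holey <- recs
  holey$reference_ct[3] <- NA
  expect_warning(out <- relative_expression(holey, "cal"), "excluded")
  expect_equal(nrow(out), 2)

  # planted 4-fold induction is recovered within 10% at 6 replicates,
  # averaged over replicated seeded simulations (a single 6-replicate
  # experiment has ~6.5% relative SE, so replication keeps the check sharp)
  rqs <- vapply(1:10, function(s) {
    sim <- simulate_assays(assay_sim_spec(qpcr_fold = 4, n_replicates = 6),
                           seed = s)
    rec <- relative_expression(sim$qpcr, calibrator = "control")
    mean(rec$rq[rec$condition == "treated"])
  }, numeric(1))
  expect_lt(abs(mean(rqs) - 4) / 4, 0.10)
})

test_that("TUNEL percent positive sums counts before dividing", {
  f <- tibble::tibble(
    condition = "trt", field_index = 1:2,
    dapi_count = c(200L, 40L), tunel_count = c(10L, 2L)
  )
  expect_equal(tunel_percent(f)$percent_positive, 5)  # 100*12/240

  zeroes <- dplyr::mutate(f, tunel_count = 0L)
  expect_equal(tunel_percent(zeroes)$percent_positive, 0)

  # invariant to re-partitioning the same totals across fields
  repart <- tibble::tibble(
    condition = "trt", field_index = 1:4,
    dapi_count = c(100L, 100L, 20L, 20L), tunel_count = c(3L, 7L, 1L, 1L)
  )
  expect_equal(tunel_percent(repart)$percent_positive,
               tunel_percent(f)$percent_positive)

  # sum-aggregation is the contract: mean of per-field percentages differs
  # on unbalanced fields (5% vs 5.0% here? use an asymmetric fixture)
  unb <- tibble::tibble(
    condition = "trt", field_index = 1:2,
    dapi_count = c(1000L, 10L), tunel_count = c(10L, 5L)
  )
  by_sum <- tunel_percent(unb)$percent_positive
  by_mean <- mean(100 * unb$tunel_count / unb$dapi_count)
  expect_equal(by_sum, 100 * 15 / 1010)
  expect_gt(abs(by_mean - by_sum), 20)  # mean-of-percent would be ~25.5

  expect_error(tunel_percent(dplyr::mutate(f, tunel_count = dapi_count + 1L)),
               "cannot exceed")
  expect_error(tunel_percent(dplyr::mutate(f, dapi_count = 0L,
                                           tunel_count = 0L)), "zero DAPI")
})

test_that("caspase densitometry normalizes to loading and the maximum condition", {
  one <- tibble::tibble(condition = "only", cc3_density = 123,
                        loading_density = 456)
  expect_equal(caspase_relative(one)$percent_of_max, 100)

  two <- tibble::tibble(condition = c("a", "b"),
                        cc3_density = c(200, 100), loading_density = c(100, 200))
  out <- caspase_relative(two)  # ratios 2.0 and 0.5
  expect_equal(out$percent_of_max, c(100, 25))

  # rescaling all loading densities by a common factor changes nothing
  rescaled <- dplyr::mutate(two, loading_density = loading_density * 7)
  expect_equal(caspase_relative(rescaled)$percent_of_max, out$percent_of_max)

  # exactly one condition sits at 100 (ties allowed)
  sim <- simulate_assays(seed = 6)
  pm <- caspase_relative(sim$densitometry)$percent_of_max
  expect_equal(max(pm), 100)
  expect_true(all(pm > 0 & pm <= 100))

  expect_error(caspase_relative(dplyr::mutate(two, cc3_density = 0)), "zero")
  expect_error(caspase_relative(dplyr::mutate(two, loading_density = 0)),
               "positive")
})
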