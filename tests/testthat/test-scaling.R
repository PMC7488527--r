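pre_dc <- c("early_cleavages", "late_cleavages", "germ_band_extension",
            "germ_band_retraction", "dorsal_closure")

test_that("stage proportions reproduce the published scaling values", {
  pp <- stage_proportions(cmac_stage_durations(), pre_dc)
  lc <- pp[pp$stage == "late_cleavages", ]
  expect_equal(round(lc$proportion[lc$temp_set == 32], 2), 0.15)
  expect_equal(round(lc$proportion[lc$temp_set == 20], 2), 0.12)
  expect_equal(round(lc$proportion[lc$temp_set == 23], 2), 0.12)
  # proportions of a fully partitioned span sum to 1 at every regime
  sums <- as.numeric(tapply(pp$proportion, pp$temp_set, sum))
  expect_equal(sums, rep(1, 5), tolerance = 0.01)
  # a stage equal to the whole span has proportion 1
  single <- stage_proportions(cmac_stage_durations(), "early_cleavages")
  expect_equal(single$proportion, rep(1, 5))
})

test_that("proportions are invariant to the time unit", {
  dd <- cmac_stage_durations()
  p_h <- stage_proportions(dd, pre_dc)
  dd_days <- dd
  dd_days$duration_h <- dd$duration_h / 24
  p_d <- stage_proportions(dd_days, pre_dc)
  expect_equal(p_h$proportion, p_d$proportion, tolerance = 1e-12)
})

test_that("post/pre dorsal-closure span ratios match the published sequence", {
  sr <- span_ratio(cmac_transition_times(),
                   numerator = c("dorsal_closure", "boring"),
                   denominator = c(NA, "dorsal_closure"))
  expect_equal(round(sr$ratio[sr$temp_set == 20], 2), 1.09)
  expect_equal(round(sr$ratio[sr$temp_set == 32], 2), 1.05)
  # the published middle values (0.99, 1.00, 0.99) were computed from
  # unrounded transitions; from the printed table they agree to 0.01
  expect_equal(sr$ratio, c(1.09, 0.99, 1.00, 0.99, 1.05), tolerance = 0.011)
  # identical spans give exactly 1
  same <- span_ratio(cmac_transition_times(),
                     numerator = c(NA, "dorsal_closure"),
                     denominator = c(NA, "dorsal_closure"))
  expect_equal(same$ratio, rep(1, 5))
})

test_that("span ratios are invariant to a common time shift", {
  tt <- cmac_transition_times()
  # both spans defined by transitions (no oviposition anchor): shift cancels
  sr1 <- span_ratio(tt, c("early_cleavages", "dorsal_closure"),
                    c("dorsal_closure", "boring"))
  tt2 <- tt
  tt2$transition_h <- tt$transition_h + 5
  sr2 <- span_ratio(tt2, c("early_cleavages", "dorsal_closure"),
                    c("dorsal_closure", "boring"))
  expect_equal(sr1$ratio, sr2$ratio, tolerance = 1e-12)
})

test_that("LTT spread summarizes per-stage thresholds as order statistics", {
  dd <- cmac_stage_durations()
  fits <- fit_stage_norms(dd[dd$stage %in% pre_dc, ])
  sp <- ltt_spread(fits)
  ltts <- vapply(fits, function(f) f$ltt_c, numeric(1))
  expect_equal(sp$min, min(ltts))
  expect_equal(sp$max, max(ltts))
  expect_equal(sp$range, diff(range(ltts)))
  expect_equal(sp$min_stage, "late_cleavages")
  # identical fits: range zero, isomorphy-compatible
  same <- ltt_spread(list(fits[[1]], fits[[1]]))
  expect_equal(same$range, 0)
  expect_true(same$isomorphy_compatible)
})

test_that("a common true threshold is recovered with a tight range", {
  # three stages sharing LTT = 14 degC, low noise
  set.seed(10)
  tc <- c(20, 23, 26, 29, 32)
  fits <- lapply(c(0.004, 0.008, 0.012), function(b) {
    r <- b * (tc - 14) * exp(rnorm(5, 0, 0.01))
    fit_linear_norm(tc, r, "per_hour")
  })
  sp <- ltt_spread(fits, tol = 1)
  expect_lt(sp$range, 1)
  expect_true(sp$isomorphy_compatible)
})

test_that("pupa:feeding ratios are reported under both definitions", {
  pr <- pupa_feeding_ratio(summaries = cmac_individual_summaries())
  expect_equal(round(pr$ratio_of_medians[pr$temp_c == 20], 2), 0.26)
  expect_true(all(diff(pr$ratio_of_medians) > -0.05))  # rises with temperature
  expect_true(all(is.na(pr$median_of_ratios)))

  cfg <- default_sim_config(cv = 0.1, n_individuals = 200L)
  sim <- simulate_cohort(cfg, seed = 6)
  pr2 <- pupa_feeding_ratio(records = sim$individuals)
  expect_false(any(is.na(pr2$median_of_ratios)))
  expect_equal(pr2$median_of_ratios, pr2$ratio_of_medians, tolerance = 0.1)
})
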