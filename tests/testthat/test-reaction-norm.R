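test_that("differencing transitions reproduces the published durations", {
  tt <- cmac_transition_times()
  d <- durations_from_transitions(tt)
  expect_equal(
    d$duration_h[d$stage == "germ_band_retraction" & d$temp_c == 19.8],
    107.90 - 54.63)
  expect_equal(d$duration_h[d$stage == "early_cleavages" & d$temp_c == 19.8],
               14.10)
  # sum of durations equals the final transition time, exactly
  for (tp in unique(d$temp_set))
    expect_equal(sum(d$duration_h[d$temp_set == tp]),
                 max(tt$transition_h[tt$temp_set == tp]))
  # degenerate: a repeated transition time is flagged with the pair named
  bad <- data.frame(stage = factor(c("a", "b"), levels = c("a", "b"),
                                   ordered = TRUE),
                    temp_c = 20, transition_h = c(50, 50))
  expect_error(durations_from_transitions(bad), "non-monotone")
})

test_that("rates are reciprocal durations with explicit unit conversion", {
  expect_equal(rates_from_durations(24, "per_day"), 1.0)
  expect_equal(rates_from_durations(10, "per_hour"), 0.1)
  expect_equal(rates_from_durations(10, "per_day"), 2.4)
  expect_equal(round(269.90 / 24, 1), 11.2)  # hatching time in days at 19.8 degC
  expect_error(rates_from_durations(c(5, 0)), "positive")
})

test_that("OLS norms agree with the closed-form normal equations", {
  set.seed(42)
  for (i in 1:5) {
    tc <- c(20, 23, 26, 29, 32)
    r <- 0.01 * (tc - 12) + rnorm(5, 0, 0.005)
    f <- fit_linear_norm(tc, r, "per_day")
    b_hat <- cov(tc, r) / var(tc)
    a_hat <- mean(r) - b_hat * mean(tc)
    expect_equal(f$a, a_hat, tolerance = 1e-12)
    expect_equal(f$b, b_hat, tolerance = 1e-12)
  }
})

test_that("an exact line is recovered with R2 = 1 and zero-SE threshold", {
  tc <- c(15, 20, 25, 30)
  f <- fit_linear_norm(tc, 0.01 * (tc - 10), "per_day")
  expect_equal(f$a, -0.1, tolerance = 1e-12)
  expect_equal(f$b, 0.01, tolerance = 1e-12)
  expect_equal(f$r2, 1)
  expect_equal(f$ltt_c, 10)
  expect_true(f$linear_ok)
  for (m in c("campbell", "delta"))
    expect_equal(ltt_se(f, m), 0, tolerance = 1e-9)
})

test_that("published LTT and R2 values are reproduced from the duration table", {
  dd <- cmac_stage_durations()
  norm_of <- function(st) {
    d <- dd[dd$stage == st, ]
    fit_linear_norm(d$temp_c, 1 / d$duration_h, "per_hour")
  }
  expect_equal(round(norm_of("germ_band_extension")$ltt_c, 1), 16.7)
  expect_equal(round(norm_of("hatching")$ltt_c, 1), 15.7)
  expect_equal(round(norm_of("boring")$ltt_c, 1), 14.5)
  fm <- norm_of("final_morphogenesis")
  expect_equal(round(fm$r2, 2), 0.86)
  expect_false(fm$linear_ok)  # routed to the quadratic path by the gate
  expect_equal(round(norm_of("sclerotization")$r2, 2), 0.88)
})

test_that("threshold and thermal constant follow the closed forms", {
  expect_equal(round(ltt(-0.1607, 0.01295), 1), 12.4)
  expect_equal(round(ltt(-0.2269, 0.01479), 1), 15.3)
  expect_equal(ltt(0, 0.01), 0)
  expect_error(ltt(0.1, -0.01), "positive")
  expect_equal(round(thermal_constant(0.00527, "per_day")["degree_days"], 1),
               c(degree_days = 189.8))
  expect_equal(round(thermal_constant(0.01295, "per_day")["degree_days"], 1),
               c(degree_days = 77.2))
  k <- thermal_constant(0.00067, "per_hour")
  expect_equal(round(k[["degree_hours"]], 1), 1492.5)
  expect_equal(round(k[["degree_days"]], 1), 62.2)
  # unit scaling: degree-days = degree-hours / 24, to machine precision
  expect_equal(k[["degree_days"]], k[["degree_hours"]] / 24)
})

test_that("LTT and its SE are invariant to the rate unit", {
  tc <- c(20, 23, 26, 29, 32)
  set.seed(7)
  r_h <- 0.002 * (tc - 13) + rnorm(5, 0, 0.0004)
  fh <- fit_linear_norm(tc, r_h, "per_hour")
  fd <- fit_linear_norm(tc, 24 * r_h, "per_day")
  expect_equal(fh$ltt_c, fd$ltt_c, tolerance = 1e-12)
  expect_equal(fh$k_dd, fd$k_dd, tolerance = 1e-9)
  for (m in c("campbell", "delta"))
    expect_equal(ltt_se(fh, m), ltt_se(fd, m), tolerance = 1e-9)
})

test_that("delta-method LTT SE is close to a parametric bootstrap", {
  tc <- c(20, 23, 26, 29, 32)
  set.seed(123)
  r <- 0.01 * (tc - 14) + rnorm(5, 0, 0.004)
  f <- fit_linear_norm(tc, r, "per_day")
  se_d <- ltt_se(f, "delta")
  se_b <- ltt_se(f, "bootstrap", B = 10000L, seed = 99)
  expect_lt(abs(se_d - se_b) / se_b, 0.15)
})

test_that("quadratic norms find the lower temperature-axis crossing", {
  expect_equal(round(quad_lower_root(-0.0021, 0.1219, -1.443), 1), 16.6)
  expect_equal(quad_lower_root(0, 0.01, -0.1), 10)
  r <- quad_lower_root(-0.0021, 0.1219, -1.443)
  expect_lt(abs(-0.0021 * r^2 + 0.1219 * r - 1.443), 1e-10)
  expect_true(is.na(quad_lower_root(-0.001, 0.01, -1)))  # no real root
  # fitting exactly quadratic data recovers the coefficients
  tc <- c(18, 21, 24, 27, 30, 33)
  r2 <- -0.002 * tc^2 + 0.12 * tc - 1.4
  qf <- fit_quadratic_norm(tc, r2, "per_day")
  expect_equal(qf$c2, -0.002, tolerance = 1e-9)
  expect_equal(qf$lower_root_c, quad_lower_root(-0.002, 0.12, -1.4),
               tolerance = 1e-6)
})

test_that("strong curvature falls below the linearity gate and is rerouted", {
  tc <- c(18, 21, 24, 27, 30, 33)
  r <- -0.004 * (tc - 25.5)^2 + 0.3
  lin <- fit_linear_norm(tc, r, "per_day")
  expect_lt(lin$r2, 0.97)
  auto <- fit_reaction_norm(tc, r, "per_day")
  expect_equal(auto$model, "quadratic")
  expect_s3_class(attr(auto, "linear_fit"), "reaction_norm_fit")
})

test_that("fit_linear_norm enforces at least three temperatures", {
  expect_error(fit_linear_norm(c(20, 25), c(0.1, 0.2), "per_day"),
               "3 distinct")
})
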