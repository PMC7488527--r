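test_that("individual rates are reciprocal durations with exclusion bookkeeping", {
  rec <- data.frame(
    id = 1:4, temp_c = 20, sex = c("female", "male", "female", "male"),
    larva_d = c(38.9, 40, NA, 40), pupa_d = c(10.3, 10, 9.5, 10),
    flag = c("", "", "", "discarded")
  )
  expect_message(r <- individual_rates(rec), "excluded")
  expect_equal(r$rate[r$stage == "pupa" & r$id == 1], 1 / 10.3)
  expect_equal(sum(r$stage == "larva"), 2L)  # one NA, one flagged
  expect_equal(sum(r$stage == "pupa"), 3L)
  expect_equal(individual_rates(rec[1, ])$rate[1], 1 / 38.9)
})

test_that("homoskedastic data reduce the GLS fit to OLS", {
  d <- make_gls_data(60, sigma = c(1, 1, 1, 1), seed = 21)
  fit <- fit_gls_varident(d, "y")
  X <- stagetherm:::gls_design(d$temp_c, d$sex)
  ols <- qr.coef(qr(X), d$y)
  expect_equal(unname(fit$coefficients), unname(ols), tolerance = 1e-5)
  expect_true(all(abs(fit$multipliers - 1) < 0.5))
})

test_that("a 4:1 stratum variance ratio is recovered", {
  errs <- vapply(1:20, function(s) {
    d <- make_gls_data(500, sigma = sqrt(c(1, 1, 1, 4)), seed = 100 + s)
    fit <- fit_gls_varident(d, "y")
    fit$multipliers[length(fit$multipliers)]
  }, numeric(1))
  expect_lt(abs(median(errs) - 4) / 4, 0.15)
})

test_that("sequential F statistics equal the brute-force nested-RSS oracle", {
  d <- make_gls_data(40, beta = c(1, 0.05, 0.2, 0.01),
                     sigma = sqrt(c(1, 2, 0.5, 4)), seed = 33)
  fit <- fit_gls_varident(d, "y")
  X <- stagetherm:::gls_design(d$temp_c, d$sex)
  F_oracle <- seqF_oracle(X, d$y, fit$weights)
  expect_equal(fit$anova$F, unname(F_oracle), tolerance = 1e-8)
  expect_equal(fit$anova$df2, rep(nrow(d) - 4L, 3))
})

test_that("the GLS fit matches nlme::gls with varIdent weights", {
  skip_if_not_installed("nlme")
  d <- make_gls_data(50, beta = c(1, 0.04, 0.3, 0.02),
                     sigma = sqrt(c(1, 3, 0.5, 2)), seed = 8)
  fit <- fit_gls_varident(d, "y")
  d$tc <- d$temp_c - mean(d$temp_c)
  d$sx <- ifelse(d$sex == "female", 0.5, -0.5)
  d$stratum <- interaction(factor(d$temp_c), factor(d$sex), drop = TRUE)
  g <- nlme::gls(y ~ tc + sx + tc:sx, data = d,
                 weights = nlme::varIdent(form = ~ 1 | stratum),
                 method = "REML")
  expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-5)
  # nlme reports SD ratios relative to its reference stratum
  vf <- nlme::varWeights(g$modelStruct$varStruct)
  s2_nlme <- as.numeric(g$sigma^2 / tapply(vf, d$stratum, function(x) x[1])^2)
  expect_equal(as.numeric(fit$sigma2 / fit$sigma2[1]),
               s2_nlme / s2_nlme[1], tolerance = 1e-3)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(g)))), tolerance = 1e-3)
})

test_that("GLS coefficients are invariant to a common variance rescaling", {
  d <- make_gls_data(50, sigma = sqrt(c(1, 2, 3, 4)), seed = 13)
  f1 <- fit_gls_varident(d, "y")
  d2 <- d; d2$y <- d$y * 1  # same data; rescale all variances via response
  # multiplying the response by c scales all variances by c^2 but leaves
  # standardized structure: coefficients scale exactly by c
  d2$y <- 3 * d$y
  f2 <- fit_gls_varident(d2, "y")
  expect_equal(unname(f2$coefficients), 3 * unname(f1$coefficients),
               tolerance = 1e-8)
  expect_equal(unname(f2$multipliers), unname(f1$multipliers),
               tolerance = 1e-6)
  expect_equal(f2$anova$F, f1$anova$F, tolerance = 1e-6)
})

test_that("df bookkeeping matches the N minus coefficients rule", {
  # 574 individuals across 5 temperatures and 2 sexes -> denominator df 570
  set.seed(77)
  n <- 574
  tc <- sample(c(20, 23, 26, 29, 32), n, replace = TRUE)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  d <- data.frame(temp_c = tc, sex = sex,
                  y = 0.1 + 0.005 * tc + rnorm(n, 0, 0.02))
  fit <- fit_gls_varident(d, "y")
  expect_equal(unique(fit$anova$df2), 570L)
})

test_that("stage summaries follow the quantile convention", {
  rec <- data.frame(id = 1:3, temp_c = 20, sex = "female",
                    pupa_d = c(9.8, 10.3, 10.8))
  s <- summarize_stages(rec)
  expect_equal(s$median_d, 10.3)
  expect_equal(s$q1_d, 10.05)
  expect_equal(s$q3_d, 10.55)
  one <- summarize_stages(data.frame(id = 1, temp_c = 25, sex = "male",
                                     pupa_d = 5))
  expect_equal(c(one$median_d, one$q1_d, one$q3_d), c(5, 5, 5))
  # lognormal sample: empirical median near exp(meanlog)
  set.seed(4)
  big <- data.frame(id = 1:1000, temp_c = 25, sex = "female",
                    larva_d = rlnorm(1000, log(20), 0.1))
  sb <- summarize_stages(big)
  expect_lt(abs(sb$median_d - 20) / 20, 0.02)
})

test_that("mass analysis detects a sex offset and the temperature-size rule", {
  cfg <- default_sim_config(cv = 0.05, n_individuals = 100L)
  hits <- vapply(1:20, function(s) {
    sim <- simulate_cohort(cfg, seed = 300 + s)
    ma <- mass_analysis(sim$individuals)
    ma$fit$anova$p[ma$fit$anova$term == "sex"] < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.9)
  sim <- simulate_cohort(cfg, seed = 55)
  ma <- mass_analysis(sim$individuals)
  # females heavier, and negative temperature trend overall
  expect_gt(ma$fit$coefficients[["sex"]], 0)
  expect_lt(ma$fit$coefficients[["temp"]], 0)
  expect_equal(nrow(ma$summary), 10L)
})

test_that("zero-noise masses recover the configured sex offset exactly", {
  cfg <- default_sim_config(cv = 0.05, n_individuals = 40L)
  cfg$mass_sd <- 0
  cfg$mass_female <- c(0, 0, 6.95)
  cfg$mass_male <- c(0, 0, 5.05)
  sim <- simulate_cohort(cfg, seed = 2)
  ma <- mass_analysis(sim$individuals)
  expect_equal(unname(ma$fit$coefficients["sex"]), 1.9, tolerance = 1e-8)
  expect_equal(unname(ma$fit$coefficients["temp"]), 0, tolerance = 1e-10)
})
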