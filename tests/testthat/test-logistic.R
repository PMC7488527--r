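test_that("replicate pooling follows the round-to-hour rule", {
  s <- make_samples(c(36.4, 35.8), n_past = c(3, 5), n_total = c(10, 12))
  p <- pool_replicates(s)
  expect_equal(nrow(p), 1L)
  expect_equal(p$age_h, 36)
  expect_equal(p$n_total, 22)
  expect_equal(p$n_past, 8)

  one <- make_samples(36.4, 3, 10)
  expect_equal(pool_replicates(one)[names(one)], one)

  sep <- make_samples(c(36.4, 37.2), c(3, 5), c(10, 12))
  expect_equal(nrow(pool_replicates(sep)), 2L)
  expect_equal(pool_replicates(sep)$age_h, c(36.4, 37.2))

  mixed <- rbind(make_samples(10, 1, transition = "a"),
                 make_samples(10, 1, transition = "b"))
  expect_error(pool_replicates(mixed), "different transitions")
})

test_that("a symmetric design puts the median transition at its centre", {
  s <- make_samples(c(4, 5, 6), n_past = c(0, 5, 10))
  for (m in c("ml", "firth")) {
    fit <- fit_transition(s, method = m)
    expect_equal(fit$t50, 5, tolerance = 1e-6)
    expect_true(fit$beta1 > 0)
    expect_equal(plogis(fit$beta0 + fit$beta1 * fit$t50), 0.5)
  }
})

test_that("ML and Firth estimates match a brute-force 2-D maximization", {
  datasets <- list(
    make_samples(c(4, 5, 6), c(1, 5, 9)),
    make_samples(c(10, 14, 18, 22), c(0, 3, 8, 10)),
    make_samples(c(2, 3, 4, 5, 6, 7), c(0, 1, 4, 7, 9, 10)),
    make_samples(c(30, 36, 42), c(2, 6, 11), n_total = 12)
  )
  for (s in datasets) {
    ml <- fit_logistic_ml(s)
    got <- c(ml$beta0, ml$beta1)
    want <- grid_maximize(
      function(b) binom_loglik(b, s$age_h, s$n_past, s$n_total),
      center = got, span = c(2, 0.5))
    expect_equal(got, want, tolerance = 1e-4)

    fi <- fit_logistic_firth(s)
    gotf <- c(fi$beta0, fi$beta1)
    wantf <- grid_maximize(
      function(b) firth_loglik(b, s$age_h, s$n_past, s$n_total),
      center = gotf, span = c(2, 0.5))
    expect_equal(gotf, wantf, tolerance = 1e-4)
  }
})

test_that("ML agrees with the standard glm fit on non-separated data", {
  s <- make_samples(c(2, 3, 4, 5, 6, 7), c(0, 1, 4, 7, 9, 10))
  fit <- fit_logistic_ml(s)
  g <- glm(cbind(n_past, n_total - n_past) ~ age_h, binomial, data = s,
           control = glm.control(epsilon = 1e-12))
  expect_equal(unname(c(fit$beta0, fit$beta1)), unname(coef(g)),
               tolerance = 1e-6)
  expect_equal(unname(c(fit$se0, fit$se1)),
               unname(summary(g)$coefficients[, 2]), tolerance = 1e-4)
})

test_that("complete separation is detected and Firth still yields the midpoint", {
  s <- make_samples(c(4, 6), c(0, 10))
  expect_warning(ml <- fit_logistic_ml(s), "separation")
  expect_true(ml$separation)

  fi <- fit_logistic_firth(s)
  expect_true(all(is.finite(c(fi$beta0, fi$beta1))))
  expect_true(fi$separation)
  expect_equal(fi$t50, 5, tolerance = 1e-6)

  auto <- fit_transition(s, method = "auto")
  expect_equal(auto$method, "firth")
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_logistic_ml(make_samples(c(4, 5), c(0, 0))),
               "no transition observed")
  expect_error(fit_logistic_ml(make_samples(c(4, 5), c(10, 10))),
               "no transition observed")
  expect_error(fit_logistic_firth(make_samples(c(5, 5), c(2, 8))),
               "distinct")
})

test_that("Firth estimates approach ML as counts grow", {
  s <- make_samples(c(2, 3, 4, 5, 6, 7), c(0, 1, 4, 7, 9, 10))
  big <- s
  big$n_total <- s$n_total * 100L
  big$n_past <- s$n_past * 100L
  ml <- fit_logistic_ml(big)
  fi <- fit_logistic_firth(big)
  expect_equal(fi$beta1, ml$beta1, tolerance = 2e-3)
  expect_equal(fi$t50, ml$t50, tolerance = 1e-3)
  # at the original counts the gap is visibly larger
  gap_small <- abs(fit_logistic_firth(s)$beta1 - fit_logistic_ml(s)$beta1)
  gap_big <- abs(fi$beta1 - ml$beta1)
  expect_lt(gap_big, gap_small / 10)
})

test_that("t50 is location- and scale-equivariant", {
  s <- make_samples(c(10, 14, 18, 22), c(0, 3, 8, 10))
  base <- fit_logistic_ml(s)$t50
  for (m in c("ml", "firth")) {
    sh <- s; sh$age_h <- s$age_h + 7.5
    t_m <- fit_transition(s, method = m)$t50
    expect_equal(fit_transition(sh, method = m)$t50, t_m + 7.5,
                 tolerance = 1e-6)
    sc <- s; sc$age_h <- s$age_h * 3
    expect_equal(fit_transition(sc, method = m)$t50, 3 * t_m,
                 tolerance = 1e-6)
  }
  expect_equal(base, fit_transition(s, method = "ml")$t50)
})

test_that("median_transition_time validates the slope sign", {
  s <- make_samples(c(4, 5, 6), c(0, 5, 10))
  fit <- fit_logistic_ml(s)
  expect_equal(median_transition_time(fit), -fit$beta0 / fit$beta1)
  bad <- fit
  bad$beta1 <- -bad$beta1
  expect_error(median_transition_time(bad), "non-monotone")
  direct <- fit
  direct$beta0 <- -5; direct$beta1 <- 0.05
  expect_equal(median_transition_time(direct), 100)
})

test_that("zero-noise pipeline t50 lands within half a grid step of truth", {
  sp <- data.frame(stage = "s1", law = "linear", a = -0.1, b = 0.008,
                   unit = "per_hour", mode = "destructive", cv = 0)
  temps <- data.frame(regime = 25, temp_c = 25)
  truth <- 1 / (-0.1 + 0.008 * 25)  # 10 h
  step <- 0.5
  sched <- data.frame(regime = 25, age_h = seq(5, 15, by = step), n = 30L)
  cfg <- sim_config(sp, temps, sched, collection_window_min = 0, seed = 3)
  sim <- simulate_cohort(cfg)
  fit <- fit_transition(sim$samples, method = "auto")
  expect_lt(abs(fit$t50 - truth), step / 2)
})
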