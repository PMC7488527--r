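# Independent oracles and small fixture builders used across the suite.

# Build a one-transition sample table.
make_samples <- function(age_h, n_past, n_total = 10L, temp_c = 25,
                         regime = temp_c, transition = "t") {
  data.frame(regime = regime, temp_c = temp_c, age_h = age_h,
             transition = transition,
             n_total = rep_len(n_total, length(age_h)), n_past = n_past,
             stringsAsFactors = FALSE)
}

# Binomial logistic log-likelihood on the original age scale.
binom_loglik <- function(beta, age, y, m) {
  eta <- beta[1] + beta[2] * age
  sum(y * eta - m * ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30)))))
}

# Jeffreys-penalized objective: l(beta) + 0.5 * log det I(beta).
firth_loglik <- function(beta, age, y, m) {
  eta <- beta[1] + beta[2] * age
  p <- plogis(eta)
  w <- m * p * (1 - p)
  X <- cbind(1, age)
  info <- crossprod(X, X * w)
  ld <- determinant(info, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  binom_loglik(beta, age, y, m) + 0.5 * as.numeric(ld$modulus)
}

# Derivative-free nested grid-refinement maximizer over 2 parameters.
grid_maximize <- function(fn, center, span, iters = 8L, n = 41L) {
  for (i in seq_len(iters)) {
    g1 <- seq(center[1] - span[1], center[1] + span[1], length.out = n)
    g2 <- seq(center[2] - span[2], center[2] + span[2], length.out = n)
    vals <- matrix(NA_real_, n, n)
    for (a in seq_len(n)) for (b in seq_len(n))
      vals[a, b] <- fn(c(g1[a], g2[b]))
    ix <- arrayInd(which.max(vals), dim(vals))
    center <- c(g1[ix[1]], g2[ix[2]])
    span <- span * 4 / (n - 1)  # keep two grid cells on each side
  }
  center
}

# Brute-force sequential type-I F statistics on weighted data, fitting each
# nested model independently with lm() and comparing residual sums of
# squares (the nesting order is intercept, temp, sex, temp:sex).
seqF_oracle <- function(X, y, w) {
  rss <- vapply(1:4, function(k) {
    sum(w * lm.wfit(X[, 1:k, drop = FALSE], y, w)$residuals^2)
  }, numeric(1))
  df_res <- length(y) - 4L
  s2 <- rss[4] / df_res
  (rss[1:3] - rss[2:4]) / s2
}

# Individual records with a known GLS structure.
make_gls_data <- function(n_per_stratum, temps = c(20, 30),
                          beta = c(1, 0.05, 0.2, 0),
                          sigma = NULL, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(temp_c = temps, sex = c("female", "male"),
                      stringsAsFactors = FALSE)
  if (is.null(sigma)) sigma <- rep(1, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    tc <- grid$temp_c[i] - mean(rep(temps, each = 1))
    sx <- if (grid$sex[i] == "female") 0.5 else -0.5
    mu <- beta[1] + beta[2] * tc + beta[3] * sx + beta[4] * tc * sx
    data.frame(temp_c = grid$temp_c[i], sex = grid$sex[i],
               y = mu + rnorm(n_per_stratum, 0, sigma[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Simulator configuration with purely linear stage laws (ground truth for
# pipeline parameter-recovery checks).
linear_sim_config <- function(cv = 0.05, n_per_sample = 50L, seed = 1L) {
  dur <- cmac_stage_durations()
  stages <- levels(droplevels(dur$stage))
  rows <- lapply(stages, function(st) {
    d <- dur[dur$stage == st, ]
    cf <- coef(lm(I(1 / d$duration_h) ~ d$temp_c))
    data.frame(stage = st, law = "linear", a = unname(cf[1]),
               b = unname(cf[2]), c2 = NA, c1 = NA, c0 = NA,
               unit = "per_hour", mode = "destructive", cv = cv, b_sex = 0,
               stringsAsFactors = FALSE)
  })
  sp <- do.call(rbind, rows)
  temps <- data.frame(regime = c(20, 23, 26, 29, 32),
                      temp_c = c(19.8, 22.7, 25.6, 28.6, 31.7))
  cfg <- sim_config(sp, temps, schedule = NULL, n_individuals = 0L,
                    seed = seed)
  cfg$schedule <- transition_schedule(cfg, n_per_sample = n_per_sample)
  cfg
}
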