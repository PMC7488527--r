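#' Stage durations from consecutive median transition times
#'
#' The duration of stage k at a given temperature is the difference between
#' the median transition times of stages k and k-1; the first stage's
#' duration equals its transition time. Durations therefore sum exactly to
#' the final transition time at every temperature.
#'
#' @param transitions Data frame with columns `stage` (ordered factor or
#'   character in developmental order), `temp_c`, `transition_h`, and
#'   optionally `temp_set`/`block`/`regime` which are carried through.
#'   One row per stage x temperature.
#' @return The input with a `duration_h` column appended.
#' @export
#' @examples
#' durations_from_transitions(cmac_transition_times())
durations_from_transitions <- function(transitions) {
  need <- c("stage", "temp_c", "transition_h")
  if (!all(need %in% names(transitions)))
    stop("need columns: ", paste(need, collapse = ", "))
  key <- if ("temp_set" %in% names(transitions))
    transitions$temp_set else transitions$temp_c
  out <- transitions
  out$duration_h <- NA_real_
  for (tp in unique(key)) {
    idx <- which(key == tp)
    idx <- idx[order(transitions$stage[idx])]
    tt <- transitions$transition_h[idx]
    d <- diff(c(0, tt))
    bad <- which(d <= 0)
    if (length(bad)) {
      st <- as.character(transitions$stage[idx])
      stop(sprintf(
        "non-monotone transitions at temperature %s: '%s' (%.2f h) does not follow '%s' (%.2f h)",
        format(tp), st[bad[1L]], tt[bad[1L]],
        if (bad[1L] > 1L) st[bad[1L] - 1L] else "oviposition",
        if (bad[1L] > 1L) tt[bad[1L] - 1L] else 0))
    }
    out$duration_h[idx] <- d
  }
  out
}

#' Convert stage durations to developmental rates
#'
#' Developmental rate is the reciprocal stage duration, R = 1/D. Durations
#' in hours convert to per-day rates as R_d = 24/D_h.
#'
#' @param durations Data frame with a `duration_h` column (or a numeric
#'   vector of durations in hours).
#' @param out_unit `"per_hour"` or `"per_day"`.
#' @return For a data frame input, the input with `rate` and `rate_unit`
#'   columns appended; for a numeric vector, a numeric vector of rates.
#' @export
rates_from_durations <- function(durations, out_unit = c("per_hour", "per_day")) {
  out_unit <- match.arg(out_unit)
  fac <- if (out_unit == "per_day") 24 else 1
  if (is.numeric(durations)) {
    if (any(durations <= 0)) stop("durations must be positive")
    return(fac / durations)
  }
  if (!"duration_h" %in% names(durations)) stop("need a duration_h column")
  if (any(durations$duration_h <= 0)) stop("durations must be positive")
  durations$rate <- fac / durations$duration_h
  durations$rate_unit <- out_unit
  durations
}

#' Lower temperature threshold from linear rate coefficients
#'
#' The temperature at which the extrapolated linear rate-temperature
#' regression R = a + b*T crosses zero rate: `-a/b`. Invariant to the rate
#' unit, since both a and b rescale together.
#'
#' @param a Rate intercept.
#' @param b Rate slope per degree Celsius; must be positive.
#' @return LTT in degrees Celsius.
#' @export
#' @examples
#' ltt(-0.1607, 0.01295) # pupal threshold, 12.4 degC
ltt <- function(a, b) {
  if (any(b <= 0)) stop("slope b must be positive for a lower threshold")
  -a / b
}

#' Thermal constant (degree-hours and degree-days) from a rate slope
#'
#' Under the linear degree-day model the thermal sum needed to complete a
#' stage is K = 1/b, in degree-hours when the rate is per hour and
#' degree-days when per day; degree-days = degree-hours / 24.
#'
#' @param b Rate slope per degree Celsius (positive).
#' @param rate_unit Unit of the rate the slope belongs to.
#' @return Named numeric vector `c(degree_hours, degree_days)`.
#' @export
#' @examples
#' thermal_constant(0.01295, "per_day") # 77.2 degree-days
thermal_constant <- function(b, rate_unit = c("per_hour", "per_day")) {
  rate_unit <- match.arg(rate_unit)
  if (any(b <= 0)) stop("slope b must be positive")
  k <- 1 / b
  if (rate_unit == "per_hour")
    c(degree_hours = k, degree_days = k / 24)
  else
    c(degree_hours = k * 24, degree_days = k)
}

#' Fit a linear thermal reaction norm to developmental rates
#'
#' Ordinary least squares of rate on temperature, R = a + b*T. A fit is
#' accepted as linear when R-squared reaches the linearity gate (default
#' 0.97); below the gate the fit is flagged and the quadratic path
#' ([fit_quadratic_norm()]) is recommended. For linear fits the lower
#' temperature threshold (-a/b, with an approximate standard error) and the
#' thermal constant (1/b) are populated.
#'
#' @param temp_c Temperatures (degC); at least 3 distinct values.
#' @param rate Developmental rates, one or more per temperature.
#' @param rate_unit Unit of `rate`.
#' @param r2_gate Minimum R-squared for the linear model to be accepted.
#' @param stage Optional stage label carried into the result.
#' @param se_method Method for the LTT standard error, see [ltt_se()].
#' @return Object of class `reaction_norm_fit`: `model` (`"linear"`),
#'   `linear_ok`, `a`, `b`, `se_a`, `se_b`, `s2` (residual mean square),
#'   `N`, `r2`, `ltt_c`, `se_ltt_c`, `k_dh`, `k_dd`, `rate_unit`, plus the
#'   data and coefficient covariance for downstream use.
#' @export
#' @examples
#' d <- subset(cmac_stage_durations(), stage == "germ_band_extension")
#' f <- fit_linear_norm(d$temp_c, 1 / d$duration_h, "per_hour")
#' round(f$ltt_c, 1) # 16.7
fit_linear_norm <- function(temp_c, rate, rate_unit = c("per_hour", "per_day"),
                            r2_gate = 0.97, stage = NULL,
                            se_method = "campbell") {
  rate_unit <- match.arg(rate_unit)
  if (length(unique(temp_c)) < 3L)
    stop("need at least 3 distinct temperatures for a reaction norm")
  stopifnot(length(temp_c) == length(rate))
  fit <- stats::lm(rate ~ temp_c)
  # summary.lm warns on an exactly collinear response; that case is fine here
  sm <- suppressWarnings(summary(fit))
  a <- unname(stats::coef(fit)[1L]); b <- unname(stats::coef(fit)[2L])
  out <- list(
    stage = stage, model = "linear",
    a = a, b = b,
    se_a = sm$coefficients[1L, 2L], se_b = sm$coefficients[2L, 2L],
    s2 = sm$sigma^2, N = length(rate), r2 = sm$r.squared,
    r2_gate = r2_gate, linear_ok = sm$r.squared >= r2_gate,
    rate_unit = rate_unit,
    vcov = suppressWarnings(stats::vcov(fit)),
    temp_c = temp_c, rate = rate
  )
  if (b > 0) {
    out$ltt_c <- ltt(a, b)
    k <- thermal_constant(b, rate_unit)
    out$k_dh <- unname(k["degree_hours"]); out$k_dd <- unname(k["degree_days"])
  } else {
    out$ltt_c <- NA_real_; out$k_dh <- NA_real_; out$k_dd <- NA_real_
  }
  class(out) <- "reaction_norm_fit"
  out$se_ltt_c <- if (b > 0) ltt_se(out, method = se_method) else NA_real_
  out
}

#' Approximate standard error of the lower temperature threshold
#'
#' Three estimators of the sampling error of LTT = -a/b from a linear
#' reaction-norm fit:
#' \describe{
#'   \item{campbell}{the classical approximation
#'     `SE = (Rbar/b) * sqrt(s2/(N*Rbar^2) + (se_b/b)^2)` with `Rbar` the
#'     mean rate; widely used in degree-day studies although its
#'     statistical properties are not well characterized.}
#'   \item{delta}{first-order delta method on -a/b using the full
#'     coefficient covariance, including Cov(a, b).}
#'   \item{bootstrap}{parametric bootstrap: residuals are redrawn from
#'     N(0, s2), the norm is refitted, and the SD of the resampled
#'     thresholds is reported.}
#' }
#' All three are invariant to the rate unit.
#'
#' @param fit A linear `reaction_norm_fit`.
#' @param method One of `"campbell"`, `"delta"`, `"bootstrap"`.
#' @param B Bootstrap replicates.
#' @param seed Optional seed for the bootstrap.
#' @return Standard error in degrees Celsius.
#' @export
ltt_se <- function(fit, method = c("campbell", "delta", "bootstrap"),
                   B = 1000L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "reaction_norm_fit"), fit$model == "linear")
  if (fit$N < 3L) stop("need at least 3 observations")
  if (fit$b <= 0) stop("slope b must be positive")
  if (method == "campbell") {
    rbar <- mean(fit$rate)
    return((rbar / fit$b) *
             sqrt(fit$s2 / (fit$N * rbar^2) + (fit$se_b / fit$b)^2))
  }
  if (method == "delta") {
    V <- fit$vcov
    g <- c(-1 / fit$b, fit$a / fit$b^2)  # d(-a/b)/d(a,b)
    return(sqrt(drop(t(g) %*% V %*% g)))
  }
  if (!is.null(seed)) set.seed(seed)
  mu <- fit$a + fit$b * fit$temp_c
  reps <- vapply(seq_len(B), function(i) {
    r <- mu + stats::rnorm(fit$N, 0, sqrt(fit$s2))
    cf <- stats::coef(stats::lm(r ~ fit$temp_c))
    if (cf[2L] <= 0) NA_real_ else -cf[1L] / cf[2L]
  }, numeric(1))
  stats::sd(reps, na.rm = TRUE)
}

#' Fit a provisional quadratic thermal reaction norm
#'
#' Least-squares fit of R = c2*T^2 + c1*T + c0, used for markedly nonlinear
#' responses (in the beetle data, the composite sclerotization period and
#' the teneral adult stage). The provisional lower threshold is the smaller
#' real root of the polynomial, i.e. the temperature-axis crossing below
#' the vertex; if the discriminant is negative no crossing is reported.
#'
#' @inheritParams fit_linear_norm
#' @return Object of class `reaction_norm_fit` with `model = "quadratic"`,
#'   coefficients `c2`, `c1`, `c0`, `r2`, `lower_root_c` (or `NA`), and
#'   `no_crossing` flag.
#' @export
fit_quadratic_norm <- function(temp_c, rate, rate_unit = c("per_hour", "per_day"),
                               stage = NULL) {
  rate_unit <- match.arg(rate_unit)
  if (length(unique(temp_c)) < 3L)
    stop("need at least 3 distinct temperatures for a quadratic norm")
  fit <- stats::lm(rate ~ temp_c + I(temp_c^2))
  cf <- stats::coef(fit)
  c0 <- unname(cf[1L]); c1 <- unname(cf[2L]); c2 <- unname(cf[3L])
  root <- quad_lower_root(c2, c1, c0)
  out <- list(
    stage = stage, model = "quadratic",
    c2 = c2, c1 = c1, c0 = c0,
    r2 = summary(fit)$r.squared, N = length(rate),
    rate_unit = rate_unit,
    lower_root_c = root, no_crossing = is.na(root),
    temp_c = temp_c, rate = rate
  )
  class(out) <- "reaction_norm_fit"
  out
}

#' Lower temperature-axis crossing of a quadratic rate polynomial
#'
#' Smaller real root of `c2*T^2 + c1*T + c0 = 0`, selected as the root below
#' the vertex. With `c2 = 0` the polynomial degenerates to a line and the
#' single root `-c0/c1` is returned. `NA` when there is no real root.
#'
#' @param c2,c1,c0 Polynomial coefficients (quadratic, linear, constant).
#' @return Crossing temperature in degrees Celsius, or `NA`.
#' @export
#' @examples
#' quad_lower_root(-0.0021, 0.1219, -1.443) # 16.6 degC (teneral stage)
quad_lower_root <- function(c2, c1, c0) {
  if (c2 == 0) {
    if (c1 == 0) stop("degenerate polynomial: c2 = c1 = 0")
    return(-c0 / c1)
  }
  disc <- c1^2 - 4 * c2 * c0
  if (disc < 0) return(NA_real_)
  roots <- (-c1 + c(-1, 1) * sqrt(disc)) / (2 * c2)
  min(roots)
}

#' Fit a thermal reaction norm, routing by linearity
#'
#' Fits the linear model first; if its R-squared falls below the gate the
#' quadratic model is returned instead (with the linear fit attached as
#' attribute `"linear_fit"` for inspection).
#'
#' @inheritParams fit_linear_norm
#' @return A `reaction_norm_fit`, linear or quadratic.
#' @export
fit_reaction_norm <- function(temp_c, rate, rate_unit = c("per_hour", "per_day"),
                              r2_gate = 0.97, stage = NULL,
                              se_method = "campbell") {
  rate_unit <- match.arg(rate_unit)
  lin <- fit_linear_norm(temp_c, rate, rate_unit, r2_gate, stage, se_method)
  if (lin$linear_ok) return(lin)
  quad <- fit_quadratic_norm(temp_c, rate, rate_unit, stage)
  attr(quad, "linear_fit") <- lin
  quad
}

#' @export
print.reaction_norm_fit <- function(x, ...) {
  hdr <- if (is.null(x$stage)) "Thermal reaction norm"
         else sprintf("Thermal reaction norm: %s", x$stage)
  cat(hdr, sprintf("(%s rates)\n", sub("_", " ", x$rate_unit)))
  if (x$model == "linear") {
    cat(sprintf("  R = %.5g + %.5g * T   (R2 = %.3f, N = %d%s)\n",
                x$a, x$b, x$r2, x$N,
                if (x$linear_ok) "" else sprintf(", below %.2f gate", x$r2_gate)))
    if (!is.na(x$ltt_c))
      cat(sprintf("  LTT = %.1f degC (SE %.1f), K = %.1f degree-days\n",
                  x$ltt_c, x$se_ltt_c, x$k_dd))
  } else {
    cat(sprintf("  R = %.5g*T^2 + %.5g*T + %.5g   (R2 = %.3f)\n",
                x$c2, x$c1, x$c0, x$r2))
    cat(if (x$no_crossing) "  no temperature-axis crossing\n"
        else sprintf("  provisional lower crossing at %.1f degC\n", x$lower_root_c))
  }
  invisible(x)
}

#' Fit reaction norms for every destructively sampled stage
#'
#' Convenience wrapper: differences a transition-time table into durations
#' (unless durations are supplied), converts to rates, and fits one norm per
#' stage against the actual chamber temperatures.
#'
#' @param stage_table Data frame with `stage`, `temp_c` and either
#'   `duration_h` or `transition_h`.
#' @param rate_unit Rate unit for the fits.
#' @param r2_gate Linearity gate.
#' @param se_method LTT standard-error method.
#' @return Named list of `reaction_norm_fit` objects, one per stage.
#' @export
fit_stage_norms <- function(stage_table, rate_unit = "per_hour",
                            r2_gate = 0.97, se_method = "campbell") {
  if (!"duration_h" %in% names(stage_table))
    stage_table <- durations_from_transitions(stage_table)
  stage_table <- rates_from_durations(stage_table, rate_unit)
  parts <- split(stage_table, stage_table$stage, drop = TRUE)
  fits <- lapply(names(parts), function(st) {
    d <- parts[[st]]
    fit_reaction_norm(d$temp_c, d$rate, rate_unit, r2_gate, stage = st,
                      se_method = se_method)
  })
  names(fits) <- names(parts)
  fits
}

#' Tabulate a list of reaction-norm fits
#'
#' @param fits List of `reaction_norm_fit` objects (e.g. from
#'   [fit_stage_norms()]).
#' @return Data frame with one row per fit: `stage`, `model`, `a`, `b`,
#'   `se_a`, `se_b`, `r2`, `ltt_c`, `se_ltt_c`, `k_dh`, `k_dd`, and the
#'   quadratic columns where applicable.
#' @export
norm_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    data.frame(
      stage = if (is.null(f$stage)) NA_character_ else f$stage,
      model = f$model,
      a = if (f$model == "linear") f$a else NA_real_,
      b = if (f$model == "linear") f$b else NA_real_,
      se_a = if (f$model == "linear") f$se_a else NA_real_,
      se_b = if (f$model == "linear") f$se_b else NA_real_,
      r2 = f$r2,
      ltt_c = if (f$model == "linear") f$ltt_c else f$lower_root_c,
      se_ltt_c = if (f$model == "linear") f$se_ltt_c else NA_real_,
      k_dh = if (f$model == "linear") f$k_dh else NA_real_,
      k_dd = if (f$model == "linear") f$k_dd else NA_real_,
      c2 = if (f$model == "quadratic") f$c2 else NA_real_,
      c1 = if (f$model == "quadratic") f$c1 else NA_real_,
      c0 = if (f$model == "quadratic") f$c0 else NA_real_,
      rate_unit = f$rate_unit,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
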