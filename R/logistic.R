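#' Pool replicate destructive samples taken at the same hour
#'
#' Replicate samples of the same transition and temperature regime whose
#' ages agree after rounding to the nearest hour are pooled by summing
#' counts; the age is replaced by the rounded hour. Samples rounding to
#' different hours are left separate.
#'
#' @param samples Data frame of destructive samples with columns `regime`,
#'   `temp_c`, `age_h`, `transition`, `n_total`, `n_past`.
#' @return Data frame with the same columns, one row per rounded hour.
#' @export
pool_replicates <- function(samples) {
  validate_transition_samples(samples)
  if (length(unique(samples$transition)) > 1L)
    stop("cannot pool samples from different transitions")
  if (length(unique(samples$regime)) > 1L)
    stop("cannot pool samples from different temperature regimes")
  hr <- round(samples$age_h)
  # only true replicates (same rounded hour) are merged; a sample alone in
  # its hour keeps its exact age
  parts <- split(seq_len(nrow(samples)), hr)
  rows <- lapply(parts, function(ix) {
    data.frame(
      regime = samples$regime[ix[1L]],
      temp_c = samples$temp_c[ix[1L]],
      age_h = if (length(ix) > 1L) round(samples$age_h[ix[1L]])
              else samples$age_h[ix],
      transition = samples$transition[ix[1L]],
      n_total = sum(samples$n_total[ix]),
      n_past = sum(samples$n_past[ix]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$age_h), , drop = FALSE]
}

validate_transition_samples <- function(samples) {
  need <- c("regime", "temp_c", "age_h", "transition", "n_total", "n_past")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("missing columns in transition samples: ", paste(miss, collapse = ", "))
  if (any(samples$n_past < 0 | samples$n_past > samples$n_total))
    stop("n_past must lie in [0, n_total]")
  if (any(samples$age_h < 0)) stop("sample ages must be non-negative")
  if (any(samples$n_total < 1)) stop("n_total must be >= 1")
  invisible(samples)
}

# Core IRLS for binomial logistic regression of counts past a transition on
# age, with optional Firth (Jeffreys-prior) bias reduction. Works on
# standardized age for numerical stability; coefficients are reported on the
# original hour scale. `y` successes out of `m` trials.
logistic_irls <- function(age, y, m, firth = FALSE, tol = 1e-8,
                          max_iter = 100L, separation_bound = 25) {
  mu_a <- mean(age)
  sd_a <- stats::sd(age)
  if (!is.finite(sd_a) || sd_a == 0) stop("need at least 2 distinct sample ages")
  z <- (age - mu_a) / sd_a
  X <- cbind(1, z)
  # numerically stable log(1 + exp(eta))
  log1pexp <- function(eta) ifelse(eta > 30, eta, log1p(exp(eta)))
  objective <- function(g) {
    eta <- drop(X %*% g)
    val <- sum(y * eta - m * log1pexp(eta))
    if (firth) {
      p <- stats::plogis(eta)
      info <- crossprod(X, X * (m * p * (1 - p)))
      ld <- determinant(info, logarithm = TRUE)
      if (ld$sign <= 0) return(-Inf)
      val <- val + 0.5 * as.numeric(ld$modulus)
    }
    val
  }
  g <- c(stats::qlogis(max(min(sum(y) / sum(m), 0.95), 0.05)), 1)
  cur <- objective(g)
  converged <- FALSE
  separation <- FALSE
  score_norm <- Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% g)
    p <- stats::plogis(eta)
    w <- m * p * (1 - p)
    XtWX <- crossprod(X, X * w)
    if (firth) {
      # hat diagonals of W^{1/2} X (X'WX)^{-1} X' W^{1/2}
      XtWXi <- tryCatch(solve(XtWX), error = function(e) NULL)
      if (is.null(XtWXi)) break
      h <- w * rowSums((X %*% XtWXi) * X)
      U <- drop(crossprod(X, y - m * p + h * (0.5 - p)))
    } else {
      U <- drop(crossprod(X, y - m * p))
    }
    score_norm <- sqrt(sum(U^2))
    if (score_norm < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(XtWX, U), error = function(e) NULL)
    if (is.null(step)) break
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    # accept only ascent steps: halve until the objective improves
    improved <- FALSE
    for (half in 1:30) {
      cand <- g + step
      val <- objective(cand)
      if (is.finite(val) && val >= cur - 1e-12) {
        g <- cand; cur <- val; improved <- TRUE; break
      }
      step <- step / 2
    }
    if (!improved) break
    if (!firth && max(abs(g)) > separation_bound) { separation <- TRUE; break }
  }
  if (!firth && !converged && max(abs(g)) > separation_bound) separation <- TRUE
  if (!converged && !separation) {
    # Newton can stall when the weights concentrate on one or two samples
    # (very steep transitions); polish with quasi-Newton on the same
    # objective, whose exact gradient is the (penalized) score
    score <- function(g) {
      eta <- drop(X %*% g)
      p <- stats::plogis(eta)
      w <- m * p * (1 - p)
      if (firth) {
        XtWXi <- tryCatch(solve(crossprod(X, X * w)), error = function(e) NULL)
        if (is.null(XtWXi)) return(c(0, 0))
        h <- w * rowSums((X %*% XtWXi) * X)
        drop(crossprod(X, y - m * p + h * (0.5 - p)))
      } else drop(crossprod(X, y - m * p))
    }
    best <- g
    for (round in 1:5) {
      opt <- tryCatch(
        stats::optim(best, fn = function(gg) -objective(gg),
                     method = "Nelder-Mead",
                     control = list(maxit = 5000L, reltol = 1e-15)),
        error = function(e) NULL)
      if (!is.null(opt) && is.finite(opt$value) && -opt$value >= cur) {
        best <- opt$par; cur <- -opt$value
      }
      opt <- tryCatch(
        stats::optim(best, fn = function(gg) -objective(gg),
                     gr = function(gg) -score(gg), method = "BFGS",
                     control = list(maxit = 500L, reltol = 1e-15)),
        error = function(e) NULL)
      if (!is.null(opt) && is.finite(opt$value) && -opt$value >= cur) {
        best <- opt$par; cur <- -opt$value
      }
      if (sqrt(sum(score(best)^2)) < max(tol, 1e-6 * sum(m))) break
    }
    g <- best
    score_norm <- sqrt(sum(score(g)^2))
    # accept on a score scaled by the information magnitude
    converged <- score_norm < max(tol, 1e-6 * sum(m))
  }
  eta <- drop(X %*% g)
  p <- stats::plogis(eta)
  w <- m * p * (1 - p)
  XtWX <- crossprod(X, X * w)
  cov_z <- tryCatch(solve(XtWX), error = function(e) matrix(NA_real_, 2, 2))
  # back-transform: beta = J %*% gamma with J = [[1, -mu/sd], [0, 1/sd]]
  J <- rbind(c(1, -mu_a / sd_a), c(0, 1 / sd_a))
  beta <- drop(J %*% g)
  cov_b <- J %*% cov_z %*% t(J)
  ll <- sum(stats::dbinom(y, m, stats::plogis(beta[1] + beta[2] * age), log = TRUE))
  list(beta = beta, se = sqrt(pmax(diag(cov_b), 0)), vcov = cov_b,
       converged = converged, separation = separation,
       score_norm = score_norm, iterations = it, loglik = ll)
}

new_transition_fit <- function(res, samples, method) {
  fit <- list(
    transition = as.character(samples$transition[1L]),
    regime = samples$regime[1L],
    temp_c = samples$temp_c[1L],
    method = method,
    beta0 = res$beta[1L], beta1 = res$beta[2L],
    se0 = res$se[1L], se1 = res$se[2L],
    vcov = res$vcov,
    t50 = if (res$beta[2L] > 0) -res$beta[1L] / res$beta[2L] else NA_real_,
    converged = res$converged,
    separation = res$separation,
    valid = res$beta[2L] > 0,
    loglik = res$loglik,
    n_samples = nrow(samples),
    n_individuals = sum(samples$n_total)
  )
  class(fit) <- "transition_fit"
  fit
}

check_fit_input <- function(samples) {
  validate_transition_samples(samples)
  if (length(unique(samples$age_h)) < 2L)
    stop("need at least 2 distinct sample ages")
  invisible(samples)
}

#' Maximum-likelihood logistic fit of a stage transition
#'
#' Fits the binomial logistic model `logit P(past transition) = b0 + b1*age`
#' to destructive-sample counts by iteratively reweighted least squares.
#' Each sample enters as a binomial observation with its own `n_total`.
#' Complete or quasi-complete separation (no overlap between all-zero and
#' all-one ages) drives the ML estimates to infinity; this is detected and
#' flagged, and [fit_logistic_firth()] should then be used.
#'
#' @param samples Data frame of samples for one transition at one
#'   temperature (columns `regime`, `temp_c`, `age_h`, `transition`,
#'   `n_total`, `n_past`).
#' @param tol Convergence tolerance on the score norm (standardized scale).
#' @param max_iter Maximum IRLS iterations.
#' @param separation_bound Declare separation when a standardized
#'   coefficient exceeds this bound while the score has not vanished.
#' @return An object of class `transition_fit` with elements `beta0`,
#'   `beta1`, `se0`, `se1`, `t50` (hours, `-beta0/beta1`), `method`,
#'   `converged`, `separation`, `valid` (`beta1 > 0`), `n_samples`,
#'   `n_individuals`.
#' @export
#' @examples
#' s <- data.frame(regime = 1, temp_c = 25, age_h = c(4, 5, 6),
#'                 transition = "hatching", n_total = 10, n_past = c(0, 5, 10))
#' fit_logistic_ml(s)$t50
fit_logistic_ml <- function(samples, tol = 1e-8, max_iter = 100L,
                            separation_bound = 25) {
  check_fit_input(samples)
  if (sum(samples$n_past) == 0L || all(samples$n_past == samples$n_total))
    stop("no transition observed: proportions are all zero or all one")
  res <- logistic_irls(samples$age_h, samples$n_past, samples$n_total,
                       firth = FALSE, tol = tol, max_iter = max_iter,
                       separation_bound = separation_bound)
  if (res$separation)
    warning("complete or quasi-complete separation detected; ",
            "maximum-likelihood estimates diverge - use fit_logistic_firth()")
  new_transition_fit(res, samples, "ml")
}

#' Bias-reduced (Firth) logistic fit of a stage transition
#'
#' Maximizes the Jeffreys-prior penalized binomial log-likelihood
#' `l(beta) + 0.5 * log det I(beta)` by IRLS with hat-value-adjusted
#' working responses. The penalty guarantees finite estimates even under
#' complete separation, which is the typical situation for the rapid,
#' synchronous pre-dorsal-closure transitions where samples jump from all-0
#' to all-1 within a few hours.
#'
#' @inheritParams fit_logistic_ml
#' @return A `transition_fit` object (see [fit_logistic_ml()]); the
#'   `separation` flag records whether an ML fit of the same data would
#'   have separated.
#' @export
fit_logistic_firth <- function(samples, tol = 1e-8, max_iter = 100L,
                               separation_bound = 25) {
  check_fit_input(samples)
  res <- logistic_irls(samples$age_h, samples$n_past, samples$n_total,
                       firth = TRUE, tol = tol, max_iter = max_iter)
  # record whether plain ML would separate on these data
  ml <- tryCatch(
    logistic_irls(samples$age_h, samples$n_past, samples$n_total,
                  firth = FALSE, tol = tol, max_iter = max_iter,
                  separation_bound = separation_bound),
    error = function(e) NULL
  )
  res$separation <- is.null(ml) || ml$separation
  new_transition_fit(res, samples, "firth")
}

#' Fit a stage transition, choosing the estimator automatically
#'
#' Uses plain maximum likelihood when the data support it and falls back to
#' the Firth bias-reduced fit under separation or an all-zero/all-one
#' response.
#'
#' @inheritParams fit_logistic_ml
#' @param method `"auto"` (ML with Firth fallback), `"ml"`, or `"firth"`.
#' @return A `transition_fit` object.
#' @export
fit_transition <- function(samples, method = c("auto", "ml", "firth"),
                           tol = 1e-8, max_iter = 100L,
                           separation_bound = 25) {
  method <- match.arg(method)
  if (method == "ml")
    return(fit_logistic_ml(samples, tol, max_iter, separation_bound))
  if (method == "firth")
    return(fit_logistic_firth(samples, tol, max_iter, separation_bound))
  fit <- tryCatch(
    suppressWarnings(fit_logistic_ml(samples, tol, max_iter, separation_bound)),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$separation || !fit$converged)
    fit <- fit_logistic_firth(samples, tol, max_iter, separation_bound)
  fit
}

#' Median transition time from a logistic fit
#'
#' The age at which the fitted proportion past the transition equals 0.5,
#' i.e. `-beta0/beta1`.
#'
#' @param fit A `transition_fit` object.
#' @return Median transition time in hours.
#' @export
median_transition_time <- function(fit) {
  stopifnot(inherits(fit, "transition_fit"))
  if (!is.finite(fit$beta1) || fit$beta1 <= 0)
    stop("non-monotone transition: logistic slope is not positive")
  -fit$beta0 / fit$beta1
}

#' @export
print.transition_fit <- function(x, ...) {
  cat(sprintf(
    "Logistic transition fit (%s): %s at %.1f degC\n",
    x$method, x$transition, x$temp_c))
  cat(sprintf("  beta0 = %.4g (SE %.3g), beta1 = %.4g (SE %.3g) per h\n",
              x$beta0, x$se0, x$beta1, x$se1))
  cat(sprintf("  t50 = %.2f h  [%d samples, %d individuals]\n",
              x$t50, x$n_samples, x$n_individuals))
  if (x$separation) cat("  note: data are (quasi-)completely separated\n")
  if (!x$converged) cat("  warning: fit did not converge\n")
  invisible(x)
}

#' Fit every transition at every temperature in a sample table
#'
#' Splits a destructive-sample table by transition and regime, pools
#' replicates taken at the same (rounded) hour, and fits each logistic
#' time-course.
#'
#' @param samples Full sample table (see [read_transition_counts()]).
#' @param method Estimator passed to [fit_transition()].
#' @param ... Further arguments to [fit_transition()].
#' @return Data frame with one row per transition x regime: `transition`,
#'   `regime`, `temp_c`, `method`, `beta0`, `beta1`, `se0`, `se1`, `t50_h`,
#'   `separation`, `converged`.
#' @export
fit_all_transitions <- function(samples, method = "auto", ...) {
  validate_transition_samples(samples)
  parts <- split(samples, list(samples$transition, samples$regime), drop = TRUE)
  rows <- lapply(parts, function(d) {
    fit <- fit_transition(pool_replicates(d), method = method, ...)
    data.frame(
      transition = fit$transition, regime = fit$regime, temp_c = fit$temp_c,
      method = fit$method, beta0 = fit$beta0, beta1 = fit$beta1,
      se0 = fit$se0, se1 = fit$se1, t50_h = fit$t50,
      separation = fit$separation, converged = fit$converged,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
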