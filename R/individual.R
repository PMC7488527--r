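#' Per-individual developmental rates
#'
#' Converts individually-resolved stage durations (days) to rates
#' R = 1/D (per day), one row per individual per stage. Records with a
#' non-empty `flag` (e.g. overlooked or discarded individuals) or with
#' missing/non-positive durations are excluded, and the number excluded is
#' reported via a message.
#'
#' @param records Data frame of individual records: `id`, `temp_c`, `sex`,
#'   one or more `<stage>_d` duration columns, optionally `mass_mg`, `flag`.
#' @return Long data frame: `id`, `regime` (if present), `temp_c`, `sex`,
#'   `stage`, `duration_d`, `rate` (per day).
#' @export
individual_rates <- function(records) {
  dcols <- grep("_d$", names(records), value = TRUE)
  if (!length(dcols)) stop("no '<stage>_d' duration columns found")
  if (!all(c("id", "temp_c", "sex") %in% names(records)))
    stop("records need id, temp_c and sex columns")
  keep <- rep(TRUE, nrow(records))
  if ("flag" %in% names(records))
    keep <- keep & (is.na(records$flag) | records$flag == "")
  n_flagged <- sum(!keep)
  rows <- lapply(dcols, function(cl) {
    st <- sub("_d$", "", cl)
    d <- records[[cl]]
    ok <- keep & !is.na(d) & d > 0
    out <- records[ok, intersect(c("id", "regime", "temp_c", "sex"),
                                 names(records)), drop = FALSE]
    out$stage <- st
    out$duration_d <- d[ok]
    out$rate <- 1 / d[ok]
    out
  })
  out <- do.call(rbind, rows)
  n_bad <- length(dcols) * sum(keep) - sum(!is.na(out$duration_d))
  n_excl <- nrow(records) * length(dcols) - nrow(out)
  if (n_excl > 0)
    message(n_excl, " stage records excluded (flagged: ", n_flagged,
            " individuals; remainder missing or non-positive durations)")
  rownames(out) <- NULL
  out
}

# design matrix: intercept, centered temperature, sex contrast (+1/2 female,
# -1/2 male), interaction
gls_design <- function(temp_c, sex) {
  tc <- temp_c - mean(temp_c)
  sx <- ifelse(sex == "female", 0.5, -0.5)
  X <- cbind(`(Intercept)` = 1, temp = tc, sex = sx, `temp:sex` = tc * sx)
  X
}

#' Heteroskedastic GLS fit with a variance per temperature-by-sex stratum
#'
#' Fits the linear model `response ~ temperature + sex + temperature:sex`
#' (temperature continuous and centred internally, sex as a +/-1/2
#' contrast) allowing a distinct residual variance in every
#' temperature-by-sex stratum, estimated by restricted maximum likelihood.
#' Estimation profiles the variances: given stratum variances, the
#' coefficients solve weighted least squares; given coefficients, each
#' stratum variance is updated from its residual sum of squares divided by
#' its REML-adjusted degrees of freedom (observations minus accumulated
#' leverage), iterating to convergence.
#'
#' Term significance is assessed with sequential (type I) F-tests in the
#' order temperature, sex, interaction: nested weighted residual sums of
#' squares are compared with the final variance weights held fixed, with
#' denominator degrees of freedom N minus the number of coefficients.
#'
#' @param data Data frame containing the response and the `temp_c` and
#'   `sex` columns.
#' @param response Name of the response column.
#' @param tol Relative convergence tolerance on the stratum variances.
#' @param max_iter Maximum profiling iterations.
#' @return Object of class `gls_varident_fit`: `coefficients`, `se`,
#'   `vcov`, `sigma2` (stratum variances), `multipliers` (variance ratios,
#'   reference stratum = 1), `anova` (term, df1, df2, F, p), `logLik_reml`,
#'   `N`, `converged`, `fitted`, `residuals`, `weights`.
#' @export
fit_gls_varident <- function(data, response, tol = 1e-8, max_iter = 200L) {
  stopifnot(all(c(response, "temp_c", "sex") %in% names(data)))
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  y <- data[[response]]
  if (!all(data$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'")
  stratum <- interaction(factor(data$temp_c), factor(data$sex), drop = TRUE)
  tab <- table(stratum)
  if (length(tab) < 2L) stop("need at least 2 temperature-by-sex strata")
  if (any(tab < 2L))
    stop("empty or singleton stratum: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  X <- gls_design(data$temp_c, data$sex)
  N <- length(y); p <- ncol(X)
  sidx <- split(seq_len(N), stratum)

  ols <- stats::lm.fit(X, y)
  res <- ols$residuals
  sig2 <- vapply(sidx, function(ix) mean(res[ix]^2), numeric(1))
  sig2 <- pmax(sig2, 1e-12)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- 1 / sig2[as.integer(stratum)]
    XtW <- t(X * w)
    XtWXi <- solve(XtW %*% X)
    beta <- drop(XtWXi %*% (XtW %*% y))
    r <- y - drop(X %*% beta)
    lev <- w * rowSums((X %*% XtWXi) * X)
    new_sig2 <- vapply(sidx, function(ix)
      sum(r[ix]^2) / (length(ix) - sum(lev[ix])), numeric(1))
    new_sig2 <- pmax(new_sig2, 1e-12)
    if (max(abs(new_sig2 - sig2) / sig2) < tol) {
      sig2 <- new_sig2; converged <- TRUE; break
    }
    sig2 <- new_sig2
  }
  if (!converged)
    warning("variance profiling did not converge in ", max_iter, " iterations")
  w <- 1 / sig2[as.integer(stratum)]
  XtW <- t(X * w)
  XtWXi <- solve(XtW %*% X)
  beta <- drop(XtWXi %*% (XtW %*% y))
  r <- y - drop(X %*% beta)

  # REML log-likelihood at the profiled solution
  ll <- -0.5 * (sum(log(sig2[as.integer(stratum)])) +
                  determinant(XtW %*% X, logarithm = TRUE)$modulus +
                  sum(w * r^2) + (N - p) * log(2 * pi))

  anova_tab <- sequential_f(X, y, w, term_order = c("temp", "sex", "temp:sex"))

  out <- list(
    response = response,
    coefficients = stats::setNames(beta, colnames(X)),
    se = sqrt(diag(XtWXi)),
    vcov = XtWXi,
    sigma2 = sig2,
    multipliers = sig2 / sig2[1L],
    stratum_levels = names(sidx),
    anova = anova_tab,
    logLik_reml = as.numeric(ll),
    N = N, p = p, converged = converged, iterations = it,
    fitted = drop(X %*% beta), residuals = r, weights = w,
    stratum = stratum
  )
  class(out) <- "gls_varident_fit"
  out
}

# sequential (type I) F-tests by nested weighted RSS with fixed weights;
# X has columns (Intercept), temp, sex, temp:sex
sequential_f <- function(X, y, w, term_order) {
  p <- ncol(X); N <- length(y)
  wrss <- function(cols) {
    f <- stats::lm.wfit(X[, cols, drop = FALSE], y, w)
    sum(w * f$residuals^2)
  }
  rss_full <- wrss(seq_len(p))
  df_res <- N - p
  s2 <- rss_full / df_res
  cum <- 1L
  rows <- lapply(term_order, function(tm) {
    j <- match(tm, colnames(X))
    prev <- wrss(seq_len(j - 1L))
    cur <- wrss(seq_len(j))
    Fv <- ((prev - cur) / 1) / s2
    data.frame(term = tm, df1 = 1L, df2 = df_res, F = Fv,
               p = stats::pf(Fv, 1, df_res, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.gls_varident_fit <- function(x, ...) {
  cat(sprintf("Heteroskedastic GLS (REML), response: %s, N = %d\n",
              x$response, x$N))
  cf <- data.frame(estimate = x$coefficients, se = x$se)
  print(round(cf, 5))
  cat("Stratum variance multipliers (reference = 1):\n")
  print(round(stats::setNames(x$multipliers, x$stratum_levels), 3))
  cat("Sequential (type I) F-tests:\n")
  print(transform(x$anova, F = round(F, 2), p = signif(p, 3)))
  invisible(x)
}

#' Median and quartile stage durations per stage and temperature
#'
#' Summarizes individually-resolved stage durations as median with lower
#' and upper quartiles, per stage and rearing temperature. The quantile
#' convention defaults to linear interpolation (R type 7) and is
#' configurable.
#'
#' @param records Individual records (wide, with `<stage>_d` columns) or a
#'   long rate table from [individual_rates()].
#' @param qtype Quantile type passed to [stats::quantile()].
#' @return Data frame: `stage`, `temp_c`, `n`, `median_d`, `q1_d`, `q3_d`.
#' @export
summarize_stages <- function(records, qtype = 7L) {
  long <- if ("duration_d" %in% names(records)) records
          else suppressMessages(individual_rates(records))
  parts <- split(long, list(long$stage, long$temp_c), drop = TRUE)
  rows <- lapply(parts, function(d) {
    q <- stats::quantile(d$duration_d, c(0.25, 0.5, 0.75), type = qtype,
                         names = FALSE)
    data.frame(stage = d$stage[1L], temp_c = d$temp_c[1L], n = nrow(d),
               median_d = q[2L], q1_d = q[1L], q3_d = q[3L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$stage, out$temp_c), ]
  rownames(out) <- NULL
  out
}

#' Adult body-mass analysis
#'
#' Applies the heteroskedastic GLS machinery to adult mass (mg) and returns
#' the fit together with a mean and SD summary per temperature and sex.
#'
#' @param records Individual records with a `mass_mg` column.
#' @param ... Passed to [fit_gls_varident()].
#' @return List with elements `fit` (a `gls_varident_fit`) and `summary`
#'   (`temp_c`, `sex`, `n`, `mean_mg`, `sd_mg`).
#' @export
mass_analysis <- function(records, ...) {
  stopifnot("mass_mg" %in% names(records))
  keep <- !is.na(records$mass_mg) & records$mass_mg > 0
  if ("flag" %in% names(records))
    keep <- keep & (is.na(records$flag) | records$flag == "")
  rec <- records[keep, , drop = FALSE]
  fit <- fit_gls_varident(rec, "mass_mg", ...)
  parts <- split(rec, list(rec$temp_c, rec$sex), drop = TRUE)
  summ <- do.call(rbind, lapply(parts, function(d) data.frame(
    temp_c = d$temp_c[1L], sex = d$sex[1L], n = nrow(d),
    mean_mg = mean(d$mass_mg), sd_mg = stats::sd(d$mass_mg),
    stringsAsFactors = FALSE
  )))
  summ <- summ[order(summ$sex, summ$temp_c), ]
  rownames(summ) <- NULL
  list(fit = fit, summary = summ)
}
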