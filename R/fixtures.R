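# Machine-readable copies of the published summary tables for the cowpea
# seed beetle study, used as inputs for desk-scale recomputation and as
# ground truth for the simulator defaults. Values are printed to 2 d.p.
# (times, durations), 1 d.p. (quartile summaries) or 4-5 significant
# figures (regression coefficients).

# Actual chamber temperatures per block; set points were 20/23/26/29/32 C.
.cmac_temps_block1 <- c(19.8, 22.7, 25.6, 28.6, 31.7)
.cmac_temps_block2 <- c(19.7, 22.6, 25.6, 28.8, 31.6)
.cmac_temp_set <- c(20, 23, 26, 29, 32)

#' Median stage-transition times of *C. maculatus* embryos and early larvae
#'
#' Logistic-regression estimates of the median time (hours from oviposition)
#' at which half of a cohort has completed each destructively sampled stage,
#' at five constant incubation temperatures. Pre-dorsal-closure stages were
#' run in one block of chambers (actual temperatures 19.8-31.7 degC),
#' post-dorsal-closure stages in a second block (19.7-31.6 degC); the actual
#' temperature is attached to each row along with the nominal set point.
#'
#' @return Data frame: `stage` (ordered factor), `block`, `temp_set` (degC),
#'   `temp_c` (actual degC), `transition_h`.
#' @seealso [cmac_stage_durations()], [cmac_rate_coefficients()]
#' @export
cmac_transition_times <- function() {
  ont <- cmac_ontology()
  dest <- ont[ont$mode == "destructive", ]
  tt <- rbind(
    early_cleavages      = c(14.10, 10.25, 6.28, 5.17, 4.11),
    late_cleavages       = c(34.37, 24.21, 18.52, 14.15, 12.42),
    germ_band_extension  = c(54.63, 39.16, 28.03, 21.09, 17.52),
    germ_band_retraction = c(107.90, 75.33, 57.06, 41.63, 34.51),
    dorsal_closure       = c(167.85, 115.20, 85.78, 64.89, 54.66),
    final_morphogenesis  = c(211.32, 134.54, 105.34, 80.57, 68.81),
    sclerotization       = c(235.74, 157.76, 118.68, 89.66, 78.59),
    hatching             = c(269.90, 177.72, 130.58, 99.12, 87.09),
    boring               = c(351.53, 229.27, 172.34, 129.15, 112.20)
  )
  block <- dest$block[match(rownames(tt), as.character(dest$stage))]
  out <- data.frame(
    stage = factor(rep(rownames(tt), each = 5L),
                   levels = levels(ont$stage), ordered = TRUE),
    block = rep(block, each = 5L),
    temp_set = rep(.cmac_temp_set, times = nrow(tt)),
    temp_c = as.vector(t(ifelse(
      matrix(block, nrow(tt), 5L) == 1L,
      matrix(.cmac_temps_block1, nrow(tt), 5L, byrow = TRUE),
      matrix(.cmac_temps_block2, nrow(tt), 5L, byrow = TRUE)
    ))),
    transition_h = as.vector(t(tt)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Published stage durations of destructively sampled stages
#'
#' Stage durations (hours) at the five incubation temperatures, obtained as
#' differences between consecutive median transition times (the first stage
#' duration equals its transition time).
#'
#' @return Data frame: `stage`, `block`, `temp_set`, `temp_c`, `duration_h`.
#' @export
cmac_stage_durations <- function() {
  ont <- cmac_ontology()
  dd <- rbind(
    early_cleavages      = c(14.10, 10.25, 6.28, 5.17, 4.11),
    late_cleavages       = c(20.27, 13.96, 12.24, 8.98, 8.32),
    germ_band_extension  = c(20.26, 14.95, 9.51, 6.94, 5.10),
    germ_band_retraction = c(53.27, 36.18, 29.03, 20.54, 16.99),
    dorsal_closure       = c(59.95, 39.87, 28.73, 23.26, 20.15),
    final_morphogenesis  = c(43.47, 19.34, 19.56, 15.69, 14.15),
    sclerotization       = c(24.42, 23.22, 13.33, 9.08, 9.78),
    hatching             = c(34.15, 19.96, 11.91, 9.47, 8.50),
    boring               = c(81.63, 51.55, 41.76, 30.03, 25.12)
  )
  tt <- cmac_transition_times()
  out <- tt
  out$transition_h <- NULL
  out$duration_h <- as.vector(t(dd))[match(
    paste(tt$stage, tt$temp_set),
    paste(rep(rownames(dd), each = 5L), rep(.cmac_temp_set, times = nrow(dd)))
  )]
  out
}

#' Published median durations of individually reared stages
#'
#' Median stage duration (days) with lower and upper quartiles for the
#' larval (feeding and pupation), pupal, and teneral adult stages at five
#' rearing temperatures (actual chamber temperatures 20.0-31.8 degC).
#'
#' @return Data frame: `stage`, `temp_c`, `median_d`, `q1_d`, `q3_d`.
#' @export
cmac_individual_summaries <- function() {
  temps <- c(20.0, 23.0, 25.9, 28.9, 31.8)
  med <- rbind(
    larva   = c(38.9, 22.6, 17.1, 14.0, 12.9),
    pupa    = c(10.3, 6.9, 5.9, 5.0, 4.1),
    teneral = c(6.8, 4.5, 3.0, 3.1, 4.0)
  )
  q1 <- rbind(
    larva   = c(35.0, 21.0, 15.9, 11.8, 11.0),
    pupa    = c(9.8, 6.0, 5.0, 4.2, 3.9),
    teneral = c(6.0, 4.0, 3.0, 2.0, 2.9)
  )
  q3 <- rbind(
    larva   = c(49.8, 24.2, 18.9, 15.0, 13.8),
    pupa    = c(10.8, 7.0, 6.2, 5.3, 5.0),
    teneral = c(7.1, 5.0, 4.0, 5.0, 5.0)
  )
  ont <- cmac_ontology()
  data.frame(
    stage = factor(rep(rownames(med), each = 5L),
                   levels = levels(ont$stage), ordered = TRUE),
    temp_c = rep(temps, times = 3L),
    median_d = as.vector(t(med)),
    q1_d = as.vector(t(q1)),
    q3_d = as.vector(t(q3)),
    stringsAsFactors = FALSE
  )
}

#' Published linear rate-temperature regression coefficients
#'
#' Intercepts `a`, slopes `b` and lower temperature thresholds (LTT) of the
#' linear developmental-rate regressions R = a + b*T per stage, with
#' standard errors. Note the mixed rate units: the embryonic, total-embryonic
#' and boring rows are per-hour rates (their reciprocal slopes are
#' degree-hours), while the larval and pupal rows, fitted by GLS to
#' individual rates, are per-day. The `rate_unit` column makes this
#' explicit.
#'
#' @return Data frame: `stage_label`, `stage` (key, `NA` for the
#'   total-embryonic composite), `a`, `se_a`, `b`, `se_b`, `ltt_c`,
#'   `se_ltt_c`, `rate_unit`.
#' @export
cmac_rate_coefficients <- function() {
  out <- data.frame(
    stage_label = c(
      "Early cleavages", "Late cleavages and germ band formation",
      "Germ band extension", "Germ band retraction", "Dorsal closure",
      "Hatching", "Total embryonic development", "Boring into the seed",
      "Larval feeding and pupation", "Pupal stage"
    ),
    stage = c("early_cleavages", "late_cleavages", "germ_band_extension",
              "germ_band_retraction", "dorsal_closure", "hatching",
              NA, "boring", "larva", "pupa"),
    a    = c(-0.2269, -0.0692, -0.2075, -0.0495, -0.0382, -0.1220,
             -0.0095, -0.0335, -0.0793, -0.1607),
    se_a = c(0.02268, 0.01565, 0.02759, 0.00561, 0.00336, 0.01736,
             0.00080, 0.00288, 0.00199, 0.00478),
    b    = c(0.01479, 0.00608, 0.01245, 0.00340, 0.00281, 0.00776,
             0.00067, 0.00231, 0.00527, 0.01295),
    se_b = c(0.00087, 0.00060, 0.00106, 0.00022, 0.00013, 0.00067,
             0.00003, 0.00011, 0.00009, 0.00023),
    ltt_c    = c(15.3, 11.4, 16.7, 14.6, 13.6, 15.7, 14.2, 14.5, 15.1, 12.4),
    se_ltt_c = c(2.2, 2.6, 2.3, 2.2, 2.2, 2.3, 2.2, 2.2, 0.4, 0.6),
    rate_unit = c(rep("per_hour", 8L), "per_day", "per_day"),
    stringsAsFactors = FALSE
  )
  out
}

#' Published quadratic rate-temperature coefficients
#'
#' Second-order polynomials R = c2*T^2 + c1*T + c0 provisionally fitted to
#' the two markedly nonlinear responses: the composite sclerotization period
#' (dorsal closure to end of sclerotization; per-hour rates) and the teneral
#' adult stage (per-day rates).
#'
#' @return Data frame: `stage`, `c2`, `c1`, `c0`, `rate_unit`.
#' @export
cmac_quadratic_coefficients <- function() {
  data.frame(
    stage = c("sclerotization_composite", "teneral"),
    c2 = c(-0.00009, -0.0021),
    c1 = c(0.0073, 0.1219),
    c0 = c(-0.0918, -1.443),
    rate_unit = c("per_hour", "per_day"),
    stringsAsFactors = FALSE
  )
}

#' All published fixture tables in one list
#'
#' Convenience wrapper returning every packaged fixture table.
#'
#' @return Named list with elements `ontology`, `transition_times`,
#'   `stage_durations`, `individual_summaries`, `rate_coefficients`,
#'   `quadratic_coefficients`.
#' @export
make_fixture_tables <- function() {
  list(
    ontology = cmac_ontology(),
    transition_times = cmac_transition_times(),
    stage_durations = cmac_stage_durations(),
    individual_summaries = cmac_individual_summaries(),
    rate_coefficients = cmac_rate_coefficients(),
    quadratic_coefficients = cmac_quadratic_coefficients()
  )
}
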