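#' Stage proportions of a reference developmental span
#'
#' Expresses each stage's duration as a fraction of a reference span (by
#' default the span covered by the listed reference stages, e.g. oviposition
#' to dorsal closure), per temperature regime. Within a fully partitioned
#' span the proportions sum to 1 at every temperature, so they are
#' diagnostics of proportional scaling (equiproportional development).
#'
#' @param durations Stage-duration table with `stage`, `duration_h`, and a
#'   regime key (`temp_set` if present, else `temp_c`).
#' @param reference_stages Stage keys whose summed duration defines the
#'   span (denominator).
#' @param stages Stages to report proportions for; defaults to the
#'   reference stages.
#' @return Data frame: `stage`, regime key, `proportion`.
#' @export
#' @examples
#' pre_dc <- c("early_cleavages", "late_cleavages", "germ_band_extension",
#'             "germ_band_retraction", "dorsal_closure")
#' stage_proportions(cmac_stage_durations(), pre_dc)
stage_proportions <- function(durations, reference_stages,
                              stages = reference_stages) {
  key <- if ("temp_set" %in% names(durations)) "temp_set" else "temp_c"
  rows <- lapply(unique(durations[[key]]), function(tp) {
    d <- durations[durations[[key]] == tp, ]
    miss <- setdiff(reference_stages, as.character(d$stage))
    if (length(miss))
      stop("reference span not covered at ", key, " = ", tp, ": missing ",
           paste(miss, collapse = ", "))
    span <- sum(d$duration_h[as.character(d$stage) %in% reference_stages])
    sel <- d[as.character(d$stage) %in% stages, ]
    data.frame(stage = as.character(sel$stage), regime = tp,
               proportion = sel$duration_h / span, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2L] <- key
  rownames(out) <- NULL
  out
}

#' Ratio of two developmental spans per temperature
#'
#' Computes `(t[end_num] - t[start_num]) / (t[end_den] - t[start_den])` from
#' a transition-time table, per regime. A span start of `NULL` means
#' oviposition (time zero). Used, e.g., to compare post- and
#' pre-dorsal-closure development.
#'
#' @param transitions Transition-time table (`stage`, `transition_h`,
#'   regime key `temp_set` or `temp_c`).
#' @param numerator,denominator Each a list/character vector
#'   `c(start, end)` of stage keys; use `NA` or omit the start for
#'   oviposition.
#' @return Data frame: regime key, `numerator_h`, `denominator_h`, `ratio`.
#' @export
#' @examples
#' span_ratio(cmac_transition_times(),
#'            numerator = c("dorsal_closure", "boring"),
#'            denominator = c(NA, "dorsal_closure"))
span_ratio <- function(transitions, numerator, denominator) {
  key <- if ("temp_set" %in% names(transitions)) "temp_set" else "temp_c"
  span_ends <- function(spec, d) {
    start <- if (length(spec) == 2L) spec[1L] else NA
    end <- spec[length(spec)]
    t_end <- d$transition_h[as.character(d$stage) == end]
    t_start <- if (is.na(start) || is.null(start)) 0
               else d$transition_h[as.character(d$stage) == start]
    if (!length(t_end) || !length(t_start))
      stop("span stages not found in transition table")
    t_end - t_start
  }
  rows <- lapply(unique(transitions[[key]]), function(tp) {
    d <- transitions[transitions[[key]] == tp, ]
    num <- span_ends(numerator, d)
    den <- span_ends(denominator, d)
    if (den == 0) stop("zero denominator span at ", key, " = ", tp)
    data.frame(regime = tp, numerator_h = num, denominator_h = den,
               ratio = num / den)
  })
  out <- do.call(rbind, rows)
  names(out)[1L] <- key
  rownames(out) <- NULL
  out
}

#' Spread of lower temperature thresholds across stages
#'
#' Summarizes per-stage LTTs: minimum, maximum and range, with stage
#' labels. A range below the isomorphy tolerance (default 1 degC) is
#' flagged as compatible with developmental rate isomorphy, under which
#' every stage shares a single threshold; this is a descriptive diagnostic,
#' not a formal test.
#'
#' @param fits List of linear `reaction_norm_fit` objects, or a data frame
#'   with `stage` and `ltt_c` columns.
#' @param tol Isomorphy tolerance in degrees Celsius.
#' @return List: `table` (stage, ltt_c), `min`, `max`, `range`,
#'   `min_stage`, `max_stage`, `isomorphy_compatible`.
#' @export
ltt_spread <- function(fits, tol = 1) {
  tab <- if (is.data.frame(fits)) fits[c("stage", "ltt_c")]
  else {
    fits <- Filter(function(f) f$model == "linear" && !is.na(f$ltt_c), fits)
    data.frame(
      stage = vapply(fits, function(f)
        if (is.null(f$stage)) NA_character_ else f$stage, character(1)),
      ltt_c = vapply(fits, function(f) f$ltt_c, numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  tab <- tab[!is.na(tab$ltt_c), , drop = FALSE]
  if (nrow(tab) < 2L) stop("need at least 2 linear fits")
  list(
    table = tab,
    min = min(tab$ltt_c), max = max(tab$ltt_c),
    range = diff(range(tab$ltt_c)),
    min_stage = tab$stage[which.min(tab$ltt_c)],
    max_stage = tab$stage[which.max(tab$ltt_c)],
    isomorphy_compatible = diff(range(tab$ltt_c)) < tol
  )
}

#' Pupa-to-feeding duration ratio per temperature
#'
#' The published pupa:feeding sequence is not reproducible from stage
#' medians alone, so the ratio is computed two ways and both are labelled:
#' the ratio of stage medians, and the median of per-individual ratios
#' (which requires individual records).
#'
#' @param records Individual records (wide format) with `pupa_d` and
#'   `larva_d` columns, or `NULL`.
#' @param summaries A stage summary table (from [summarize_stages()] or
#'   [cmac_individual_summaries()]) used for the ratio-of-medians; required
#'   if `records` is `NULL`.
#' @return Data frame: `temp_c`, `ratio_of_medians`,
#'   `median_of_ratios` (`NA` without individual records).
#' @export
pupa_feeding_ratio <- function(records = NULL, summaries = NULL) {
  if (is.null(records) && is.null(summaries))
    stop("supply individual records and/or a summary table")
  if (is.null(summaries)) summaries <- summarize_stages(records)
  med <- function(st) {
    d <- summaries[summaries$stage == st, ]
    stats::setNames(d$median_d, d$temp_c)
  }
  mp <- med("pupa"); ml <- med("larva")
  temps <- sort(as.numeric(intersect(names(mp), names(ml))))
  out <- data.frame(
    temp_c = temps,
    ratio_of_medians = as.numeric(mp[as.character(temps)] /
                                    ml[as.character(temps)]),
    median_of_ratios = NA_real_
  )
  if (!is.null(records)) {
    ok <- !is.na(records$pupa_d) & !is.na(records$larva_d) &
      records$larva_d > 0
    rec <- records[ok, ]
    mr <- tapply(rec$pupa_d / rec$larva_d, rec$temp_c, stats::median)
    out$median_of_ratios <- as.numeric(mr[as.character(out$temp_c)])
  }
  out
}
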