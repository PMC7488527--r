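# CSV interchange. Destructive-sample tables use the header
# regime,temp_c,age_h,transition,n_total,n_past; individual tables use
# id,regime,temp_c,sex,<stage>_d...,mass_mg,flag.

#' Read a destructive-sample count table
#'
#' Reads and validates a CSV of transition counts. Malformed rows are
#' reported with their line numbers.
#'
#' @param path CSV file with columns `regime`, `temp_c`, `age_h`,
#'   `transition`, `n_total`, `n_past`.
#' @return Validated data frame.
#' @export
read_transition_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("regime", "temp_c", "age_h", "transition", "n_total", "n_past")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  bad <- which(is.na(d$n_total) | is.na(d$n_past) | d$n_total < 1 |
                 d$n_past < 0 | d$n_past > d$n_total | d$age_h < 0)
  if (length(bad))
    stop("invalid rows (data lines ", paste(bad, collapse = ", "),
         "): counts must satisfy 0 <= n_past <= n_total, n_total >= 1, age >= 0")
  if (nrow(d) == 0L) warning("empty sample table: ", path)
  d
}

#' Write a destructive-sample count table
#'
#' @param samples Sample data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transition_counts <- function(samples, path) {
  validate_transition_samples(samples)
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an individual-record table
#'
#' @param path CSV with columns `id`, `temp_c`, `sex`, one or more
#'   `<stage>_d` duration columns, optionally `regime`, `mass_mg`, `flag`.
#' @return Validated data frame; an empty file yields an empty data frame
#'   with a warning.
#' @export
read_individual_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "temp_c", "sex")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(d) == 0L) {
    warning("empty individual-record table: ", path)
    return(d)
  }
  bad_sex <- which(!d$sex %in% c("male", "female"))
  if (length(bad_sex))
    stop("invalid sex (must be 'male' or 'female') on data lines ",
         paste(bad_sex, collapse = ", "))
  dcols <- grep("_d$", names(d), value = TRUE)
  for (cl in dcols) {
    bad <- which(!is.na(d[[cl]]) & d[[cl]] <= 0)
    if (length(bad))
      stop("non-positive duration in ", cl, " on data lines ",
           paste(bad, collapse = ", "))
  }
  if ("mass_mg" %in% names(d)) {
    bad <- which(!is.na(d$mass_mg) & d$mass_mg <= 0)
    if (length(bad))
      stop("non-positive mass on data lines ", paste(bad, collapse = ", "))
  }
  d
}

#' Write an individual-record table
#'
#' @param records Individual-record data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_individual_records <- function(records, path) {
  stopifnot(all(c("id", "temp_c", "sex") %in% names(records)))
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flat key-value simulator configuration
#'
#' Minimal YAML-like `key: value` format for scalar simulator options
#' (`cv`, `shared_factor_sd`, `collection_window_min`, `sex_ratio`,
#' `n_individuals`, `seed`); unknown keys are rejected. The stage laws and
#' schedule of [default_sim_config()] are used.
#'
#' @param path Config file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, character(1), 2L)))
  known <- c("cv", "shared_factor_sd", "collection_window_min", "sex_ratio",
             "n_individuals", "seed")
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  opts <- stats::setNames(as.list(vals), keys)
  cfg <- default_sim_config(
    cv = if (!is.null(opts$cv)) opts$cv else 0.08,
    shared_factor_sd = if (!is.null(opts$shared_factor_sd))
      opts$shared_factor_sd else 0,
    n_individuals = if (!is.null(opts$n_individuals))
      opts$n_individuals else 115L,
    seed = if (!is.null(opts$seed)) opts$seed else 1L
  )
  if (!is.null(opts$collection_window_min))
    cfg$collection_window_min <- opts$collection_window_min
  if (!is.null(opts$sex_ratio)) cfg$sex_ratio <- opts$sex_ratio
  cfg
}
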