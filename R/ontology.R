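#' Developmental stage ontology of *Callosobruchus maculatus*
#'
#' The full development from oviposition to adult emergence is divided into
#' twelve ordered stages. The first nine (oviposition to complete boring into
#' the seed) are observed by destructive sampling of egg cohorts, so their
#' timing is inferred from stage-frequency counts; the last three (larva,
#' pupa, teneral adult) are followed individually through an incision in the
#' seed coat.
#'
#' @return A data frame of class `stage_ontology` with columns `stage`
#'   (ordered factor), `label` (long descriptive name), `mode`
#'   (`"destructive"` or `"individual"`) and `block` (temperature-regime
#'   block: pre-dorsal-closure stages were incubated in the first block of
#'   chambers, post-dorsal-closure stages in the second; `NA` for
#'   individually reared stages).
#' @export
#' @examples
#' cmac_ontology()
cmac_ontology <- function() {
  stages <- c(
    "early_cleavages", "late_cleavages", "germ_band_extension",
    "germ_band_retraction", "dorsal_closure", "final_morphogenesis",
    "sclerotization", "hatching", "boring", "larva", "pupa", "teneral"
  )
  labels <- c(
    "Early cleavages up to 256 nuclei",
    "Late cleavages and germ band formation",
    "Germ band extension",
    "Germ band retraction",
    "Dorsal closure",
    "Final morphogenesis",
    "Sclerotization",
    "Hatching",
    "Boring into the seed",
    "Larva (feeding and pupation)",
    "Pupa",
    "Teneral adult"
  )
  out <- data.frame(
    stage = factor(stages, levels = stages, ordered = TRUE),
    label = labels,
    mode = c(rep("destructive", 9L), rep("individual", 3L)),
    block = c(rep(1L, 5L), rep(2L, 4L), rep(NA_integer_, 3L)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("stage_ontology", class(out))
  validate_ontology(out)
}

#' Construct a custom stage ontology
#'
#' @param stages Character vector of stage keys, in developmental order.
#' @param mode Character vector, one of `"destructive"`/`"individual"` per
#'   stage. All destructive stages must precede all individual stages, as
#'   sampling designs that stage a cohort destructively cannot follow
#'   individuals that are later observed semi-destructively.
#' @param labels Optional long names (defaults to the keys).
#' @param block Optional integer temperature-block id per stage.
#' @return A `stage_ontology` data frame.
#' @export
stage_ontology <- function(stages, mode, labels = stages,
                           block = rep(NA_integer_, length(stages))) {
  stopifnot(length(stages) >= 1L, length(mode) == length(stages),
            length(labels) == length(stages))
  out <- data.frame(
    stage = factor(stages, levels = stages, ordered = TRUE),
    label = labels,
    mode = mode,
    block = as.integer(block),
    stringsAsFactors = FALSE
  )
  class(out) <- c("stage_ontology", class(out))
  validate_ontology(out)
}

validate_ontology <- function(x) {
  if (anyDuplicated(x$stage)) stop("duplicated stage names in ontology")
  if (!all(x$mode %in% c("destructive", "individual")))
    stop("mode must be 'destructive' or 'individual'")
  ind <- which(x$mode == "individual")
  if (length(ind) && any(x$mode[seq_len(min(ind) - 1L)] != "destructive"))
    stop("destructive stages must precede individually observed stages")
  if (length(ind) && max(which(x$mode == "destructive"), 0L) > min(ind))
    stop("destructive stages must precede individually observed stages")
  x
}

destructive_stages <- function(ontology = cmac_ontology()) {
  as.character(ontology$stage[ontology$mode == "destructive"])
}

individual_stages <- function(ontology = cmac_ontology()) {
  as.character(ontology$stage[ontology$mode == "individual"])
}
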