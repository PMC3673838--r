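#' Phase schema for a research program
#'
#' A phase schema is the ordered ladder of research phases a program moves
#' through. Rank 0 is the earliest phase; later ranks are "higher" phases.
#' The default ladder is the standard drug-development sequence from
#' pre-clinical bench work to the pivotal clinical trial.
#'
#' @param phases Character vector of phase names, earliest first. Names must
#'   be unique, non-empty tokens.
#' @param labels Optional character vector of display labels, same length as
#'   `phases`. Defaults to the phase names themselves.
#'
#' @return A tibble with columns `phase`, `label` and integer `rank`
#'   (0-based), classed `aero_phases`.
#' @examples
#' aero_phases()
#' aero_phases(c("bench", "animal", "human"))
#' @export
aero_phases <- function(phases = c("in_vitro", "in_vivo", "phase1", "phase2", "phase3"),
                        labels = NULL) {
  phases <- as.character(phases)
  if (length(phases) < 1L) {
    rlang::abort("a phase schema needs at least one phase", class = "aero_error_schema")
  }
  if (anyNA(phases) || any(!nzchar(phases))) {
    rlang::abort("phase names must be non-empty", class = "aero_error_schema")
  }
  if (anyDuplicated(phases)) {
    rlang::abort("phase names must be unique", class = "aero_error_schema")
  }
  if (is.null(labels)) {
    labels <- c(
      in_vitro = "in vitro", in_vivo = "in vivo",
      phase1 = "phase 1", phase2 = "phase 2", phase3 = "phase 3"
    )[phases]
    labels <- ifelse(is.na(labels), phases, labels)
  }
  stopifnot(length(labels) == length(phases))
  out <- tibble::tibble(
    phase = phases,
    label = as.character(labels),
    rank = seq_along(phases) - 1L
  )
  class(out) <- c("aero_phases", class(out))
  out
}

phase_rank <- function(schema, phase) {
  schema$rank[match(phase, schema$phase)]
}

#' The three study outcomes and their canonical colors
#'
#' Completed studies carry exactly one of three outcome codes: `positive`
#' (supports further research, drawn green), `negative` (argues against
#' further research, red) or `inconclusive` (ambivalent, yellow).
#'
#' @return Named character vector mapping outcome to fill color (hex).
#' @examples
#' aero_outcomes()
#' @export
aero_outcomes <- function() {
  c(positive = "#2ca25f", negative = "#de2d26", inconclusive = "#fec44f")
}

outcome_levels <- function() names(aero_outcomes())
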