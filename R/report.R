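#' Full robustness report for a research program
#'
#' Aggregates every analytic over the graph: per-phase outcome tallies,
#' within-phase consistency, de-facto thresholds for every adjacent phase
#' pair, orphaned studies, maximal same-outcome sub-trajectories, and the
#' overall outcome trend. The result is deterministic and serializable
#' ([report_to_json()]).
#'
#' @param g An `aero_graph`.
#' @return An `aero_report`: a list with elements `phase_summary`,
#'   `consistency`, `thresholds`, `orphans`, `subtrajectories`, `trend`,
#'   `n_studies`, `n_completed`, `n_contemplated`, `year_span`.
#' @examples
#' aero_analyze(fixture_moxifloxacin())
#' @export
aero_analyze <- function(g) {
  s <- g$studies
  sch <- g$phases
  thresholds <- purrr::map(
    sch$phase[sch$rank < max(sch$rank)],
    ~ de_facto_threshold(g, .x)
  ) |> purrr::list_rbind()
  structure(list(
    phase_summary = phase_counts(g),
    consistency = assess_consistency(g),
    thresholds = thresholds,
    orphans = detect_orphans(g),
    subtrajectories = monochromatic_subtrajectories(g),
    trend = trend_ratio(g),
    n_studies = nrow(s),
    n_completed = sum(s$status == "completed"),
    n_contemplated = sum(s$status == "contemplated"),
    # the span of the program is the span of what has actually been done
    year_span = if (any(s$status == "completed")) {
      diff(range(s$year[s$status == "completed"])) + 1L
    } else {
      0L
    }
  ), class = "aero_report")
}

#' @export
print.aero_report <- function(x, ...) {
  cat(sprintf("<aero_report> %d studies (%d completed, %d contemplated), %d-year span\n",
              x$n_studies, x$n_completed, x$n_contemplated, x$year_span))
  t <- x$trend
  cat(sprintf("  trend: %d positive / %d negative / %d inconclusive",
              t$n_positive, t$n_negative, t$n_inconclusive))
  if (!is.na(t$ratio_display)) cat(sprintf("  (%s positive:negative)", t$ratio_display))
  cat("\n")
  occ <- x$phase_summary[x$phase_summary$n_completed > 0L, ]
  for (i in seq_len(nrow(occ))) {
    cat(sprintf("  %-9s %d completed (+%d -%d ?%d)\n", occ$phase[i],
                occ$n_completed[i], occ$n_positive[i], occ$n_negative[i],
                occ$n_inconclusive[i]))
  }
  th <- x$thresholds[!is.na(x$thresholds$n_positive_before), ]
  for (i in seq_len(nrow(th))) {
    cat(sprintf("  threshold %s -> %s: %d positive before %s\n",
                th$source_phase[i], th$target_phase[i],
                th$n_positive_before[i], th$first_target_study[i]))
  }
  if (length(x$orphans)) {
    cat("  orphans:", paste(x$orphans, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a robustness report
#'
#' `tidy()` returns the per-phase summary joined with the consistency flags,
#' one row per schema phase; `glance()` returns a one-row overview of the
#' whole program.
#'
#' @param x An `aero_report`.
#' @param ... Unused.
#' @return A tibble.
#' @examples
#' tidy(aero_analyze(fixture_moxifloxacin()))
#' glance(aero_analyze(fixture_moxifloxacin()))
#' @method tidy aero_report
#' @export
tidy.aero_report <- function(x, ...) {
  dplyr::left_join(x$phase_summary,
                   x$consistency[, c("phase", "has_consistency",
                                     "is_fully_consistent")],
                   by = "phase")
}

#' @rdname tidy.aero_report
#' @method glance aero_report
#' @export
glance.aero_report <- function(x, ...) {
  tibble::tibble(
    n_studies = x$n_studies,
    n_completed = x$n_completed,
    n_contemplated = x$n_contemplated,
    n_positive = x$trend$n_positive,
    n_negative = x$trend$n_negative,
    n_inconclusive = x$trend$n_inconclusive,
    pos_neg_ratio = x$trend$pos_neg_ratio,
    n_orphans = length(x$orphans),
    year_span = x$year_span
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' What-if planning over contemplated studies
#'
#' Assigns hypothetical outcomes to contemplated studies and recomputes the
#' robustness report on the updated program, leaving the original graph
#' untouched. This is the planning move: "suppose options A and C are both
#' pursued and turn out positive — what does the state of evidence become?"
#'
#' @param g An `aero_graph`.
#' @param ... Named assignments, `id = "outcome"`, or a single named
#'   character vector/list. Every assigned id must be a contemplated study.
#' @return A list with the updated `graph` and its `report`.
#' @examples
#' w <- whatif(fixture_moxifloxacin("figure4"), A = "positive", C = "positive")
#' w$report$trend
#' @export
whatif <- function(g, ...) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) ||
      (length(dots) == 1L && identical(names(dots), "")) ) {
    dots <- as.list(dots[[1]])
  }
  assignments <- purrr::map_chr(dots, as.character)
  if (length(assignments)) {
    assert_known_ids(g, names(assignments))
    s <- g$studies
    idx <- match(names(assignments), s$id)
    not_cont <- s$status[idx] != "contemplated"
    if (any(not_cont)) {
      rlang::abort(paste0("what-if assignment to completed study: ",
                          paste(names(assignments)[not_cont], collapse = ", ")),
                   class = "aero_error_whatif")
    }
    s$outcome[idx] <- parse_outcome(assignments)
    s$status[idx] <- "completed"
    g$studies <- s
    validate_aero_graph(g)
  }
  list(graph = g, report = aero_analyze(g))
}

#' Serialize a robustness report to JSON
#'
#' A stable, schema-versioned JSON document with fixed key order, suitable
#' for machine consumption downstream of the command-line `analyze`
#' subcommand.
#'
#' @param report An `aero_report`.
#' @param pretty Pretty-print the JSON.
#' @return A JSON string.
#' @examples
#' cat(report_to_json(aero_analyze(fixture_toy("figure1"))))
#' @export
report_to_json <- function(report, pretty = TRUE) {
  st <- report$subtrajectories
  doc <- list(
    schema_version = "1.0",
    n_studies = report$n_studies,
    n_completed = report$n_completed,
    n_contemplated = report$n_contemplated,
    year_span = report$year_span,
    trend = as.list(report$trend),
    phase_summary = report$phase_summary,
    consistency = dplyr::mutate(
      report$consistency,
      consistent_outcomes = purrr::map(.data$consistent_outcomes, as.list)),
    thresholds = report$thresholds,
    orphans = as.list(report$orphans),
    subtrajectories = purrr::map(seq_len(nrow(st)), function(i) {
      list(outcome = st$outcome[i],
           studies = as.list(st$studies[[i]]),
           edges = st$edges[[i]][, c("parent", "child")])
    })
  )
  jsonlite::toJSON(doc, dataframe = "rows", auto_unbox = TRUE, na = "null",
                   pretty = pretty)
}
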