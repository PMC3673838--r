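#' Build an evidence graph from study and edge tables
#'
#' The central container: a directed acyclic graph whose nodes are individual
#' study reports, stratified by research phase and ordered in time, with
#' directed edges recording intellectual lineage from a parent study to the
#' child study that built on it. Edges may descend in phase (a later-phase
#' result informing a subsequent earlier-phase experiment) — only time must
#' be respected. Edges between two studies published in the same report are
#' flagged `same_report` and are exempt from strict temporal precedence
#' (their endpoints must share a year).
#'
#' @param studies Data frame with columns `id` (unique whitespace-free
#'   token), `phase` (member of the schema), `year` (integer calendar year),
#'   and optionally `label` (free-text citation; defaults to the id), `seq`
#'   (integer within-year ordinal used as a tie-breaker, default 0),
#'   `outcome` (`positive`/`negative`/`inconclusive`; required for completed
#'   studies, must be absent/NA for contemplated ones) and `status`
#'   (`completed`, the default, or `contemplated`). Extra columns are kept
#'   and survive serialization round-trips.
#' @param edges Data frame with columns `parent`, `child` and optionally
#'   logical `same_report` (default `FALSE`). May be `NULL` for an edgeless
#'   graph.
#' @param phases An [aero_phases()] schema.
#' @param year_range Permitted span of calendar years.
#'
#' @return An `aero_graph`: a list with tibbles `studies` and `edges` plus
#'   the `phases` schema.
#' @examples
#' g <- aero_graph(
#'   tibble::tibble(
#'     id = c("a", "b"), phase = c("in_vitro", "in_vivo"),
#'     year = c(2001, 2003), outcome = c("positive", "negative")
#'   ),
#'   tibble::tibble(parent = "a", child = "b")
#' )
#' g
#' @export
aero_graph <- function(studies = NULL, edges = NULL, phases = aero_phases(),
                       year_range = c(1800L, 2100L)) {
  studies <- normalize_studies(studies)
  edges <- normalize_edges(edges)
  g <- structure(
    list(studies = studies, edges = edges, phases = phases,
         year_range = as.integer(year_range)),
    class = "aero_graph"
  )
  validate_aero_graph(g)
}

normalize_studies <- function(studies) {
  if (is.null(studies) || nrow(tibble::as_tibble(studies)) == 0L) {
    return(tibble::tibble(
      id = character(), label = character(), phase = character(),
      year = integer(), seq = integer(), outcome = character(),
      status = character()
    ))
  }
  studies <- tibble::as_tibble(studies)
  need <- setdiff(c("id", "phase", "year"), names(studies))
  if (length(need)) {
    rlang::abort(paste0("study table is missing column(s): ",
                        paste(need, collapse = ", ")),
                 class = "aero_error_input")
  }
  if (!"label" %in% names(studies)) studies$label <- studies$id
  if (!"seq" %in% names(studies)) studies$seq <- 0L
  if (!"outcome" %in% names(studies)) studies$outcome <- NA_character_
  if (!"status" %in% names(studies)) studies$status <- "completed"
  studies <- dplyr::mutate(
    studies,
    id = as.character(.data$id),
    label = dplyr::coalesce(as.character(.data$label), .data$id),
    phase = as.character(.data$phase),
    year = as.integer(.data$year),
    seq = dplyr::coalesce(as.integer(.data$seq), 0L),
    outcome = parse_outcome(.data$outcome),
    status = dplyr::coalesce(tolower(as.character(.data$status)), "completed")
  )
  dplyr::relocate(studies, "id", "label", "phase", "year", "seq", "outcome", "status")
}

parse_outcome <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("", "na", "-", "–")] <- NA_character_
  bad <- !is.na(x) & !x %in% outcome_levels()
  if (any(bad)) {
    rlang::abort(paste0("unknown outcome value(s): ",
                        paste(unique(x[bad]), collapse = ", ")),
                 class = "aero_error_input")
  }
  x
}

normalize_edges <- function(edges) {
  if (is.null(edges) || nrow(tibble::as_tibble(edges)) == 0L) {
    return(tibble::tibble(parent = character(), child = character(),
                          same_report = logical()))
  }
  edges <- tibble::as_tibble(edges)
  need <- setdiff(c("parent", "child"), names(edges))
  if (length(need)) {
    rlang::abort(paste0("edge table is missing column(s): ",
                        paste(need, collapse = ", ")),
                 class = "aero_error_input")
  }
  if (!"same_report" %in% names(edges)) edges$same_report <- FALSE
  tibble::tibble(
    parent = as.character(edges$parent),
    child = as.character(edges$child),
    same_report = dplyr::coalesce(as.logical(edges$same_report), FALSE)
  )
}

#' Validate an evidence graph
#'
#' Checks every structural invariant: unique whitespace-free ids, phases
#' drawn from the schema, years in range, outcome present exactly when the
#' study is completed, edge endpoints known, no self-loops or duplicate
#' edges, acyclicity, and temporal sanity (a parent's year never exceeds its
#' child's; same-report edges join studies of equal year).
#'
#' @param g An `aero_graph`.
#' @return `g`, invisibly unchanged, or an error describing the violation.
#' @export
validate_aero_graph <- function(g) {
  s <- g$studies
  e <- g$edges
  if (anyDuplicated(s$id)) {
    rlang::abort(paste0("duplicate study id(s): ",
                        paste(unique(s$id[duplicated(s$id)]), collapse = ", ")),
                 class = "aero_error_validate")
  }
  if (any(!nzchar(s$id)) || any(grepl("\\s", s$id))) {
    rlang::abort("study ids must be non-empty, whitespace-free tokens",
                 class = "aero_error_validate")
  }
  bad_phase <- setdiff(s$phase, g$phases$phase)
  if (length(bad_phase)) {
    rlang::abort(paste0("unknown phase(s): ", paste(bad_phase, collapse = ", ")),
                 class = "aero_error_validate")
  }
  if (any(is.na(s$year)) ||
      any(s$year < g$year_range[1] | s$year > g$year_range[2])) {
    rlang::abort(paste0("study years must lie in ", g$year_range[1], "-",
                        g$year_range[2]),
                 class = "aero_error_validate")
  }
  if (any(!s$status %in% c("completed", "contemplated"))) {
    rlang::abort("status must be 'completed' or 'contemplated'",
                 class = "aero_error_validate")
  }
  no_out <- s$status == "completed" & is.na(s$outcome)
  if (any(no_out)) {
    rlang::abort(paste0("completed study without outcome: ",
                        paste(s$id[no_out], collapse = ", ")),
                 class = "aero_error_validate")
  }
  has_out <- s$status == "contemplated" & !is.na(s$outcome)
  if (any(has_out)) {
    rlang::abort(paste0("contemplated study may not carry an outcome: ",
                        paste(s$id[has_out], collapse = ", ")),
                 class = "aero_error_validate")
  }
  if (nrow(e)) {
    unknown <- setdiff(c(e$parent, e$child), s$id)
    if (length(unknown)) {
      rlang::abort(paste0("edge references unknown study id(s): ",
                          paste(unknown, collapse = ", ")),
                   class = "aero_error_validate")
    }
    if (any(e$parent == e$child)) {
      rlang::abort("self-loop edges are not allowed", class = "aero_error_validate")
    }
    if (anyDuplicated(paste(e$parent, e$child))) {
      rlang::abort("duplicate (parent, child) edges", class = "aero_error_validate")
    }
    yp <- s$year[match(e$parent, s$id)]
    yc <- s$year[match(e$child, s$id)]
    late <- !e$same_report & yp > yc
    if (any(late)) {
      rlang::abort(paste0("temporal violation: child precedes parent on edge(s) ",
                          paste(e$parent[late], "->", e$child[late], collapse = "; ")),
                   class = "aero_error_validate")
    }
    uneq <- e$same_report & yp != yc
    if (any(uneq)) {
      rlang::abort("same-report edges must join studies of equal year",
                   class = "aero_error_validate")
    }
    ig <- as_igraph(g)
    if (!igraph::is_dag(ig)) {
      cyc <- find_cycle(ig)
      rlang::abort(paste0("lineage edges form a cycle: ",
                          paste(cyc, collapse = " -> ")),
                   class = "aero_error_cycle")
    }
  }
  # temporal_order() errors if within-year lineage contradicts seq
  if (nrow(s) > 0L) temporal_order(g)
  invisible(g)
}

find_cycle <- function(ig) {
  # one directed cycle, for the diagnostic only
  for (v in igraph::V(ig)) {
    reach <- igraph::subcomponent(ig, v, mode = "out")
    preds <- igraph::neighbors(ig, v, mode = "in")
    back <- intersect(as.integer(preds), as.integer(reach))
    if (length(back)) {
      p <- igraph::shortest_paths(ig, from = v, to = back[1], mode = "out")$vpath[[1]]
      return(c(igraph::V(ig)$name[as.integer(p)], igraph::V(ig)$name[v]))
    }
  }
  character()
}

#' Convert an evidence graph to an igraph object
#'
#' Vertices carry `phase`, `year`, `seq`, `outcome`, `status` attributes;
#' edges carry `same_report`.
#'
#' @param g An `aero_graph`.
#' @param drop_same_report Drop same-report edges (used where only strict
#'   lineage precedence matters).
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(g, drop_same_report = FALSE) {
  e <- g$edges
  if (drop_same_report) e <- e[!e$same_report, , drop = FALSE]
  igraph::graph_from_data_frame(
    d = data.frame(from = e$parent, to = e$child, same_report = e$same_report),
    directed = TRUE,
    vertices = data.frame(
      name = g$studies$id, phase = g$studies$phase, year = g$studies$year,
      seq = g$studies$seq,
      outcome = ifelse(is.na(g$studies$outcome), "", g$studies$outcome),
      status = g$studies$status
    )
  )
}

#' Add a study to an evidence graph
#'
#' @param g An `aero_graph`.
#' @param id,phase,year Study key, phase (schema member) and calendar year.
#' @param outcome Outcome code; required for completed studies and forbidden
#'   for contemplated ones.
#' @param status `"completed"` (default) or `"contemplated"`.
#' @param label Display label; defaults to the id.
#' @param seq Within-year ordinal tie-breaker.
#' @return The graph with the study added.
#' @examples
#' g <- aero_graph()
#' g <- add_study(g, "u1", "in_vitro", 1998, outcome = "positive")
#' @export
add_study <- function(g, id, phase, year, outcome = NULL,
                      status = "completed", label = id, seq = 0L) {
  if (id %in% g$studies$id) {
    rlang::abort(paste0("duplicate study id: ", id), class = "aero_error_validate")
  }
  row <- tibble::tibble(
    id = as.character(id), label = as.character(label),
    phase = as.character(phase), year = as.integer(year),
    seq = as.integer(seq),
    outcome = if (is.null(outcome)) NA_character_ else parse_outcome(outcome),
    status = tolower(status)
  )
  g$studies <- dplyr::bind_rows(g$studies, row)
  validate_aero_graph(g)
  g
}

#' Add a lineage edge to an evidence graph
#'
#' Adds a directed parent-to-child intellectual-lineage link and re-checks
#' acyclicity and temporal precedence. Phase backtracking (later-phase
#' parent to earlier-phase child) is legal; travelling backwards in time is
#' not.
#'
#' @param g An `aero_graph`.
#' @param parent,child Existing study ids.
#' @param same_report `TRUE` when the two studies were published in the same
#'   report; such edges require equal years and are drawn without an
#'   arrowhead.
#' @return The graph with the edge added.
#' @export
add_edge <- function(g, parent, child, same_report = FALSE) {
  ids <- g$studies$id
  unknown <- setdiff(c(parent, child), ids)
  if (length(unknown)) {
    rlang::abort(paste0("unknown study id(s): ", paste(unknown, collapse = ", ")),
                 class = "aero_error_validate")
  }
  if (any(g$edges$parent == parent & g$edges$child == child)) {
    rlang::abort(paste0("edge already present: ", parent, " -> ", child),
                 class = "aero_error_validate")
  }
  g$edges <- dplyr::bind_rows(
    g$edges,
    tibble::tibble(parent = parent, child = child,
                   same_report = isTRUE(same_report))
  )
  validate_aero_graph(g)
  g
}

#' @export
print.aero_graph <- function(x, ...) {
  s <- x$studies
  n_c <- sum(s$status == "completed")
  n_t <- sum(s$status == "contemplated")
  cat(sprintf("<aero_graph> %d studies (%d completed, %d contemplated), %d edges\n",
              nrow(s), n_c, n_t, nrow(x$edges)))
  if (nrow(s)) {
    cat(sprintf("  phases: %s\n",
                paste(intersect(x$phases$phase, unique(s$phase)), collapse = " < ")))
    cat(sprintf("  years:  %d-%d\n", min(s$year), max(s$year)))
    tab <- table(factor(s$outcome[s$status == "completed"], outcome_levels()))
    cat(sprintf("  outcomes: %s\n",
                paste(names(tab), as.integer(tab), sep = "=", collapse = " ")))
  }
  invisible(x)
}

#' Structural equality of two evidence graphs
#'
#' Compares the phase schema, the study table (core columns, id order
#' ignored) and the edge set. Used by serialization round-trip checks.
#'
#' @param a,b Two `aero_graph` objects.
#' @return `TRUE` or `FALSE`.
#' @export
aero_equal <- function(a, b) {
  core <- c("id", "label", "phase", "year", "seq", "outcome", "status")
  sa <- dplyr::arrange(a$studies[core], .data$id)
  sb <- dplyr::arrange(b$studies[core], .data$id)
  ea <- dplyr::arrange(a$edges, .data$parent, .data$child)
  eb <- dplyr::arrange(b$edges, .data$parent, .data$child)
  identical(a$phases$phase, b$phases$phase) &&
    isTRUE(all.equal(as.data.frame(sa), as.data.frame(sb),
                     check.attributes = FALSE)) &&
    isTRUE(all.equal(as.data.frame(ea), as.data.frame(eb),
                     check.attributes = FALSE))
}
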