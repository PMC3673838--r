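#' Per-phase outcome tallies
#'
#' Counts completed studies by phase and outcome. Contemplated studies are
#' excluded from every count; phases of the schema with no studies appear
#' with zeros so that the shape of the ladder is always visible.
#'
#' @param g An `aero_graph`.
#' @return A tibble with one row per schema phase: `phase`, `rank`,
#'   `n_completed`, `n_positive`, `n_negative`, `n_inconclusive`.
#' @examples
#' phase_counts(fixture_moxifloxacin())
#' @export
phase_counts <- function(g) {
  s <- completed(g)
  base <- tibble::tibble(phase = g$phases$phase, rank = g$phases$rank)
  tallies <- s |>
    dplyr::count(.data$phase, .data$outcome) |>
    tidyr::pivot_wider(names_from = "outcome", values_from = "n",
                       values_fill = 0L)
  for (oc in outcome_levels()) {
    if (!oc %in% names(tallies)) tallies[[oc]] <- integer(nrow(tallies))
  }
  base |>
    dplyr::left_join(tallies, by = "phase") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(outcome_levels()),
                                ~ dplyr::coalesce(.x, 0L))) |>
    dplyr::transmute(
      phase = .data$phase, rank = .data$rank,
      n_completed = .data$positive + .data$negative + .data$inconclusive,
      n_positive = .data$positive,
      n_negative = .data$negative,
      n_inconclusive = .data$inconclusive
    )
}

completed <- function(g) g$studies[g$studies$status == "completed", , drop = FALSE]

#' Within-phase consistency of results
#'
#' Consistency — agreement among studies measuring the same or a similar
#' endpoint — requires at least two completed studies in a phase sharing an
#' outcome. A phase is fully consistent when every completed study in it
#' shares one outcome; a phase mixing all three outcomes one study each has
#' no evidence of consistency at all.
#'
#' @param g An `aero_graph`.
#' @return A tibble with one row per schema phase: `phase`,
#'   `has_consistency` (some outcome is shared by at least two studies),
#'   `consistent_outcomes` (list-column of those outcomes) and
#'   `is_fully_consistent`.
#' @examples
#' assess_consistency(fixture_toy("figure2"))
#' @export
assess_consistency <- function(g) {
  pc <- phase_counts(g)
  counts <- as.matrix(pc[, c("n_positive", "n_negative", "n_inconclusive")])
  colnames(counts) <- outcome_levels()
  tibble::tibble(
    phase = pc$phase,
    has_consistency = apply(counts >= 2L, 1L, any),
    consistent_outcomes = apply(counts, 1L, function(r) names(r)[r >= 2L],
                                simplify = FALSE),
    is_fully_consistent = pc$n_completed > 0L &
      apply(counts, 1L, max) == pc$n_completed
  )
}

#' Concordance along a lineage path
#'
#' Concordance is agreement in the direction of result along a translational
#' path across qualitatively different endpoints (for instance an in-vivo
#' efficacy endpoint feeding a phase 1 pharmacokinetic study). A path is
#' perfectly concordant exactly when all studies on it share one outcome;
#' otherwise the adjacent pairs whose outcomes differ are reported as
#' discordant steps.
#'
#' @param g An `aero_graph`.
#' @param path Character vector of study ids forming a directed lineage path
#'   (each consecutive pair must be an edge); all studies must be completed.
#' @return A list with `path`, `classification`
#'   (`"perfectly_concordant"` or `"discordant"`) and `discordant_steps`, a
#'   tibble of offending `(from, to)` pairs.
#' @examples
#' classify_path(fixture_toy("figure2"), c("a1", "a2", "b3", "g3", "d2"))
#' @export
classify_path <- function(g, path) {
  assert_known_ids(g, path)
  if (length(path) > 1L) {
    key <- paste(g$edges$parent, g$edges$child)
    steps <- paste(path[-length(path)], path[-1])
    if (!all(steps %in% key)) {
      rlang::abort(paste0("not a directed lineage path; missing edge(s): ",
                          paste(setdiff(steps, key), collapse = ", ")),
                   class = "aero_error_path")
    }
  }
  s <- g$studies[match(path, g$studies$id), , drop = FALSE]
  if (any(s$status != "completed")) {
    rlang::abort("concordance is defined over completed studies only",
                 class = "aero_error_path")
  }
  if (length(path) > 1L) {
    differ <- s$outcome[-nrow(s)] != s$outcome[-1]
  } else {
    differ <- logical(0)
  }
  list(
    path = path,
    classification = if (any(differ)) "discordant" else "perfectly_concordant",
    discordant_steps = tibble::tibble(from = path[-length(path)][differ],
                                      to = path[-1][differ])
  )
}

#' De-facto threshold for a phase transition
#'
#' The number of positive completed studies accumulated in `source_phase`
#' strictly before the first study of the next phase up — the implicit
#' evidential bar the program applied before committing to the transition.
#' "Before" is judged in the temporal total order ([temporal_order()]), so
#' a same-year parent of the first next-phase study still counts.
#'
#' @param g An `aero_graph`.
#' @param source_phase A schema phase that is not the top rank.
#' @return A one-row tibble: `source_phase`, `target_phase`,
#'   `first_target_study`, `n_positive_before`. When the target phase has no
#'   completed study the last two are `NA` (the transition has not
#'   happened).
#' @examples
#' de_facto_threshold(fixture_moxifloxacin(), "phase1")
#' @export
de_facto_threshold <- function(g, source_phase) {
  sch <- g$phases
  r <- phase_rank(sch, source_phase)
  if (is.na(r)) {
    rlang::abort(paste0("unknown phase: ", source_phase),
                 class = "aero_error_validate")
  }
  if (r == max(sch$rank)) {
    rlang::abort("the top-rank phase has no next phase to transition into",
                 class = "aero_error_validate")
  }
  target_phase <- sch$phase[sch$rank == r + 1L]
  ord <- temporal_order(g)
  s <- completed(g)
  pos <- stats::setNames(match(s$id, ord), s$id)
  tgt <- s$id[s$phase == target_phase]
  if (length(tgt) == 0L) {
    return(tibble::tibble(source_phase = source_phase,
                          target_phase = target_phase,
                          first_target_study = NA_character_,
                          n_positive_before = NA_integer_))
  }
  first_tgt <- tgt[which.min(pos[tgt])]
  src_pos <- s$id[s$phase == source_phase & s$outcome == "positive"]
  tibble::tibble(
    source_phase = source_phase,
    target_phase = target_phase,
    first_target_study = first_tgt,
    n_positive_before = sum(pos[src_pos] < pos[first_tgt])
  )
}

#' Orphaned studies
#'
#' An orphaned study has no incoming lineage edge: it was not directly
#' justified by prior evidence within the program. Parentless studies in
#' the lowest-rank phase present are exempt — every program has to start
#' somewhere.
#'
#' @param g An `aero_graph`.
#' @return Character vector of orphaned study ids.
#' @examples
#' detect_orphans(fixture_toy("figure2"))
#' @export
detect_orphans <- function(g) {
  s <- g$studies
  if (nrow(s) == 0L) return(character())
  lowest <- min(phase_rank(g$phases, s$phase))
  roots <- setdiff(s$id, g$edges$child)
  roots[phase_rank(g$phases, s$phase[match(roots, s$id)]) > lowest]
}

#' Maximal same-outcome sub-trajectories
#'
#' Finds, for each outcome, the maximal weakly connected sub-structures
#' induced by completed studies sharing that outcome — the "robustly
#' positive" or "robustly negative" strands of a program. Weak connectivity
#' groups siblings that hang off a common same-outcome study. Only
#' components of two or more studies are reported.
#'
#' @param g An `aero_graph`.
#' @return A tibble with columns `outcome`, `studies` (list of id vectors,
#'   sorted), `edges` (list of tibbles of internal edges) and `n_studies`.
#' @examples
#' monochromatic_subtrajectories(fixture_moxifloxacin())
#' @export
monochromatic_subtrajectories <- function(g) {
  s <- completed(g)
  out <- purrr::map(outcome_levels(), function(oc) {
    ids <- s$id[s$outcome == oc]
    if (length(ids) < 2L) return(NULL)
    e <- g$edges[g$edges$parent %in% ids & g$edges$child %in% ids, , drop = FALSE]
    sub <- igraph::graph_from_data_frame(
      d = e[, c("parent", "child")], directed = TRUE,
      vertices = data.frame(name = ids))
    comp <- igraph::components(sub, mode = "weak")
    keep <- which(comp$csize >= 2L)
    purrr::map(keep, function(k) {
      members <- sort(names(comp$membership)[comp$membership == k])
      tibble::tibble(
        outcome = oc,
        studies = list(members),
        edges = list(e[e$parent %in% members & e$child %in% members, ,
                       drop = FALSE]),
        n_studies = length(members)
      )
    }) |> purrr::list_rbind()
  })
  res <- purrr::list_rbind(purrr::compact(out))
  if (is.null(res) || nrow(res) == 0L) {
    return(tibble::tibble(outcome = character(), studies = list(),
                          edges = list(), n_studies = integer()))
  }
  res
}

#' Overall outcome trend
#'
#' Tallies completed studies by outcome across the whole program and forms
#' the positive-to-negative ratio, the headline figure for whether the
#' accumulated evidence leans for or against further development.
#'
#' @param g An `aero_graph`.
#' @return A one-row tibble: `n_positive`, `n_negative`, `n_inconclusive`,
#'   `pos_neg_ratio` (NA when there are no negative studies) and
#'   `ratio_display`, the reduced integer form such as `"3:1"`.
#' @examples
#' trend_ratio(fixture_moxifloxacin())
#' @export
trend_ratio <- function(g) {
  s <- completed(g)
  np <- sum(s$outcome == "positive")
  nn <- sum(s$outcome == "negative")
  ni <- sum(s$outcome == "inconclusive")
  ratio <- if (nn > 0L) np / nn else NA_real_
  disp <- if (nn > 0L && np > 0L) {
    d <- gcd(np, nn)
    paste0(np / d, ":", nn / d)
  } else {
    NA_character_
  }
  tibble::tibble(n_positive = np, n_negative = nn, n_inconclusive = ni,
                 pos_neg_ratio = ratio, ratio_display = disp)
}

gcd <- function(a, b) if (b == 0L) a else gcd(b, a %% b)
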