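#' Generate a synthetic research program
#'
#' Produces a random but valid evidence graph emulating the structure of a
#' translational program: studies accumulate phase by phase over a span of
#' years, each non-root study cites one to `max_parents` temporally earlier
#' studies with a preference for the same or the immediately lower phase,
#' and a small fraction of studies are deliberate orphans. The seed fully
#' determines the output.
#'
#' Default outcome probabilities (0.63/0.21/0.16) follow the empirical
#' outcome mix of the packaged moxifloxacin program (12/19, 4/19, 3/19);
#' the default shape (a handful of studies per phase over roughly a decade)
#' likewise mirrors that program's scale.
#'
#' @param n_per_phase Integer vector, studies per schema phase (recycled to
#'   the schema length).
#' @param phases An [aero_phases()] schema.
#' @param year_range Two-element span of calendar years.
#' @param p_outcomes Probabilities of positive/negative/inconclusive; must
#'   sum to 1.
#' @param max_parents Maximum parents drawn per study (k >= 1).
#' @param p_backtrack Probability that a study may also cite parents from
#'   higher phases (phase backtracking).
#' @param p_orphan Probability that a non-lowest-phase study is left without
#'   parents.
#' @param p_contemplated Probability that a final-year study is a
#'   contemplated future study rather than a completed one.
#' @param seed Integer seed; identical seeds give identical graphs.
#' @return A validated `aero_graph`.
#' @examples
#' aero_generate(n_per_phase = c(3, 4, 4, 3, 1), seed = 42)
#' @export
aero_generate <- function(n_per_phase = c(3, 5, 6, 5, 0),
                          phases = aero_phases(),
                          year_range = c(1998L, 2009L),
                          p_outcomes = c(positive = 0.63, negative = 0.21,
                                         inconclusive = 0.16),
                          max_parents = 3L,
                          p_backtrack = 0.1,
                          p_orphan = 0.05,
                          p_contemplated = 0,
                          seed = 1L) {
  n_per_phase <- rep_len(as.integer(n_per_phase), nrow(phases))
  if (any(p_outcomes < 0) || abs(sum(p_outcomes) - 1) > 1e-8) {
    rlang::abort("p_outcomes must be non-negative and sum to 1",
                 class = "aero_error_input")
  }
  if (max_parents < 1L) {
    rlang::abort("max_parents must be >= 1", class = "aero_error_input")
  }
  present <- which(n_per_phase > 0L)
  if (length(present) == 0L) return(aero_graph(phases = phases))
  if (n_per_phase[1] == 0L && p_backtrack == 0 && p_orphan == 0 &&
      min(present) > 1L) {
    rlang::abort(paste0("infeasible config: no studies in the lowest phase ",
                        "but backtracking and orphans are disabled"),
                 class = "aero_error_input")
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  y0 <- year_range[1]
  span <- year_range[2] - year_range[1]
  nphase <- length(n_per_phase)
  resample <- function(x, ...) x[sample.int(length(x), ...)]
  rows <- purrr::map(seq_len(nphase), function(p) {
    n <- n_per_phase[p]
    if (n == 0L) return(NULL)
    # phases start later up the ladder but overlap, as real programs do
    lo <- y0 + floor(span * (p - 1) / (nphase + 1))
    yrs <- sort(resample(seq(lo, year_range[2]), n, replace = TRUE))
    tibble::tibble(
      id = paste0("s", p, "_", seq_len(n)),
      phase = phases$phase[p],
      year = as.integer(yrs),
      seq = seq_len(n)
    )
  }) |> purrr::list_rbind()

  # the program must begin in its lowest occupied phase: pull that phase's
  # first study to the front of the timeline
  low_phase <- phases$phase[min(present)]
  first_low <- which(rows$phase == low_phase)[1]
  rows$year[first_low] <- min(rows$year)
  rows$seq[first_low] <- 0L

  rows$outcome <- sample(outcome_levels(), nrow(rows), replace = TRUE,
                         prob = p_outcomes)
  rows$status <- "completed"
  if (p_contemplated > 0) {
    last <- rows$year == max(rows$year)
    cont <- last & stats::runif(nrow(rows)) < p_contemplated
    rows$status[cont] <- "contemplated"
    rows$outcome[cont] <- NA_character_
  }

  ord <- order(rows$year, rows$seq, rows$id)
  rows <- rows[ord, ]
  rank_of <- phase_rank(phases, rows$phase)
  lowest <- min(rank_of)
  edges <- list()
  for (i in seq_len(nrow(rows))) {
    if (i == 1L) next
    if (rank_of[i] > lowest && stats::runif(1) < p_orphan) next
    allow_up <- stats::runif(1) < p_backtrack
    cand <- which(seq_len(nrow(rows)) < i &
                    (allow_up | rank_of <= rank_of[i]))
    # with orphans disabled, fall back to any earlier study rather than
    # leave a higher-phase study parentless
    if (!length(cand) && p_orphan == 0 && rank_of[i] > lowest) {
      cand <- seq_len(i - 1L)
    }
    if (!length(cand)) next
    # prefer the same or immediately lower phase
    wt <- 1 / (1 + abs(rank_of[cand] - (rank_of[i] - 0.5)))
    k <- sample(seq_len(min(max_parents, length(cand))), 1L)
    par <- cand[sample.int(length(cand), k, prob = wt)]
    edges[[length(edges) + 1L]] <- tibble::tibble(
      parent = rows$id[par], child = rows$id[i])
  }
  edges <- purrr::list_rbind(edges)
  aero_graph(rows, edges, phases = phases, year_range = year_range)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
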