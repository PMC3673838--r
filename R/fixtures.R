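#' The moxifloxacin-for-tuberculosis research program
#'
#' Nineteen studies (1998-2009) evaluating moxifloxacin for drug-susceptible
#' tuberculosis, spanning in-vitro and in-vivo pre-clinical work and phase 1
#' and phase 2 clinical trials, with hand-curated parent/child lineage
#' links. The `u1`-`v1` link is a same-report edge (both studies appeared in
#' one publication, hence drawn without an arrowhead).
#'
#' With `state = "figure4"` four contemplated future studies are added —
#' `A` (another in-vivo study), `B` (phase 1), `C` (phase 2) and `D` (a
#' phase 3 trial) — attached to the terminal studies of the sub-trajectories
#' that motivate each option. The parent links of these contemplated nodes
#' are a reconstruction from the narrative arguments, not tabulated data.
#'
#' @param state `"completed_only"` (default): the 19 completed studies;
#'   `"figure4"`: additionally the four contemplated options A-D.
#' @return An `aero_graph`.
#' @examples
#' fixture_moxifloxacin()
#' fixture_moxifloxacin("figure4")
#' @export
fixture_moxifloxacin <- function(state = c("completed_only", "figure4")) {
  state <- match.arg(state)
  studies <- tibble::tribble(
    ~id,  ~label,                ~phase,     ~year, ~outcome,
    "u1", "Ji et al. 1998",      "in_vitro", 1998L, "positive",
    "u2", "Gillespie et al. 1999","in_vitro", 1999L, "positive",
    "u3", "Shandil et al. 2007", "in_vitro", 2007L, "positive",
    "v1", "Ji et al. 1998",      "in_vivo",  1998L, "positive",
    "v2", "Miyazaki et al. 1999","in_vivo",  1999L, "positive",
    "v3", "Lounis et al. 2001",  "in_vivo",  2001L, "positive",
    "v4", "Yoshimatsu et al. 2002","in_vivo", 2002L, "inconclusive",
    "v5", "Nuermberger et al. 2004","in_vivo", 2004L, "inconclusive",
    "w1", "Gosling et al. 2003", "phase1",   2003L, "positive",
    "w2", "Pletz et al. 2004",   "phase1",   2004L, "positive",
    "w3", "Gillespie et al. 2005","phase1",  2005L, "negative",
    "w4", "Johnson et al. 2006", "phase1",   2006L, "positive",
    "w5", "Nijland et al. 2007", "phase1",   2007L, "negative",
    "w6", "Peloquin et al. 2008","phase1",   2008L, "inconclusive",
    "x1", "Burman et al. 2006",  "phase2",   2006L, "negative",
    "x2", "Rustomjee et al. 2007","phase2",  2007L, "positive",
    "x3", "Conde et al. 2009",   "phase2",   2009L, "positive",
    "x4", "Dorman et al. 2009",  "phase2",   2009L, "negative",
    "x5", "Wang et al. 2009",    "phase2",   2009L, "positive"
  )
  edges <- tibble::tribble(
    ~parent, ~child, ~same_report,
    "u1", "v1", TRUE,
    "u2", "w1", FALSE,
    "u2", "w2", FALSE,
    "u3", "w5", FALSE,
    "u3", "w6", FALSE,
    "v1", "v2", FALSE,
    "v2", "v3", FALSE,
    "v2", "w1", FALSE,
    "v3", "v4", FALSE,
    "v4", "v5", FALSE,
    "v5", "u3", FALSE,
    "v5", "w3", FALSE,
    "v5", "w4", FALSE,
    "w1", "v5", FALSE,
    "w2", "v5", FALSE,
    "w3", "x1", FALSE,
    "w4", "x1", FALSE,
    "w4", "x2", FALSE,
    "w6", "x4", FALSE,
    "x1", "w5", FALSE,
    "x1", "w6", FALSE,
    "x1", "x3", FALSE,
    "x1", "x4", FALSE,
    "x2", "x3", FALSE,
    "x3", "x5", FALSE
  )
  if (state == "figure4") {
    studies <- dplyr::bind_rows(
      studies,
      tibble::tibble(
        id = c("A", "B", "C", "D"),
        label = c("contemplated in vivo study",
                  "contemplated phase 1 study",
                  "contemplated phase 2 trial",
                  "contemplated phase 3 trial"),
        phase = c("in_vivo", "phase1", "phase2", "phase3"),
        year = 2010L, outcome = NA_character_
      )
    )
    studies$status <- c(rep("completed", 19L), rep("contemplated", 4L))
    edges <- dplyr::bind_rows(
      edges,
      tibble::tibble(
        parent = c("x4", "x4", "w5", "x4", "x5", "x5"),
        child = c("A", "B", "B", "C", "C", "D"),
        same_report = FALSE
      )
    )
  }
  aero_graph(studies, edges)
}

#' Three snapshots of a toy research program
#'
#' A small worked program used to introduce each analytic in isolation:
#'
#' * `"figure1"`: eight completed studies over five years across three
#'   phases, no lineage edges yet — the raw accumulating state of evidence.
#' * `"figure2"`: eleven studies over six years with the lineage edges,
#'   including a phase-backtracking link (`d1 -> g3`, a negative phase 2
#'   result informing a later phase 1 study) and one orphaned phase 2 study
#'   (`d3`, no incoming edges).
#' * `"figure3"`: twelve completed studies (a negative phase 3 trial `e1`
#'   follows the sole positive phase 2, `d2`) plus two contemplated next
#'   steps, a fourth phase 2 trial (`d4`) and a second phase 3 trial (`e2`).
#'
#' Ids are ASCII (`a1`, `b3`, `g1`, `d2`, `e1`); the Greek forms of the
#' narrative appear as display labels. Calendar years are an assignment
#' consistent with every stated relative ordering and the printed year
#' spans, as no absolute years are tabulated for this program.
#'
#' @param stage `"figure1"`, `"figure2"` or `"figure3"`.
#' @return An `aero_graph`.
#' @examples
#' fixture_toy("figure2")
#' @export
fixture_toy <- function(stage = c("figure1", "figure2", "figure3")) {
  stage <- match.arg(stage)
  studies <- tibble::tribble(
    ~id,  ~label,        ~phase,     ~year, ~outcome,
    "a1", "α1",     "in_vitro", 2000L, "positive",
    "a2", "α2",     "in_vitro", 2000L, "positive",
    "b1", "β1",     "in_vivo",  2001L, "negative",
    "b2", "β2",     "in_vivo",  2002L, "positive",
    "b3", "β3",     "in_vivo",  2002L, "positive",
    "g1", "γ1",     "phase1",   2003L, "positive",
    "g2", "γ2",     "phase1",   2003L, "inconclusive",
    "g3", "γ3",     "phase1",   2004L, "positive"
  )
  edges <- NULL
  if (stage %in% c("figure2", "figure3")) {
    studies <- dplyr::bind_rows(
      studies,
      tibble::tribble(
        ~id,  ~label,    ~phase,   ~year, ~outcome,
        "d1", "δ1", "phase2", 2004L, "negative",
        "d2", "δ2", "phase2", 2005L, "positive",
        "d3", "δ3", "phase2", 2005L, "inconclusive"
      )
    )
    edges <- tibble::tribble(
      ~parent, ~child,
      "a1", "a2",
      "a2", "b2",
      "a2", "b3",
      "a1", "b1",
      "b2", "g1",
      "b3", "g2",
      "b3", "g3",
      "g1", "d1",
      "d1", "g3",
      "b3", "d2",
      "g3", "d2"
    )
  }
  if (stage == "figure3") {
    studies <- dplyr::bind_rows(
      studies,
      tibble::tibble(
        id = c("e1", "d4", "e2"),
        label = c("ε1", "δ4", "ε2"),
        phase = c("phase3", "phase2", "phase3"),
        year = c(2005L, 2006L, 2006L),
        outcome = c("negative", NA_character_, NA_character_),
        status = c("completed", "contemplated", "contemplated")
      )
    )
    edges <- dplyr::bind_rows(
      edges,
      tibble::tibble(parent = c("d2", "e1", "e1"),
                     child = c("e1", "d4", "e2"))
    )
  }
  aero_graph(studies, edges)
}
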