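---
title: "Evidence graphs: model, analytics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence graphs: model, analytics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerograph)
```

## The model and its assumptions

`aerograph` represents a translational research program as a directed
acyclic graph. Each node is a single study report with five properties: a
short id, a research phase drawn from an ordered schema (by default
`in_vitro < in_vivo < phase1 < phase2 < phase3`), a publication year, an
outcome (`positive`, `negative` or `inconclusive` — the direction of the
result with respect to further research, not a statistical verdict), and a
status (`completed` or `contemplated`). Each directed edge records
intellectual lineage: the child study designed its question, dose, model or
endpoint on the basis of the parent's evidence.

Three modelling assumptions are worth making explicit:

1. **Outcomes are trichotomous.** The three-way coding compresses effect
   sizes, precision and author judgment into one ordinal-free label. It is
   deliberately coarse: the analytics below count and compare labels, and
   every conclusion they support inherits that coarseness.
2. **Lineage is curated, not derived.** Edges represent a judgment about
   which earlier evidence a study actually built on — typically distilled
   from citations (see transitive reduction below) — and the package treats
   the edge list as ground truth. No automatic derivation from citation
   databases is attempted.
3. **Time is respected; phase is not a constraint.** An edge may point from
   a phase 2 trial back down to a new animal study — phase backtracking is
   a real and informative feature of programs — but a parent can never be
   published after its child. Same-report edges (two studies in one
   publication) are the one exception to strict precedence: they require
   equal years and are drawn without an arrowhead.

## The temporal total order

Several analytics need a strict "before" relation between studies, but
publication years produce ties. The package resolves a year's ties
deterministically: lineage parents come before their children within the
year, remaining ties break on an explicit integer `seq` ordinal, and
finally on the id. The result is always a linear extension of the DAG
(ignoring same-report edges, which are exempt from strictness). If a
within-year edge contradicts the supplied `seq` ordinals the order is
*reported as an error*, never silently rearranged — the caller's data
carries a claim the caller must resolve. The `seq` field is the package's
mechanism for sub-year knowledge (publication month, preprint dates); the
packaged programs leave it at 0 and rely on the lineage rule, which is
exactly what places the 2006 phase 1 study `w4` before the 2006 phase 2
trial `x1` it parented — the placement on which the phase 1 → phase 2
threshold of 3 rests.

## The analytics

**Phase tallies and consistency.** `phase_counts()` counts completed
studies per phase and outcome (contemplated studies are excluded from every
count in the package until a what-if assignment completes them; empty
phases are reported with zeros). `assess_consistency()` flags a phase as
showing consistency when at least two completed studies share an outcome —
one study can never exhibit consistency — and as fully consistent when all
of them do. An inconclusive pair *is* a consistent pair (two studies
agreeing that the evidence is ambivalent), but inconclusive studies count
toward neither the positive nor the negative side of any other analytic.

**Concordance.** `classify_path()` evaluates a directed lineage path and
is strict: a path is perfectly concordant exactly when every study on it
carries the same outcome, and each adjacent pair that differs is reported
as a discordant step. A single-node path is trivially concordant.
Concordance is defined over directed paths only — it asks whether the
evidence *handed down* a lineage pointed one way.

**De-facto thresholds.** `de_facto_threshold(g, p)` counts the positive
completed studies of phase `p` that strictly precede, in the temporal total
order, the earliest completed study of the next phase up. Two choices are
deliberate. First, the count is over the immediately preceding phase only,
not the union of everything below it: the pre-clinical-to-clinical bar is
the in-vivo record, which is the reading that reproduces the packaged
program's value of three. Whether positives from still-lower phases should
count is a genuinely open question; the package exposes the per-phase
counts so a user can form either reading. Second, when the next phase has
no completed study the threshold is *absent* (`NA`), not zero — the
transition has not happened, so no bar was applied.

**Orphans.** `detect_orphans()` returns studies with no incoming edge
whose phase is above the lowest-rank phase present. The exemption is
substantive: the founding studies of a program necessarily have no parents
and flagging them would be noise; a parentless phase 2 trial, by contrast,
is a study not directly justified by anything in the program.

**Monochromatic sub-trajectories.** `monochromatic_subtrajectories()`
returns, per outcome, the maximal weakly connected components of the
subgraph induced by completed studies with that outcome, listing components
of two or more studies. Weak (undirected) connectivity is the right notion
here because two negative children of a common negative parent form one
negative strand even though no directed path joins the siblings. Maximality
makes the decomposition a partition: every study with outcome *o* belongs
to exactly one maximal *o*-component (possibly a singleton, which is not
listed but is covered by the partition property tests).

**Trend.** `trend_ratio()` reports program-wide outcome counts, the
positive:negative ratio as a float (absent when there are no negatives) and
a reduced integer display form such as `"3:1"`.

**What-if planning.** `whatif()` assigns hypothetical outcomes to
contemplated studies, completes them in a copy of the graph, and recomputes
the full report; the original graph is untouched and an empty assignment is
the identity. Assignments to completed studies are errors — the package
deliberately refuses to rewrite history. No recommendation engine sits on
top of the report: choosing among contemplated options is a scientific
negotiation the representation is meant to sharpen, not settle.

**Transitive reduction.** `transitive_reduction()` computes the unique
minimal edge set of the DAG with the same reachability, the standard
distillation of a raw citation network into direct lineage. Same-report
edges are always retained: co-publication is a fact, not an inferable
citation step. Note that a curated edge list need not be reduced — the
packaged moxifloxacin table carries one shortcut edge (`x1 → x4`, implied
via `x1 → w6 → x4`), which the reduction removes; the package keeps the
curated list as-is and leaves reduction to the caller.

## Rendering

The canonical view places studies at (year, phase-rank) with the lowest
phase at the bottom. Same-year studies within a band are fanned apart by a
fixed offset (`x_offset`, default 0.25 year) following the temporal order,
so x strictly increases with that order inside every band and no two nodes
coincide. Fills are `#2ca25f` (positive), `#de2d26` (negative), `#fec44f`
(inconclusive); contemplated nodes are white with a `#3182bd` border —
named colors in the field's convention, pinned to specific hexes here for
reproducible output. Rendering is a pure function of graph and style:
repeated calls are byte-identical. Edges are straight segments (DOT output
delegates routing to the layout engine); hand-shaped splines for
publication aesthetics are out of scope. Style keys can be overridden in
code or via a `key=value` config file; only whole-line `#` comments are
recognized there, since `#` also starts hex colors.

## Fixtures and what the generator does (and does not) emulate

Two programs ship with the package. The moxifloxacin-TB table (19 studies,
1998-2009, 25 lineage links, one same-report pair) is the real, curated
program; the `"figure4"` state adds the four contemplated options `A`-`D`.
The narrative source tabulates no parents for contemplated options, so
their incoming edges here are a minimal reconstruction from the
sub-trajectory arguments made for each option (`A ← x4`; `B ← x4, w5`;
`C ← x4, x5`; `D ← x5`), placed in 2010, the year after the last completed
study. The toy program's three snapshots are built from narrative
statements rather than a table; its calendar years (2000-2005) are the
minimal assignment satisfying every stated relative ordering (`b2` after
`a2`, `g1` after `b3`, `g3` after `d1`) and the stated five- and six-year
spans. One edge of the toy program is genuinely ambiguous in its source —
whether the positive phase 2 study `d2` has both `g3` and `b3` as parents
or `g3` alone; both edges are included here, and no analytic in the
package changes its answer under either reading except the enumeration of
paths into `d2`.

`aero_generate()` produces arbitrary valid programs for property tests and
simulation. It emulates the *structural* features the analytics consume:
phases opening progressively later but overlapping, one to `max_parents`
parents per study drawn from temporally earlier studies with a preference
for the same and the immediately lower phase, occasional phase
backtracking, optional orphans and contemplated final-year studies, and
i.i.d. outcomes. Defaults mirror the packaged program's scale and outcome
mix (probabilities 0.63/0.21/0.16, the empirical 12/19, 4/19, 3/19). What
it does **not** model: outcome dependence along lineage (a child's result
is independent of its parents', unlike any real program), informative
censoring of negative studies, or multi-arm reports beyond the same-report
flag. Passing tests on generated programs therefore certify the graph
algorithms and accounting, not any claim about how real evidence
accumulates.

## Numerical and degenerate-input choices

- Empty graphs are legal everywhere: analytics return zero-filled or empty
  tables, rendering returns a valid empty document.
- All counting is integer; the only divisions are the positive:negative
  ratio (guarded against zero negatives) and the generator's probability
  checks (tolerance `1e-8` on the simplex constraint).
- Determinism: every tie in every ordering is broken explicitly (lineage,
  `seq`, id), the generator is a pure function of its seed and restores
  the caller's random stream, and rendering has no hidden state.
- Validation is fail-fast and classed (`aero_error_*`): duplicate ids,
  unknown phases, missing outcomes on completed studies, outcomes on
  contemplated studies, dangling edge endpoints, cycles (reported with a
  witness cycle), temporal violations and seq contradictions are all
  rejected at construction, so every analytic may assume a valid graph.

## Problem sizes in the test suite

The property suites run the transitive-reduction oracle comparison on 200
random DAGs of up to 12 nodes, the linear-extension check on 500 generated
programs, round-trip identity on all fixtures plus 100 generated programs,
and the generator's outcome-frequency check at 2000 studies against a
binomial 99% bound (±0.03 at p = 0.6). These sizes exercise every branch
of the algorithms while keeping the full suite in the tens of seconds;
the algorithms themselves are polynomial (the reduction is
O(V·(V+E)) via a reachability matrix) and comfortably handle programs
orders of magnitude larger than any real translational trajectory.

## Known limitations

- One outcome dimension per study; no effect sizes, no posterior scales,
  no per-endpoint multi-coding.
- Lineage must be supplied; the package will reduce a citation network but
  not build one.
- The CLI covers the packaged pipeline (validate/analyze/render/whatif/
  simulate) and deliberately emits machine formats only.
- Greek display labels are carried as UTF-8 strings; typography of
  subscripts in SVG output is plain text, not publication-grade.
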