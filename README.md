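# aerograph

Evidence graphs for translational research programs.

A drug-development program is not a linear pipeline: in-vitro and in-vivo
experiments, phase 1, 2 and 3 trials overlap, backtrack and build on one
another. Systematic review and meta-analysis summarize cross-sections of
that evidence, but say nothing about the *transitions* — how a program moved
from animals into humans, what evidential bar it applied before opening each
phase, and whether the results along a lineage of studies point the same
way. `aerograph` gives researchers, funders and trial planners a
graph-theoretic representation of the whole program and the analytics to
interrogate it.

## The model

A research program is a directed acyclic graph `G = (V, E)`:

- each node `v ∈ V` is one study report, placed by calendar year (x) and
  research phase (y, ordered `in_vitro < in_vivo < phase1 < phase2 <
  phase3` by default), colored by outcome — **positive** (green, supports
  further research), **negative** (red), **inconclusive** (yellow);
  contemplated future studies are white with a blue border and carry no
  outcome;
- each directed edge `(p, c) ∈ E` records intellectual lineage: study `c`
  (the *child*) built on the evidence of study `p` (the *parent*). Edges
  may descend in phase (a phase 2 result motivating a new animal study);
  only time must be respected. Two studies published in one report are
  joined by a *same-report* edge, drawn without an arrowhead.

Over this structure the package computes:

- **consistency** — per phase, whether ≥ 2 completed studies share an
  outcome (agreement on a similar endpoint);
- **concordance** — whether all studies along a directed lineage path share
  one outcome direction (agreement across different endpoints);
- **de-facto thresholds** — the number of positive studies a phase had
  accumulated, in the temporal total order, before the first study of the
  next phase: the implicit evidential bar for the transition;
- **orphans** — studies with no incoming lineage, i.e. not justified by
  prior evidence in the program (the founding phase is exempt);
- **monochromatic sub-trajectories** — maximal weakly connected
  same-outcome substructures ("robustly negative" strands);
- **trend** — program-wide outcome counts and the positive:negative ratio;
- **what-if planning** — assign hypothetical outcomes to contemplated
  studies and recompute everything;
- **transitive reduction** — distil a full citation network to the minimal
  edge set with the same reachability (unique on a DAG).

## Worked example

The packaged `fixture_moxifloxacin()` program contains 19 studies
(1998-2009) of moxifloxacin for drug-susceptible tuberculosis with
hand-curated lineage; the `"figure4"` state adds four contemplated options:
`A` (another in-vivo study), `B` (phase 1), `C` (phase 2), `D` (phase 3).

```r
library(aerograph)

g <- fixture_moxifloxacin("figure4")
g
#> <aero_graph> 23 studies (19 completed, 4 contemplated), 31 edges
#>   phases: in_vitro < in_vivo < phase1 < phase2 < phase3
#>   years:  1998-2010
#>   outcomes: positive=12 negative=4 inconclusive=3

aero_analyze(g)
#> <aero_report> 23 studies (19 completed, 4 contemplated), 12-year span
#>   trend: 12 positive / 4 negative / 3 inconclusive  (3:1 positive:negative)
#>   in_vitro  3 completed (+3 -0 ?0)
#>   in_vivo   5 completed (+3 -0 ?2)
#>   phase1    6 completed (+3 -2 ?1)
#>   phase2    5 completed (+3 -2 ?0)
#>   threshold in_vitro -> in_vivo: 1 positive before v1
#>   threshold in_vivo -> phase1: 3 positive before w1
#>   threshold phase1 -> phase2: 3 positive before x1
```

Reading the report: the completed program leans positive overall (12:4,
i.e. a 3:1 positive-to-negative ratio), and both the pre-clinical-to-
clinical and the phase 1-to-phase 2 transition were taken after three
positive studies in the source phase — the program's de-facto threshold.
The negative strand is visible too:

```r
st <- monochromatic_subtrajectories(g)
st$studies[st$outcome == "negative"]
#> [[1]]
#> [1] "w3" "w5" "x1" "x4"
```

a consistently and concordantly negative sub-trajectory running from a
negative phase 1 result (`w3`) into the negative phase 2 trials. Planning
is a one-liner — suppose options A and C are pursued and both come back
positive:

```r
whatif(g, A = "positive", C = "positive")$report$trend
#> # A tibble: 1 × 5
#>   n_positive n_negative n_inconclusive pos_neg_ratio ratio_display
#>        <int>      <int>          <int>         <dbl> <chr>
#> 1         14          4              3           3.5 7:2
```

`autoplot(g)` draws the canonical layered view (time on x, phase strata on
y, traffic-light colors); `aero_render(g, "svg")` and
`aero_render(g, "dot")` emit standalone documents, and
`read_study_table()` / `write_study_table()` move programs in and out of
CSV/TSV/JSON study tables. A command-line front end with
`validate`/`analyze`/`render`/`whatif`/`simulate` subcommands ships as
`system.file("cli", "aero.R", package = "aerograph")`.

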