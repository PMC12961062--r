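---
title: "Methods: modeling, classifying and mapping branched-case decision-making"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling, classifying and mapping branched-case decision-making}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(branchmap)
```

## The model

A branched case study is modeled as a directed acyclic graph. Decision
nodes are either *treatment* prompts (a menu of clinical options, drawn
as circles) or *hydration* prompts (fluid-management choices, drawn as
diamonds); *endpoint* nodes (squares) terminate the case. Every edge is
one verbatim answer option and carries a classification:

* **expert** — the option the consulted specialists chose; every decision
  node has exactly one expert edge;
* **tolerable** — not the expert option, but not immediately harmful to
  the simulated patient;
* **incorrect** — an option that would harm the patient.

Following the unique expert edge from the start node until an endpoint
yields the **expert route**; its terminal node is the **FINISH** node,
the successful outcome. Several options may route to one endpoint
("endpoint collapsing"), so the graph is a DAG rather than a tree.
Directed cycles are rejected outright (`CYCLE` validation error): the
cases are time-ordered, so a cycle indicates an authoring mistake.
Rejoins to the expert route are legal and expected — they are exactly the
"erred but returned" behavior the analysis wants to surface.

Node identifiers are free-form strings; the originating survey-platform
section number, if any, is irrelevant to the analysis and simply not
modeled. The hydration-then-treatment or treatment-then-hydration order
within a timepoint is whatever the case file declares: the declared node
and edge structure is authoritative.

## Replay

Response logs arrive wide: one row per submission, one column per form
question, blank cells for branches a respondent never saw. Replay walks
the graph from the start node, reading the recorded answer at each
node's question key and following the matching edge. Matching is exact
after trimming and collapsing internal whitespace — forms export verbatim
option text, so fuzzy matching would only mask authoring errors; an
answer matching no option at the visited node is a hard
`UNMATCHED_OPTION` error rather than a silent skip.

Three anomalies are reported without failing: `MISSING_ANSWER` (replay
stops before an endpoint; the path is marked incomplete),
`ORPHAN_ANSWER` (a recorded answer for a question the replayed route
never visits — the signature of a survey back-button that cannot be
disabled), and `MULTI_ANSWER` (several recorded values for one visited
question; the last submission wins, mirroring how a re-answered form
overwrites state). Incomplete paths are retained by default and excluded
from endpoint and route tallies; a strict mode drops them. Duplicate user
ids are kept as separate records with a `#2`, `#3`, ... suffix — the
toolkit never silently merges submissions.

## Cumulative behavior classification

The expert route's nodes are the **checkpoints** — the rows of the
behavior table. Let *D* be a user's total decision count and *k* a
0-based checkpoint index. The user's status at checkpoint *k* is computed
from their first min(*k*, *D*) decisions:

* `incorrect` if any of those edges is classified incorrect (absorbing:
  once harmful, always harmful);
* `expert` if they are exactly the first *k* expert-route edges;
* `tolerable_only` otherwise.

At *k* = 0 every user is expert (no decision made yet), and a user who
stopped deciding — at an early endpoint or an unanswered prompt — is
frozen at their terminal classification for all later rows. This
decision-count alignment was chosen over a case-clock (hours-based)
alternative because it requires no timepoint bookkeeping for off-route
nodes and guarantees the table's structural identities directly:
tolerable + incorrect = N on every row, expert ≤ tolerable, expert
non-increasing and incorrect non-decreasing down the rows.

Reported **tolerable** counts include expert users ("expert and/or
unharmful so far"), not just those who erred and returned; that is the
definition under which the row arithmetic closes, and the stricter
"erred but returned" reading is recoverable as tolerable − expert.

Percentages are rounded **half-up** to one decimal (14/54 → 25.9,
28/54 → 51.9, 53/54 → 98.1); banker's rounding would flip ties like
6.25% the other way. Exports print exactly one decimal. An empty cohort
yields an N = 0 table with 0.0 percentages and a warning rather than an
error, so group comparisons with an empty stratum degrade gracefully.

## Maps

`render_dot()` emits Graphviz DOT text; rendering to an image is
delegated to any DOT processor and is deliberately outside the package's
contract, which ends at deterministic text (sorted node and edge
emission, fixed number formatting — identical inputs give byte-identical
output, making golden-file testing trivial).

Layout conventions: the expert route is pinned to the top rank in route
order, incorrect endpoints to the bottom rank, other nodes float between;
node shape encodes kind; a key subgraph names every node. Edge pen width
is linear in the cohort fraction traversing the edge,
`w_min + (w_max − w_min)·fraction`, defaults 1 and 8 — the published
convention says only that weight grows with frequency, and a linear map
keeps equal traffic differences equally visible.

Edges are colored by a **taxonomy of the edge**, not of the users on it —
a single drawn line can carry users of mixed status, so per-user coloring
is not well defined at the edge level. Precedence: incorrect-classified
edges are magenta; the expert-route edges black; edges whose source is
off the expert route but whose destination is on it are teal rejoins;
everything else is an orange deviation; and any edge no one traversed is
gray regardless of taxonomy. (Orange-deviation / teal-rejoin rather than
a single deviation color distinguishes more behavior and is the default;
the palette is fully configurable through `map_style()`.) A
tolerable-classified edge that happens to connect two consecutive
expert-route nodes — endpoint collapsing makes this possible — is
deliberately styled as a deviation, not as expert: classification, not
geometry, decides.

## The synthetic cohort generator

`simulate_cohort()` emulates a cohort of respondents as independent
per-decision mixtures: at each decision node a user draws a class from
(p_expert, p_tolerable, p_incorrect), then one option uniformly within
that class. At nodes missing a class, the mixture renormalizes over the
classes present. The default profile (0.85, 0.08, 0.07) describes a
moderately skilled cohort — mostly expert choices, occasional harmless
detours, rare harmful ones — chosen so that a 54-user cohort displays the
qualitative shape seen in real cohorts: a gradual expert decay and a
substantial minority reaching harmful endpoints. Two study arms are
emulated as two profiles differing in p_expert; no claim is made that
real cohorts are generated this way.

Under this model the probability of still being fully expert at
checkpoint *k* is p_expert^*k*, which gives a closed-form calibration
target: the observed expert fraction at each checkpoint must sit within
three binomial standard errors of p^*k*, and the maximum-likelihood
estimate of p_expert (the expert fraction over all decision draws) must
recover the input. These checks hold only because every decision node of
the demo case offers all three classes; that is why its hydration menus
have three options (increase / maintain / decrease fluids — the last
being the harmful one during high-dose methotrexate, where aggressive
hydration is protective) rather than a bare yes/no.

Reproducibility discipline: each user's draws come from a private stream
seeded by a fixed affine map of (cohort seed, user index). Identical
specs give byte-identical logs, and enlarging a cohort never reshuffles
earlier users.

What the generator does **not** emulate: learning within a case, answer
timing, fatigue, or any correlation between a user's successive choices
beyond the absorbing endpoint structure. Passing tests on simulated
cohorts therefore demonstrate the *pipeline's* correctness — replay
fidelity, table arithmetic, map determinism — not the behavioral realism
of any particular human cohort.

## The demo case

`make_demo_case(n_treatment_stages = 5, options_per_menu = 8)` builds a
structurally faithful stand-in for a high-dose methotrexate monitoring
scenario: an expert spine alternating treatment and hydration prompts at
6-hour-grid timepoints (24 h, then 42–60 h, FINISH at 66 h), a tolerable
detour menu between consecutive spine timepoints that rejoins at the next
one, and per-stage adverse endpoints that collapse all harmful options of
a stage. Five stages give an expert route of 11 checkpoints (five
treatment, five hydration, FINISH); eight options per treatment menu sit
at the bottom of the 8–14 range observed in real cases, keeping the demo
small. The clinical option texts are flavor, not modeled content.

## Numerical and degenerate-input choices

* Duplicate option text at one node is reported as a `DUP_OPTION`
  warning; replay then takes the first declared edge, deterministically.
* Treatment menus outside 8–14 options warn (`MENU_SIZE`) but never
  reject — small menus are legitimate in minimal or teaching cases.
* Validation always returns a full report; only downstream operations
  refuse a case whose report contains errors.
* Serialization sorts nodes by id and edges by (from, option, to) with
  locale-independent (radix) ordering, so case files and DOT output are
  byte-stable across platforms.
* Seeds are kept below 2^31 − 1 throughout.

## Problem sizes used by the test suite

The suite exercises 200 randomly shaped case/cohort pairs for the
structural invariants, exhaustive path enumeration on cases with at most
200 root-to-leaf paths for the replay oracle, and a 2000-user cohort for
simulator calibration; the full run completes in well under a minute.
These sizes were chosen as the smallest at which the stochastic checks
have comfortable statistical headroom (three standard errors).

## Known limitations

* Group comparisons are descriptive; no inferential statistics are
  attached to between-group differences.
* The XLSX reader is a convenience for spreadsheet exports; CSV/TSV are
  the canonical dialects.
* The checkpoint-alignment rule counts the hydration decision itself at
  its own row; an hours-based alignment would differ for users parked at
  off-route timepoints, and is not implemented.
* DOT output targets the Graphviz dialect; other graph-description
  languages are out of scope.
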