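# branchmap

Tools for analyzing how learners navigate **branched clinical case
studies** — "choose your own adventure" (CYOA) style assessments, also
known as diagnostic branched trees, in which every choice routes the
learner to a different continuation or ending. Instructors and
medical-education researchers use this format to probe multi-step clinical
reasoning, but evaluating the resulting tangle of routes is hard:
responses land in a sparse wide spreadsheet, and the interesting signal is
*where* cohorts leave the expert path, whether they recover, and which
endings they reach.

`branchmap` turns that raw material into numbers and pictures:

* **Case model** — a branched case is a directed acyclic graph. Nodes are
  treatment prompts, hydration prompts, and endpoints; edges are the
  verbatim answer options, each classified *expert* (the specialists'
  choice — exactly one per decision node), *tolerable* (off the expert
  path but not immediately harmful), or *incorrect* (harmful). Following
  the unique expert edge from the start node defines the **expert route**
  ending at the **FINISH** node. Cases live in a plain-text (YAML) file
  with stable round-trip serialization.
* **Replay** — wide-format response logs (one column per form question,
  blank cells for unvisited branches) are replayed answer-by-answer into
  each user's path through the graph, with anomaly reporting for
  back-button artifacts, missing answers and duplicate submissions.
* **Behavior classification** — at every checkpoint *k* along the expert
  route, a user's cumulative status is computed from their first
  min(*k*, *D*) decisions: `incorrect` once any harmful edge has been
  crossed (absorbing), `expert` while the decisions are exactly the first
  *k* expert-route edges, `tolerable_only` otherwise. Cohort tables report
  n and % per checkpoint, where reported "tolerable" counts everyone not
  yet incorrect (experts included), so tolerable + incorrect = N on every
  row, expert counts are non-increasing and incorrect counts
  non-decreasing.
* **Maps** — deterministic Graphviz DOT output: expert route pinned to the
  top row, incorrect endpoints on the bottom row, circles/diamonds/squares
  for treatment/hydration/endpoint nodes, edge width proportional to the
  fraction of the cohort traversing the edge, and colors by edge taxonomy
  (black expert, orange deviation, teal rejoin, magenta incorrect, gray
  untraveled). Side-by-side group comparisons share one layout.
* **Simulator** — a stochastic cohort generator: each synthetic user draws
  a choice class per decision from a mixture (p_expert, p_tolerable,
  p_incorrect), then an option uniformly within the class. Logs are
  byte-reproducible from a seed, so the whole pipeline is testable without
  participant data.

## Worked example

```r
library(branchmap)
case <- make_demo_case()          # 5 treatment stages, 8-option menus
case
#> Branched case 'demo_mtx_s5m8': High-dose methotrexate monitoring (demo case)
#>   21 nodes (6 endpoints), 95 classified edges
#>   expert route (11 checkpoints): T1 -> H1 -> T2 -> H2 -> T3 -> H3 -> T4 -> H4 -> T5 -> H5 -> FINISH

sim <- simulate_cohort(case, n_users = 54, seed = 7,
                       profile = behavior_profile(0.85, 0.08, 0.07),
                       group_labels = c("SOC", "MTX"))
behavior_table(case, sim$paths)
#> Cohort behavior at 11 checkpoints (N = 54 users)
#>  node_id      label n_tolerable pct_tolerable n_expert pct_expert n_incorrect pct_incorrect
#>       T1       24Hr          54         100.0       54      100.0           0           0.0
#>       H1 24Hr fluid          52          96.3       47       87.0           2           3.7
#>       T2       42Hr          47          87.0       41       75.9           7          13.0
#>       ...
#>   FINISH       66Hr          24          44.4       10       18.5          30          55.6
```

Each row is one expert-route checkpoint. At the 42-hour treatment
decision, for example, 47 of 54 users (87.0%) had not yet made a harmful
choice, 41 (75.9%) had made only expert choices, and 7 (13.0%) had already
crossed an incorrect edge; by FINISH only 10 users (18.5%) stayed on the
expert route end-to-end, while 30 (55.6%) reached a harmful ending.
Endpoint and route tallies come from the same paths:

```r
endpoint_distribution(sim$paths)
#>   node_id count
#> 1  FINISH    24
#> 2      E5     9
#> ...
head(route_frequency(sim$paths), 2)
#> 1 T1 -> H1 -> T2 -> H2 -> T3 -> H3 -> T4 -> H4 -> T5 -> H5 -> FINISH    18
#> 2                                                     T1 -> H1 -> E1     5
```

A traffic-weighted map (and per-group maps via `compare_groups()` +
`render_comparison()`):

```r
writeLines(render_dot(case, edge_usage(case, sim$paths)), "map.dot")
# then e.g.:  dot -Tsvg map.dot -o map.svg
```

The same workflow is scriptable from a shell via the bundled CLI
(`system.file("cli", "branchmap", package = "branchmap")`):

```sh
branchmap simulate --demo --n 54 --seed 7 --out-dir out/
branchmap summarize out/demo_mtx_s5m8.yaml --responses out/demo_mtx_s5m8_cohort.csv --out-dir out/
branchmap map out/demo_mtx_s5m8.yaml --responses out/demo_mtx_s5m8_cohort.csv --out-dir out/
```

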