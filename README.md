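# antnav — decentralized insect navigation simulator

`antnav` simulates a foraging insect (desert ant, honey bee) steered by a
bank of **independent procedural memories** instead of a cognitive map:

* a **path integrator** that accumulates every walked displacement into a
  compass-referenced *current vector* **C**, reset only on nest entry,
  and per-source *reference vectors* **R**ₛ stored at the moment food was
  found; its output is the direction of **R**ₛ − **C** (with the
  homeward leg realized by gating **R** to zero, not by sign arithmetic);
* **route landmarks**: circular catchments that, once entered, emit a
  stored compass *local vector* whose salience decays 1 → 0.5 → 0 over
  15 steps;
* **place landmarks** (snapshots) at nest and feeders: three stored
  goal-to-signpost vectors, continuously matched against the current
  view so the mean correction points at the goal;
* a **biased random-turn generator** (uniform turns on [−0.3, 0.7] rad);
* a recurrent **motivation network** of four winner-take-all pairs
  (stay/forage, sourceA/sourceB, outbound/inbound, search on/off) that
  gates every memory by behavioural context;
* **feedforward lateral inhibition** (weight −0.4; place inhibits route,
  never the reverse; integrator and random generator scaled by 0.2 and
  silenced by any active landmark) followed by a weighted sum of unit
  vectors: the resultant's angle is the walking direction, at a fixed
  10 length units per step.

No procedure ever reads two stored vectors together, yet novel
shortcuts between two known feeders, homing after passive displacement,
and an ever-widening area-concentrated search all emerge. The package
ships the canonical in-silico experiments, a randomized scenario
generator, YAML scenario files, trajectory logs, search-path analyses
(distance series, radial density profiles) and plotting, plus a thin
CLI (`inst/cli/antnav.R`).

Who it is for: computational neuroethologists and robotics researchers
who want a compact, fully reproducible reference implementation of
vector-plus-landmark navigation with decentralized action selection.

## Worked example

A landmark-guided trip to feeder A and back:

```r
library(antnav)
sc  <- scenario_route_trip("A")
log <- run_scenario(sc)

max(log$step)
#> [1] 94
table(log$winner)
#>    fLMA     hLM    none      PI rA_out1 rA_out2 rA_out3
#>       2       2       1      55      11      11      13
```

The agent leaves the nest under path-integrator control (`PI`), is
handed from route landmark to route landmark (`rA_out1` → `rA_out2` →
`rA_out3`, 11–13 steps each: the 15-step salience decay bounds each
hand-over), is funnelled in by the feeder snapshot (`fLMA`), finds food
at step 52, and returns by pure path integration — crossing an outbound
catchment that is ignored because the outbound motivation is off — until
the nest snapshot (`hLM`) takes over. `plot_trajectory(log, sc)` draws
the map with all catchment circles.

The two-feeder shortcut — feeder A emptied, the motivation network hands
the goal to B, and steering by **R**_B − **C** alone reproduces the
direct A→B course without any B−A subtraction:

```r
sc2  <- scenario_shortcut()
log2 <- run_scenario(sc2)
i <- which(grepl("food_absent", log2$events))
log2$heading[i + 1]                          # -1.572 rad
angle_between(sc2$food$A$pos, sc2$food$B$pos) # -1.571 rad (due south)
```

Emergent area-concentrated search of ten zero-vector releases — looping
paths whose per-unit-area radial density peaks at the release point:

```r
prof <- density_profile(batch_run(scenario_search(), seeds = 1:10),
                        origin = c(0, 0))
round(prof$density[1:4], 3)
#> [1] 0.233 0.175 0.132 0.093
```

Other ready-made experiments: `scenario_route_trip("B")` (local vector
runs off, integrator resumes), `scenario_displaced_forager()` (capture
at the feeder, release elsewhere: home-vector flight, search, landmark
chain home), `scenario_zero_vector_release()` (released at the empty
feeder with an empty integrator: heads along vector B, not B−A — the
experimentally testable signature that separates this architecture from
a map), and `random_scenario(seed)`.

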