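---
title: "Decentralized insect navigation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decentralized insect navigation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(fig.width = 6, fig.height = 6)
library(antnav)
```

## The question the simulator addresses

Desert ants and honey bees navigate over enormous distances with a toolbox
of simple mechanisms: a path integrator that keeps a running, compass-
referenced tally of displacement (the *current vector*); stored
nest-to-food vectors (*reference vectors*); landmark memories that either
define places (nest, feeder) or are sprinkled along routes; and a
systematic search that kicks in when the integrator says "you are there"
but the goal is not in sight. A long-standing debate asks whether these
memories are fused into a *cognitive map* — a common spatial
representation in which stored vectors can be combined arithmetically —
or whether a fully decentralized bank of independent memories, each
usable only in the motivational context in which it was acquired,
suffices to produce the observed behaviour, including novel shortcuts.

`antnav` implements the decentralized architecture as an agent-based
simulator and reproduces its key in-silico experiments: landmark-guided
round trips, the two-food shortcut, homing after passive displacement,
the zero-vector release prediction, and emergent area-concentrated
search. The architecture contains **no operation that reads two stored
vectors at once**; every behaviour below falls out of gating, competition
and vector summation of independent procedures.

## Architecture

Each behavioural step runs the same pipeline:

1. **Sense events.** Nest departure/entry and food found/missing at the
   motivationally targeted source (detection radius `eps_goal`, 10 length
   units = one step).
2. **Motivation relaxation.** Eight units in [0, 1] form four mutually
   inhibitory pairs — `stay`/`forage`, `sourceA`/`sourceB`,
   `outbound`/`inbound`, `ACSon`/`ACSoff` — with `forage` exciting the six
   lower units. Events map to additive drives (`left_nest` to `outbound`,
   `food_found` to `inbound`, a failed visit to a negative drive on the
   disappointed source unit); the summed landmark salience drives
   `ACSoff` and the search gain drives `ACSon`. The network relaxes to an
   attractor within the step; relaxed pairs have a single winner.
3. **Gated memory outputs.** Every procedural memory emits a compass
   angle and a salience, and emits nothing unless its gating motivations
   are above threshold (0.5):
   * *Path integrator*: direction of (gated reference − current vector),
     normalized to length 1; length 0 within `eps_pi` = 1 unit of the
     goal (the zero-vector state). Inbound, the gated reference is the
     zero vector — the homeward sign reversal is implemented by gating,
     not arithmetic.
   * *Route landmarks*: entering the catchment (radius 20) samples the
     stored local vector once at salience 1; salience then decays 0.05
     per step for ten steps, holds at 0.5 for five more, and drops to 0 —
     so a landmark guides for at most 15 steps before the integrator
     resumes, and a newly seen landmark overrides a fading one.
   * *Place landmarks* (snapshots): inside the catchment (radius 25) the
     element continuously compares stored goal-to-signpost vectors with
     the currently seen agent-to-signpost vectors; the mean correction
     points at the goal, emitted at salience 1 (0 on arrival).
   * *Random generator*: previous heading plus a uniform turn from
     [−0.3, 0.7] rad (counter-clockwise bias, mean +0.2), scaled by the
     `ACSon` activation.
4. **Arbitration.** Saliences compete in two separate one-shot
   feedforward lateral-inhibition pools (weight −0.4, rectified at 0):
   the landmark pool, where place elements inhibit route elements but not
   vice versa, and the integrator/search pool. The integrator and the
   random generator are scaled by 0.2 before competing, so any active
   landmark dominates both; additionally any nonzero landmark salience
   zeroes the integrator outright. The surviving weighted unit vectors
   are summed; the resultant's angle is the commanded heading (previous
   heading kept if the resultant is shorter than `eps_dir`).
5. **Motor step.** 10 length units along the heading; speed is fixed and
   not under network control. The displacement — and only actual walking,
   never experimenter transport — updates the current vector, which is
   reset exactly once per trip, on nest entry.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `step_length` | 10 | length units | fixed forward speed per step |
| `eps_goal` | 10 | length units | nest/food detection radius |
| `eps_pi` | 1 | length units | integrator zero-state radius |
| route catchment | 20 | length units | trigger radius of route landmarks |
| place catchment | 25 | length units | trigger radius of snapshots |
| decay schedule | 1 − 0.05k; 0.5; 0 | salience | route-landmark forgetting |
| `b` | −0.4 | — | lateral inhibition weight |
| `pi_acs_scale` | 0.2 | — | PI/search down-scaling before summation |
| `d1, d2` at onset | 3.3, 20 | length units | search-gain breakpoints |
| `d1, d2` saturated | 33, 200 | length units | breakpoints after long search |
| `t_max` | 500 | steps | time for breakpoints to reach maxima |
| turn interval | [−0.3, 0.7] | rad | biased random heading change |

Catchment radii, `eps_goal` and `t_max` are package fixtures (the model
description fixes the other constants but not these); all are
per-scenario configurable. The two-food world geometry (nest at the
origin, sources at (350, ±250), twelve route landmarks in four gated
triples) is likewise a hand-authored fixture chosen so that each
canonical experiment exercises its intended mechanism — the coordinates
are not measurements.

## Motivation-network dynamics: design choices

The published description fixes the network's *qualitative* contract —
pairwise winner-take-all with persistence, context gating, and (for the
doubly motivated forager) oscillation under habituating inhibition — but
not its connection weights or update rule. The implementation uses
`a' = (1 − r)a + r·clip01(W a + drive)` with damping `r = 0.5`. Damping
changes no fixed point but removes the period-2 flip-flop that a fully
synchronous update of a mutually inhibitory pair can enter. Weights:
self-excitation 1.0 for `stay`/`forage`; 0.8 for the goal and direction
units, which together with the +0.3 excitation from `forage` latches a
won decision while foraging lasts yet lets it collapse when `forage`
stops backing it; 0 for `ACSon`/`ACSoff`, which must follow their
sensory drives rather than latch (a latched `ACSon` would make search
permanent); pair inhibition −1.2; child-to-`forage` feedback +0.1. The
summed landmark salience is doubled before driving `ACSoff` so that a
single fresh landmark (salience 1) reliably beats a saturated `ACSon`
rather than tying with it.

Decisions are deliberately hysteretic: overturning an entrenched unit
requires a drive of event magnitude (≥ 1, the scale at which the world
engine delivers stimuli). Exactly symmetric drives relax to a symmetric
fixed point, which `relax_motivation()` reports as a tie; the world
engine breaks potential ties with seeded noise of magnitude 1e−6 added
to drives at event time.

With habituating inhibition (`h' = h + α·a_pre(1 − h) − β·h` per
connection, defaults α = β = 0.03), a pair whose two units are both
driven alternates its winner — three sign changes of the activation
difference within 200 steps under the defaults — and never settles
numerically. The alternation amplitude decays towards a coexistence
state in the long run; the variant is exposed for the
"feeder-directed forager" interpretation but is not used by any
canonical scenario.

## Emergent search and the reciprocal gate

No search routine is programmed. The search gain
`f(d, t)` is 1 while the integrator-reported goal distance `d` is below
`d1(t)`, ramps linearly to 0 at `d2(t)`, with both breakpoints growing
linearly from (3.3, 20) to (33, 200) over `t_max` steps of searching
time. `f` drives `ACSon`, whose activation multiplies the random
generator's output — and, reciprocally, scales the integrator's salience
by `1 − ACSon` within the integrator/search pool. Near the phantom goal
the random walk therefore governs alone; further out the two blend; and
beyond the gain region the integrator steers straight back. The
resulting trajectory is a looping, origin-centred search whose
excursions widen as the breakpoints grow, whose per-unit-area radial
density is unimodal and peaked at the origin, and which never strays
more than one step beyond `d2(t)`. Without the reciprocal gate (i.e.
with the integrator held at salience 0.2 throughout, the naive reading
of the down-scaling rule) the equal-weight blend contracts the walk onto
the release point and the search area never grows; the gate is the
package's concretization of "random selection governs, then blending,
then path integration controls completely". The searching timer runs
while `ACSon` is above threshold and resets on nest entry or landmark
perception. Search-area scaling with the length of the preceding
outbound journey is deliberately not modelled.

The gain's distance argument is the goal distance reported by the
integrator, |gated reference − current|. For an inbound (homing) agent
this equals the current-vector length exactly; using the integrator's
goal distance extends the same mechanism to an agent whose outbound
integrator has run out at an empty location.

## What the generator emulates — and what it does not

Scenario worlds are deliberately minimal: a featureless plane, exact
compass, noise-free odometry, circular all-or-nothing catchments, and
memories installed "by hand" (learning is out of scope). Passing tests
therefore demonstrate properties of the *architecture* — gating,
competition, emergence — not robustness to sensory noise, view-matching
ambiguity, or integrator drift of real insects. In particular the
integrator is error-free, so zero-vector states are produced by
experimenter manipulations (displacement, goal removal) rather than by
accumulated error, and place-landmark matching is exact rather than
image-based. `random_scenario()` draws randomized worlds of the same
family (1–2 sources, 0–3 route landmarks per leg spaced within
local-vector reach, snapshots at nest and sources) for property
testing.

## Numerical choices and degenerate inputs

* Zero-length vector sums return angle 0 with length 0; callers treat
  lengths below 1e−9 as "no direction", and the motor stage then keeps
  the previous heading.
* A coinciding position pair has no bearing; `angle_between()` signals a
  classed error rather than returning an arbitrary angle.
* Motivation relaxation runs to an activation (and, with habituation,
  habituation) change below 1e−6, capped at 200 iterations per
  behavioural step; the cap is never reached by the canonical runs
  except transiently at event steps.
* Route-landmark re-entry resets the decay counter; a decayed-out or
  motivationally gated-off element deactivates entirely.
* Each run owns a single seeded random stream, isolated from R's global
  RNG; the stream state lives in the world value, so a world copied
  mid-run resumes bit-for-bit.
* The world state is a plain R value; checkpointing is assignment.

## Problem sizes used by the test-suite experiments

Canonical round trips run ~100 steps; the displaced-forager experiment
~450 steps; the emergent-search analyses use 10 replicate zero-vector
runs of 1,000 steps each (bin width 10, the step length, for radial
profiles); distribution checks on the turn generator use 10,000 draws.
These sizes match the scales at which the simulated experiments were
described and keep any analysis reproducible in seconds.

## Known limitations

* The motivation weights are this package's own parameterization of the
  stated qualitative contract, not published values; other weight sets
  satisfying the same contract exist.
* The habituation oscillation alternates with decaying amplitude rather
  than as a clean limit cycle; rates are exposed for exploration.
* Route-landmark "vector length" is realized purely through the 15-step
  salience schedule; no metric run length is stored.
* One nest, one agent, two food sources; no pheromones, terrain,
  obstacles, or 3-D flight geometry.

## A worked example

```{r example, eval = FALSE}
library(antnav)
sc <- scenario_route_trip("A")
log <- run_scenario(sc)
plot_trajectory(log, sc)
table(log$winner)

search <- batch_run(scenario_search(), seeds = 1:10)
plot(density_profile(search, origin = c(0, 0)))
```
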