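---
title: "An index-free model of multiple object tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An index-free model of multiple object tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motrack)
```

## The task and the model

Multiple object tracking (MOT) asks an observer to follow $n$ designated
targets among $m$ visually identical distractors while all objects move
unpredictably. Tracking accuracy is $k/n$ — the fraction of the $n$
reported objects that are true targets — and identification (ID)
accuracy is $p/n$ — the fraction of reports that also carry the correct
start-of-trial label. Classic explanations posit pre-attentive indexes
("pointers") that stay bound to objects. The model implemented here
dispenses with indexes: it maintains nothing but

* an **object map** $O^t$: a retinotopic grid (one cell per display
  pixel by default) counting how many objects occupy each cell at time
  $t$;
* an **attention map** $A^t$: the multiset of *attended locations*
  $a_1 \dots a_n$, cells the observer currently treats as "where a
  target is". Attended locations are distinguishable only by their
  coordinates;
* a capacity-two **unitary buffer** $U^t = [u^t, v^t]$: the last two
  locations of the single attended thread currently receiving unitary
  processing, which is the model's only access to velocity;
* an ordered **label sequence** $q_1 \dots q_n$ for identity reports.

Tracking is the maintenance of $A^t$ against $O^t$. Updates are a
constrained resource: ticks arrive at a total rate $f_{loc}$ (Hz) shared
across all attended locations, and each tick refreshes exactly one
location $a_i$:

1. if cell $a_i$ is still occupied, the location is confirmed in place;
2. otherwise a nearest-object search relocates it. The search starts at
   the velocity-extrapolated cell $a_i + (u - v)$ when $a_i$ is the
   unitary-locked thread with a full buffer, else at $a_i$ itself;
3. the search expands outward ring by ring and aborts at the
   *nearest-object bound* `nob`; on failure the location is dropped for
   the rest of the trial.

An attended location therefore coincides with an object only
immediately after its own tick; between ticks it goes stale in
proportion to $n / f_{loc}$, which is how the accuracy cost of
additional targets arises.

The unitary thread is chosen at most every $1/f_u$ seconds by the
**confusion ratio** $c_i = (d_1/d_2)^{c_e}$, where $d_1, d_2$ are the
distances from $a_i$ to the first- and second-nearest objects: the
ratio approaches 1 when a competitor is about as close as the tracked
object. Locations are selected with probability $c_i / \sum_j c_j$;
with $c_e = \infty$ the most confusable location is chosen
deterministically (lowest index on ties). Switching threads discards
the buffer.

## Identity maintenance

Identities are carried outside the map: the label sequence is kept
sorted by the locations' $(x, y)$ order (x ascending, then y, then
thread index for exact ties). When a tick relocates a thread, the moved
label is re-inserted at its new sorted rank with probability
$f_{corr}$, else left stale. At trial end the surviving locations are
sorted once more and the $k$-th label attaches to the $k$-th location;
each surviving location then claims the nearest unclaimed object
(greedy, ascending distance).

Two anchor behaviours follow. With $f_{corr} = 0$ the sequence never
changes, so any change in the targets' spatial order produces label
errors while tracking can remain perfect — the tracking/ID
dissociation. With $f_{corr} = 1$ the sequence always mirrors the true
order of the attended locations, so a label error can arise only from a
tracking confusion. In the minimum-separation regimes (objects never
within `min_distance`), tracking failures are drops or
distractor-confusions, and per-trial ID accuracy *equals* tracking
accuracy exactly — the index-like limit. When objects may cross paths,
a thread can migrate onto a *different target*; such a claim counts as
tracked (the reported object is a target) but carries the wrong label,
so in crossing-allowed regimes ID accuracy at $f_{corr} = 1$ can fall
below tracking accuracy at the level of single trials. The package
scores against ground truth and reports what the mechanism actually
does; the identity-equals-tracking property is asserted in the tests in
the separation regime where it genuinely holds.

## Stimulus dynamics

Three regimes generate trials, all seeded and bit-reproducible:

* **Constant speed with repulsion.** Objects move at exactly `sigma`
  pixels per update. Any object within `min_distance` of a neighbour or
  wall adopts the heading of the net inverse-square repulsion
  $\left(\sum_j \Delta x_j / d_j^2,\ \sum_j \Delta y_j / d_j^2\right)$
  (walls contribute at their perpendicular foot), resolved with the
  two-argument arctangent; an exactly balanced (zero) net vector keeps
  the current heading.
* **Ornstein–Uhlenbeck (OU).** Per axis,
  $v_t = \lambda v_{t-1} - k\,(x_{t-1} - x_c) + w_t$,
  $x_t = x_{t-1} + v_t$, with $w_t \sim N(0, \sigma)$ (σ a standard
  deviation), $k = 0.0005$, $\lambda = 0.9$, positions measured
  relative to the arena centre $x_c$ so the spring keeps objects
  in-window; walls reflect position and velocity. The *constrained*
  variant always updates velocities but applies a position update only
  if the mover stays at least `min_distance` from every other object
  (evaluated object-by-object in index order, for determinism).
* **Shell game.** Objects sit on a ring of equally spaced stations; in
  each phase one random adjacent-station pair swaps along a half-circle
  arc about the pair midpoint while others hold, so the spatial sort
  order changes repeatedly although all separations stay at or above
  `min_distance` (120 px, 4 degrees of visual angle, by default). The
  ring radius is the smallest (plus 10%) satisfying both the chord
  constraint and the clearance inequality between the swept circle and
  the bystander stations, so the separation holds by construction; the
  generator still audits every frame, and additionally rejects any
  candidate that the screening tracker ($f_{corr} = 0$) labels
  perfectly, since such a trial could not dissociate identity from
  tracking. The exact arc geometry is an implementation choice: a
  half-turn about the pair midpoint is the smallest motion that swaps
  two objects' order at provably constant separation, with arc speed
  $2\sigma/\mathrm{chord}$ so moving objects travel σ px/update.

### Unit conversions

Empirical speeds ($d$ degrees/s over a window of $\theta$ degrees,
grid side $s$, update rate $\eta$) convert by equating window-crossing
times: $\sigma = s d / (\eta \theta)$ for constant speed. For OU
dynamics the per-axis mean absolute displacement per update is, in the
stationary regime and with the weak spring,
$E|v_x| = \sigma \sqrt{2 / (\pi (1 - \lambda^2))} \approx 1.83\,\sigma$
for $\lambda = 0.9$ — one update covers about 1.8 σ pixels along the
crossing axis, hence $\sigma = 0.555 \cdot s d / (\eta \theta)$.
`ou_displacement_factor()` recomputes this factor by simulation from
zero initial velocity (the v₀ = 0 transient is included; with at least
10⁵ updates it shifts the mean by well under 1%). Note the crossing
argument is one-dimensional: the 2-D Euclidean step length is π/2
times larger and is *not* the quantity the 0.555 conversion inverts.

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `f_loc` | Hz | 30 | total attention-update rate, shared across locations |
| `f_u` | Hz | 10 | unitary re-lock rate (100–300 ms dwell → 3–10 Hz) |
| `c_e` | – | ∞ | confusion exponent; ∞ = deterministic most-confusable |
| `nob` | cells | ∞ | search bound; failures drop the location |
| `f_corr` | prob. | 0 | per-relocation identity re-sync probability |
| `sigma` | px/update | – | speed (constant) or velocity-noise sd (OU) |
| `eta` | Hz | 30 | environment update rate |
| `min_distance` | px | 0 | separation constraint / repulsion radius |

Scheduling is round-robin by default; `"crowding_priority"` draws the
ticked location from the confusion ratios instead. The unitary lock is
always confusion-driven.

## Numerical and design choices

* **Grid conventions.** Cells are 0-based `(row, col) = (floor(y),
  floor(x))`; one cell = one display pixel unless overridden.
* **Search tie-breaks.** Rings are Chebyshev shells scanned row-major;
  among equal Euclidean distances the earliest cell in scan order wins.
  This makes the search deterministic and exactly checkable against a
  brute-force oracle, which the test suite does on a thousand random
  maps.
* **Tick interleaving.** Ticks are dispensed through a fractional
  accumulator (`f_loc / eta` per frame), spread evenly within the
  frame, so both `f_loc > eta` (28 Hz on a 2.5 Hz stimulus) and
  `f_loc < eta` (30 Hz on a 60 Hz stimulus) work.
* **Unitary buffer.** The buffer shifts only on ticks that actually
  relocate the locked thread; a confirmed-in-place tick leaves it
  untouched (the thread's last observed displacement remains the
  velocity estimate). A dropped locked thread clears both buffer and
  lock. Re-selecting the incumbent retains the buffer and does not
  restart the dwell clock.
* **Response protocol.** The sources do not specify how surviving
  locations become reports; the package resolves claims greedily by
  ascending distance with each object claimable once, dropped locations
  yielding no claim, and scores $k$ as the number of distinct targets
  claimed.
* **Ten-second dissociation runs.** The tracking/ID dissociation
  configuration (4 targets among 8 objects, OU, σ = 1.25,
  $f_{corr} = 0$, `f_loc` 28 Hz, `nob` ∞) is run at η = 30 Hz with 300
  updates (10 s) on a 720×720 grid: the OU parameterization and the
  σ ≈ 1.25 scale both come from the study that used 30 updates/s on a
  720-pixel window, and at the 2.5 Hz update rate of the oldest preset
  a 10-s trial contains too little motion to produce errors at all.
* **Staircase.** σ starts at 1.0 on a 0.5 lattice in [0.5, 6.0];
  success branches down/stay/up with probability ⅓ each (clamped),
  any error resets to 1.0; convergence is five consecutive fully
  correct trials spanning at most 0.5.
* **Preset object counts.** Where the source experiments do not state
  them: 10 objects (targets 1–5) for the 1988 configuration, equal
  targets and distractors for the 2007 one, 12 objects (targets 1–6)
  for the 2016 one, 8 objects for the 2008 displays, 14 for the
  package's Exp1 design, and one distractor more than targets for the
  shell-game design. All are recorded in `mot_preset()$meta` and
  overridable.
* **Degenerate inputs.** All-zero confusion ratios fall back to a
  uniform draw (argmax-with-lowest-index under $c_e = \infty$); a
  location exactly on an object has confusion 0 (unambiguous); an
  empty attended list clears the unitary buffer; `sigma = 0` shell-game
  requests are rejected outright (no order change is possible).

## What the generators emulate — and what they do not

The simulated displays reproduce the *kinematic* structure of the
source experiments: speeds, update rates, separation constraints,
window geometry, trial durations. They do not render anything, and they
idealise away several properties of real displays and observers:
objects are points (no size, occlusion cues, or T-junctions), there is
no eye movement, no attentional lapses, no feature information, and
initial positions are uniform within the arena rather than
experimenter-designed. Passing tests therefore show that the *model
mechanism* behaves as specified under these idealised conditions; they
do not certify fits to any individual human dataset beyond the summary
benchmarks the acceptance script recomputes.

## Problem sizes

The test suite and the acceptance script run at deliberately modest,
fixed scales chosen to keep every statistic stable at its asserted
tolerance: 10⁵ OU updates for the displacement factor, 200 seeded
trials per accuracy benchmark, 200 trials per point for the
monotonicity properties (asserted within 2 SEM), 10³ random maps for
the search oracle, and 10⁴ draws for Bernoulli/staircase frequency
checks (±0.02). Reruns with the same seeds are bit-identical.

## Known limitations

* Tracking shares a single total update rate; there is no account of
  the 5–8 Hz temporal limits on attentional tracking reported
  elsewhere.
* Velocity use is restricted to one thread; trials where humans
  exploit predictable motion for several targets are outside the
  model's reach.
* The correspondence-update rule is one defensible reading of a
  heuristic the sources leave underspecified (remove the moved label,
  re-insert at its new rank); a global re-sort is equivalent under
  this rule.
* Speed thresholds assume accuracy is monotone in σ over the bracket;
  the bisection inherits that assumption.

## A worked example

```{r example, eval = FALSE}
env <- mot_env("ou", sigma = 1.25, arena = c(720, 720), eta = 30,
               n_updates = 300, n_targets = 4, n_objects = 8)
params <- mot_params(f_loc = 28, f_u = 10, c_e = Inf, nob = Inf,
                     f_corr = 0)
block <- run_block(env, params, n_trials = 200, seed = 1)
block$summary
```
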